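#' Tidiers for fitted epitope models and selection results
#'
#' `tidy()` on an `epitope_model` lists the model's features, one row each;
#' `glance()` gives a one-row model summary. On a `feature_selection`
#' result, `tidy()` returns the elimination log (one row per removal
#' attempt) and `glance()` the before/after cross-validated MCC.
#'
#' @param x An `epitope_model` or `feature_selection` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy epitope_model
#' @export
tidy.epitope_model <- function(x, ...) {
  tibble::tibble(term = x$manifest, index = seq_along(x$manifest))
}

#' @rdname tidiers
#' @method glance epitope_model
#' @export
glance.epitope_model <- function(x, ...) {
  tibble::tibble(
    C = x$config$C, gamma = x$config$gamma, seed = x$config$seed,
    n_features = length(x$manifest), n_train = x$n_train,
    n_support = x$fit$tot.nSV
  )
}

#' @rdname tidiers
#' @method tidy feature_selection
#' @export
tidy.feature_selection <- function(x, ...) x$log

#' @rdname tidiers
#' @method glance feature_selection
#' @export
glance.feature_selection <- function(x, ...) {
  tibble::tibble(
    n_kept = length(x$manifest),
    initial_mcc = x$initial_mcc, final_mcc = x$final_mcc,
    C = x$config$C, gamma = x$config$gamma, folds = x$config$folds
  )
}
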