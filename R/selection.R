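#' Biserial correlation of a feature with the epitope label
#'
#' `BCC = (M_e - M_ne) * sqrt(n_e * n_ne / n) / stdev`, where `M_e` and
#' `M_ne` are the class-conditional feature means, `n_e`, `n_ne`, `n` the
#' class and total counts, and `stdev` the population standard deviation of
#' the feature over all samples. A constant feature (`stdev = 0`) scores 0.
#'
#' Note the `sqrt(n_e*n_ne/n)` normalizer is used verbatim; the classical
#' point-biserial coefficient divides by `n` inside the square root twice,
#' so this statistic can exceed `[-1, 1]`. Since `n` is fixed across
#' features, the induced ranking is identical, which is all the selection
#' procedure uses.
#'
#' @param x Numeric feature values.
#' @param labels Epitope/non-epitope labels (factor, character, or logical
#'   with `TRUE` = epitope).
#' @return Real; positive when epitopes have the larger mean.
#' @export
biserial_cc <- function(x, labels) {
  if (is.logical(labels)) {
    pos <- labels
  } else {
    pos <- as.character(labels) == "epitope"
  }
  stopifnot(length(x) == length(pos))
  n_e <- sum(pos); n_ne <- sum(!pos); n <- n_e + n_ne
  if (n_e == 0 || n_ne == 0) {
    stop("both classes must be present to compute the BCC", call. = FALSE)
  }
  stdev <- sqrt(mean((x - mean(x))^2))  # population form
  if (stdev == 0) return(0)
  (mean(x[pos]) - mean(x[!pos])) * sqrt(n_e * n_ne / n) / stdev
}

#' Rank features by cross-fold mean absolute biserial correlation
#'
#' For each feature, the absolute BCC is computed on the training portion of
#' each stratified fold and averaged; features are returned sorted by that
#' mean in ascending order (the least label-correlated features first, the
#' order in which backward elimination attempts removals). Ties keep the
#' canonical feature order.
#'
#' @param data Featurized tibble with a `label` column.
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param fold Optional precomputed fold assignment (overrides
#'   `folds`/`seed`).
#' @param label_col Name of the label column.
#' @return Tibble with `feature` and `mean_abs_bcc`, ascending.
#' @export
rank_features <- function(data, folds = 10, seed = 1, fold = NULL,
                          label_col = "label") {
  y <- as.character(data[[label_col]]) == "epitope"
  feats <- setdiff(names(data), label_col)
  if (is.null(fold)) fold <- make_folds(y, folds, seed)
  k <- max(fold)
  abs_bcc <- sapply(feats, function(f) {
    mean(vapply(seq_len(k), function(i) {
      tr <- fold != i
      abs(biserial_cc(data[[f]][tr], y[tr]))
    }, numeric(1)))
  })
  ord <- order(abs_bcc)  # stable: ties keep canonical order
  tibble::tibble(feature = feats[ord], mean_abs_bcc = unname(abs_bcc[ord]))
}

#' Backward feature elimination under cross-validated MCC
#'
#' Starting from the full feature set, features are considered for removal
#' in ascending order of mean absolute BCC (least correlated first). A
#' feature is dropped iff removing it does not lower the cross-validated MCC
#' of the SVM classifier; sweeps over the remaining features repeat until a
#' full sweep removes nothing. One seeded stratified fold partition is used
#' for the entire procedure, making the outcome deterministic given the
#' seed, the ranking, and the hyperparameters. The final MCC is by
#' construction at least the initial MCC.
#'
#' @param data Featurized tibble with a `label` column.
#' @param ranking Optional tibble from [rank_features()]; computed on the
#'   same fold partition when omitted.
#' @param C,gamma SVM hyperparameters used throughout.
#' @param folds Number of cross-validation folds.
#' @param seed Seed for the fold partition.
#' @param label_col Name of the label column.
#' @return Object of class `feature_selection`: a list with `manifest`
#'   (surviving features in canonical order), `log` (one row per removal
#'   attempt: feature, MCC before/after, kept or dropped), `initial_mcc`,
#'   `final_mcc`, and the fold assignment.
#' @export
backward_eliminate <- function(data, ranking = NULL, C = 2^3, gamma = 2^-10,
                               folds = 10, seed = 1, label_col = "label") {
  y <- fragment_label(as.character(data[[label_col]]))
  feats <- setdiff(names(data), label_col)
  fold <- make_folds(y, folds, seed)
  if (is.null(ranking)) {
    ranking <- rank_features(data, fold = fold, label_col = label_col)
  }
  x_all <- as.matrix(data[, feats, drop = FALSE])
  cv_mcc <- function(cols) {
    cv_criterion(cv_predictions(x_all[, cols, drop = FALSE], y, C, gamma,
                                fold), "mcc")
  }
  current <- feats
  current_mcc <- cv_mcc(current)
  initial_mcc <- current_mcc
  log <- list()
  repeat {
    removed_any <- FALSE
    for (f in intersect(ranking$feature, current)) {
      if (length(current) <= 1) break
      trial <- setdiff(current, f)
      trial_mcc <- cv_mcc(trial)
      kept <- trial_mcc < current_mcc
      log[[length(log) + 1]] <- tibble::tibble(
        feature = f, mcc_before = current_mcc, mcc_after = trial_mcc,
        action = if (kept) "kept" else "dropped")
      if (!kept) {
        current <- trial
        current_mcc <- trial_mcc
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  structure(
    list(manifest = feats[feats %in% current],  # canonical order
         log = dplyr::bind_rows(log),
         initial_mcc = initial_mcc, final_mcc = current_mcc,
         fold = fold,
         config = list(C = C, gamma = gamma, folds = folds, seed = seed)),
    class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection> kept ", length(x$manifest), " features; CV MCC ",
      round(x$initial_mcc, 4), " -> ", round(x$final_mcc, 4), "\n", sep = "")
  invisible(x)
}
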