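#' Train the RBF-kernel fragment classifier
#'
#' Fits a radial-basis support vector machine on a featurized fragment
#' dataset. Features are standardized (zero mean, unit variance) with
#' parameters learned on the training data, and probability outputs are
#' produced by the standard sigmoid calibration of the margin scores, so
#' predictions land in `[0, 1]` and a fragment is called an epitope when its
#' score exceeds 0.5.
#'
#' Default hyperparameters are `C = 2^0`, `gamma = 2^-9`, the values tuned
#' for the selected-feature model; the full 198-feature model uses `C = 2^3`,
#' `gamma = 2^-10` (see [grid_search()]).
#'
#' @param data Tibble from [extract_features()] holding the feature columns
#'   and a `label` column (factor, levels `non-epitope`/`epitope`).
#' @param C,gamma SVM cost and RBF width.
#' @param seed Seed fixed before fitting (probability calibration uses
#'   internal cross-validation).
#' @param manifest Feature names to train on, in order; defaults to every
#'   non-label column.
#' @param library,scale,fallback_table,background Optional artifacts bundled
#'   into the model so that whole-chain prediction can re-featurize windows
#'   consistently.
#' @param label_col Name of the label column.
#' @return An object of class `epitope_model`.
#' @export
svm_train <- function(data, C = 2^0, gamma = 2^-9, seed = 1,
                      manifest = NULL, library = NULL, scale = NULL,
                      fallback_table = NULL, background = NULL,
                      label_col = "label") {
  if (!label_col %in% names(data)) {
    stop("no '", label_col, "' column in training data", call. = FALSE)
  }
  y <- fragment_label(as.character(data[[label_col]]))
  if (length(unique(y)) < 2) {
    stop("training data holds a single class; need both epitope and ",
         "non-epitope fragments", call. = FALSE)
  }
  if (min(table(y)) < 2) stop("need at least 2 fragments per class", call. = FALSE)
  if (is.null(manifest)) {
    manifest <- setdiff(names(data), label_col)
  }
  x <- as.matrix(data[, manifest, drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  set.seed(seed)
  fit <- suppressWarnings(e1071::svm(
    x, y, kernel = "radial", cost = C, gamma = gamma,
    probability = TRUE, scale = TRUE
  ))
  structure(
    list(fit = fit,
         config = list(C = C, gamma = gamma, seed = seed),
         manifest = manifest,
         library = library, scale = scale,
         fallback_table = fallback_table,
         background = background,
         n_train = nrow(x)),
    class = "epitope_model")
}

#' @export
print.epitope_model <- function(x, ...) {
  cat("<epitope_model> RBF SVM: C = ", x$config$C,
      ", gamma = ", format(x$config$gamma), ", ",
      length(x$manifest), " features, ", x$n_train, " training fragments\n",
      sep = "")
  invisible(x)
}

#' Score featurized fragments with a trained model
#'
#' @param model An `epitope_model`.
#' @param data Featurized tibble whose columns cover the model's manifest
#'   (order-insensitive; columns are aligned by name).
#' @param decision_values Also return the raw SVM margins?
#' @return Tibble with `score` (calibrated probability in `[0, 1]`), `call`
#'   (`"epitope"` iff `score > 0.5`; an exact 0.5 is non-epitope), and
#'   optionally `margin`.
#' @export
predict_fragments <- function(model, data, decision_values = FALSE) {
  stopifnot(inherits(model, "epitope_model"))
  missing <- setdiff(model$manifest, names(data))
  if (length(missing) > 0) {
    stop("data lacks model features (manifest mismatch): ",
         paste(utils::head(missing), collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(data[, model$manifest, drop = FALSE])
  pred <- stats::predict(model$fit, x, probability = TRUE,
                         decision.values = TRUE)
  prob <- attr(pred, "probabilities")[, "epitope"]
  out <- tibble::tibble(
    score = unname(prob),
    call = fragment_label(ifelse(prob > 0.5, "epitope", "non-epitope"))
  )
  if (decision_values) {
    dv <- attr(pred, "decision.values")
    out$margin <- orient_decision_values(dv)
  }
  out
}

# e1071 labels the decision-value column "<first>/<second>"; orient so that
# larger values always mean epitope.
orient_decision_values <- function(dv) {
  v <- as.numeric(dv[, 1])
  lab <- colnames(dv)[1]
  if (!is.null(lab) && startsWith(lab, "non-epitope/")) v <- -v
  v
}

#' Seeded stratified fold assignment
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k, seed = 1) {
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  labels <- as.character(labels)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k && length(idx) < 2) {
      stop("class '", cl, "' too small for ", k, "-fold stratification",
           call. = FALSE)
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Pooled cross-validated predictions (binary calls + oriented margins) for
# one hyperparameter pair on a fixed fold assignment.
cv_predictions <- function(x, y, C, gamma, fold) {
  k <- max(fold)
  out <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || sum(!tr) == 0) {
      stop("degenerate fold ", f, ": a training split lost a class",
           call. = FALSE)
    }
    fit <- suppressWarnings(e1071::svm(
      x[tr, , drop = FALSE], y[tr], kernel = "radial",
      cost = C, gamma = gamma, scale = TRUE))
    pred <- stats::predict(fit, x[!tr, , drop = FALSE],
                           decision.values = TRUE)
    out[[f]] <- tibble::tibble(
      truth = y[!tr],
      call = fragment_label(as.character(pred)),
      margin = orient_decision_values(attr(pred, "decision.values"))
    )
  }
  dplyr::bind_rows(out)
}

cv_criterion <- function(pred, criterion) {
  truth_pos <- pred$truth == "epitope"
  call_pos <- pred$call == "epitope"
  switch(criterion,
    mcc = {
      cm <- confusion_metrics(TP = sum(truth_pos & call_pos),
                              TN = sum(!truth_pos & !call_pos),
                              FP = sum(!truth_pos & call_pos),
                              FN = sum(truth_pos & !call_pos),
                              quiet = TRUE)
      cm$mcc
    },
    auc = auc_score(pred$margin, truth_pos),
    accuracy = mean(truth_pos == call_pos)
  )
}

#' Grid search for SVM hyperparameters
#'
#' Evaluates every `(C, gamma)` pair by stratified cross-validation on the
#' training fragments and returns the pair maximizing the criterion
#' (cross-validated MCC by default, computed on the pooled out-of-fold
#' predictions at the 0.5 cutoff). Ties are broken toward the smallest `C`,
#' then the smallest `gamma`. The default grids are
#' `C = 2^-2 .. 2^4` and `gamma = 2^-11 .. 2^0` (84 candidate pairs).
#'
#' @param data Featurized tibble with a `label` column.
#' @param C_grid,gamma_grid Candidate values.
#' @param folds Number of cross-validation folds (default 10).
#' @param criterion `"mcc"` (default), `"auc"`, or `"accuracy"`.
#' @param seed Seed for the fold assignment.
#' @param label_col Name of the label column.
#' @return List with `C`, `gamma`, the full `results` tibble, and the fold
#'   assignment used.
#' @export
grid_search <- function(data, C_grid = 2^(-2:4), gamma_grid = 2^(-11:0),
                        folds = 10, criterion = c("mcc", "auc", "accuracy"),
                        seed = 1, label_col = "label") {
  criterion <- match.arg(criterion)
  if (length(C_grid) == 0 || length(gamma_grid) == 0) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  y <- fragment_label(as.character(data[[label_col]]))
  x <- as.matrix(data[, setdiff(names(data), label_col), drop = FALSE])
  fold <- make_folds(y, folds, seed)
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    cv_criterion(cv_predictions(x, y, grid$C[i], grid$gamma[i], fold),
                 criterion)
  }, numeric(1))
  results <- tibble::tibble(C = grid$C, gamma = grid$gamma, value = vals)
  ord <- order(-results$value, results$C, results$gamma)
  best <- results[ord[1], ]
  list(C = best$C, gamma = best$gamma, criterion = criterion,
       results = results, fold = fold)
}
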