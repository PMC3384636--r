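#' Binary-classification quality measures
#'
#' Computes accuracy, sensitivity, specificity, precision, F-measure, and
#' the Matthews correlation coefficient from a confusion table:
#'
#' * `Accuracy  = (TP+TN)/(TP+FP+TN+FN)`
#' * `Sensitivity = TP/(TP+FN)`
#' * `Specificity = TN/(TN+FP)`
#' * `Precision = TP/(TP+FP)`
#' * `F-measure = 2*TP/(2*TP+FN+FP)`
#' * `MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
#'
#' The MCC numerator uses the standard minus sign (some sources misprint it
#' with a plus; the plus form is not a correlation and is not implemented).
#' When any factor of the MCC denominator is 0 the MCC is reported as 0 by
#' convention (a message notes this); ratio metrics with a zero denominator
#' are `NA` with a warning.
#'
#' @param TP,TN,FP,FN Non-negative confusion counts.
#' @param quiet Suppress the degenerate-denominator message.
#' @return One-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f_measure`, `mcc`.
#' @export
#' @examples
#' confusion_metrics(TP = 50, TN = 40, FP = 10, FN = 20)
confusion_metrics <- function(TP, TN, FP, FN, quiet = FALSE) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("negative confusion counts", call. = FALSE)
  if (sum(counts) == 0) stop("empty confusion table", call. = FALSE)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom2 == 0) {
    if (!quiet) message("MCC denominator has a zero factor; reporting 0")
    0
  } else {
    (TP * TN - FP * FN) / sqrt(denom2)
  }
  tibble::tibble(
    accuracy = (TP + TN) / sum(counts),
    sensitivity = ratio(TP, TP + FN, "sensitivity"),
    specificity = ratio(TN, TN + FP, "specificity"),
    precision = ratio(TP, TP + FP, "precision"),
    f_measure = ratio(2 * TP, 2 * TP + FN + FP, "F-measure"),
    mcc = mcc
  )
}

#' @rdname confusion_metrics
#' @param truth,prediction Logical vectors (or factors coercible to
#'   epitope/non-epitope) of true and predicted positives.
#' @export
confusion_counts <- function(truth, prediction) {
  as_pos <- function(x) {
    if (is.logical(x)) return(x)
    as.character(x) %in% c("epitope", "1", "TRUE")
  }
  t <- as_pos(truth); p <- as_pos(prediction)
  stopifnot(length(t) == length(p))
  list(TP = sum(t & p), TN = sum(!t & !p), FP = sum(!t & p), FN = sum(t & !p))
}

#' Area under the ROC curve
#'
#' Two equivalent constructions are implemented: the tie-corrected
#' Mann--Whitney rank statistic (default; ties contribute 1/2) and an
#' explicit threshold sweep over the unique scores with trapezoidal
#' integration. The two agree exactly and either may be requested.
#'
#' @param scores Real-valued predictions (higher = more epitope-like).
#' @param labels Logical (or epitope/non-epitope factor) truth; both classes
#'   must be present.
#' @param method `"rank"` (default) or `"trapezoid"`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, method = c("rank", "trapezoid")) {
  method <- match.arg(method)
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.character(labels) == "epitope"
  }
  stopifnot(length(scores) == length(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  if (method == "rank") {
    r <- rank(scores)
    return((sum(r[labels]) - np * (np + 1) / 2) / (np * nn))
  }
  # threshold sweep: predict positive at score >= t for decreasing t
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels) / np,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & !labels) / nn,
                     numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Per-chain success rate of propensity profiles
#'
#' A chain is counted as a success when the mean predicted propensity over
#' its native epitope residues strictly exceeds the mean propensity over all
#' of its residues. Chains without any epitope residue cannot be evaluated
#' and are excluded (with a message). The success rate is the fraction of
#' evaluated chains that succeed.
#'
#' @param data Tibble with one row per residue and columns `chain_id`,
#'   `propensity`, and `is_epitope` (logical or 0/1).
#' @return One-row tibble: `success_rate`, `n_success`, `n_evaluated`,
#'   `n_excluded`.
#' @export
success_rate <- function(data) {
  stopifnot(all(c("chain_id", "propensity", "is_epitope") %in% names(data)))
  if (nrow(data) == 0) stop("no chains to evaluate", call. = FALSE)
  per_chain <- data |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(
      has_epitope = any(as.logical(.data$is_epitope)),
      success = mean(.data$propensity[as.logical(.data$is_epitope)]) >
        mean(.data$propensity),
      .groups = "drop")
  excluded <- sum(!per_chain$has_epitope)
  if (excluded > 0) {
    message(excluded, " chain(s) without epitope residues excluded")
  }
  eval_chains <- per_chain[per_chain$has_epitope, ]
  if (nrow(eval_chains) == 0) stop("no evaluable chains", call. = FALSE)
  tibble::tibble(
    success_rate = mean(eval_chains$success),
    n_success = sum(eval_chains$success),
    n_evaluated = nrow(eval_chains),
    n_excluded = excluded
  )
}

#' Expand 1-based inclusive epitope intervals to a per-residue truth vector
#'
#' @param intervals Tibble/data frame with columns `start` and `end`.
#' @param length Chain length.
#' @return Logical vector of the given length.
#' @export
intervals_to_truth <- function(intervals, length) {
  truth <- rep(FALSE, length)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s < 1 || e > length || s > e) {
      stop("interval [", s, ", ", e, "] out of range for chain of length ",
           length, call. = FALSE)
    }
    truth[s:e] <- TRUE
  }
  truth
}
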