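#' Slice an annotated chain into sliding 20-mer fragments
#'
#' A chain of length `L >= 20` yields `L - 19` windows at offsets
#' `1 .. L-19` (1-based), each carrying its peptide and the consistently
#' sliced secondary-structure, RSA, and conservation channels. Chains
#' shorter than 20 residues are rejected: the feature machinery is defined
#' on 20-mers and no padding rule exists.
#'
#' @param annotated An [annotate_chain()] result.
#' @return Tibble with columns `offset`, `peptide`, `ss`, `rsa`,
#'   `conservation` (the last two are list columns).
#' @export
make_windows <- function(annotated) {
  L <- nrow(annotated)
  if (L < 20) {
    stop("chain is shorter than 20 residues (", L,
         "); cannot form any 20-mer window", call. = FALSE)
  }
  seq_str <- paste(annotated$residue, collapse = "")
  ss_str <- paste(annotated$ss, collapse = "")
  offsets <- seq_len(L - 19)
  tibble::tibble(
    offset = offsets,
    peptide = substring(seq_str, offsets, offsets + 19),
    ss = substring(ss_str, offsets, offsets + 19),
    rsa = lapply(offsets, function(o) annotated$rsa[o:(o + 19)]),
    conservation = lapply(offsets, function(o)
      annotated$conservation[o:(o + 19)])
  )
}

#' Windows covering one residue
#'
#' Residue `i` (1-based) of a chain of length `L` is covered by the windows
#' at offsets `max(1, i-19) .. min(i, L-19)` -- between 1 score (at either
#' terminus) and 20 scores (residues at least 20 positions from both ends).
#'
#' @param i Residue position.
#' @param L Chain length (`>= 20`).
#' @return Integer vector of window offsets.
#' @export
covering_windows <- function(i, L) {
  stopifnot(L >= 20, i >= 1, i <= L)
  seq(max(1, i - 19), min(i, L - 19))
}

#' Aggregate the window scores of one residue into a propensity
#'
#' Every residue inherits the SVM score of each 20-mer window covering it;
#' the aggregation scheme turns that multiset into one propensity:
#'
#' * `max`: the maximum score;
#' * `average`: the mean;
#' * `median`: the median (mean of the middle two for even counts);
#' * `distance`: the mean of the `k` scores farthest from the 0.5 decision
#'   boundary (the most confident window predictions). With `k = 20` on a
#'   full multiset this reduces exactly to the average scheme. When fewer
#'   than `k` scores are available (near termini) all of them are used.
#'   Ties in `|score - 0.5|` are included by ascending window offset.
#'
#' @param scores Numeric vector of window scores (non-empty).
#' @param scheme `"distance"` (default), `"average"`, `"median"`, or
#'   `"max"`.
#' @param k Number of scores retained by the distance scheme (1--20,
#'   default 16).
#' @param offsets Window offsets parallel to `scores`, used only for
#'   deterministic tie-breaking; defaults to input order.
#' @return The aggregated propensity.
#' @export
aggregate_scores <- function(scores,
                             scheme = c("distance", "average", "median", "max"),
                             k = 16, offsets = seq_along(scores)) {
  scheme <- match.arg(scheme)
  if (length(scores) == 0) stop("empty score multiset", call. = FALSE)
  switch(scheme,
    max = max(scores),
    average = mean(scores),
    median = stats::median(scores),
    distance = {
      if (k < 1 || k > 20) stop("k must lie in 1..20", call. = FALSE)
      ord <- order(-abs(scores - 0.5), offsets)
      mean(scores[ord[seq_len(min(k, length(scores)))]])
    })
}

#' Predict a per-residue epitope propensity profile for a chain
#'
#' The end-to-end second stage: slide 20-mer windows over the annotated
#' chain, featurize each window against the model's similarity library and
#' dipeptide scale, score the windows with the SVM, and aggregate each
#' residue's covering-window scores into a propensity. The default is the
#' distance scheme with `k = 16`.
#'
#' @param annotated An [annotate_chain()] result.
#' @param model A trained [svm_train()] model bundling `library` and
#'   `scale`.
#' @param scheme,k Aggregation scheme and distance-scheme depth, see
#'   [aggregate_scores()].
#' @return Tibble of class `epitope_profile` with columns `position`,
#'   `residue`, `propensity`; attributes `id`, `scheme`, `k`.
#' @export
predict_chain <- function(annotated, model,
                          scheme = c("distance", "average", "median", "max"),
                          k = 16) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(model, "epitope_model"))
  if (is.null(model$library) || is.null(model$scale)) {
    stop("model must bundle a similarity library and a dipeptide scale ",
         "for whole-chain prediction", call. = FALSE)
  }
  windows <- make_windows(annotated)
  feats <- extract_features(windows, model$library, model$scale,
                            manifest = model$manifest, exclude = "none")
  scores <- predict_fragments(model, feats)$score
  L <- nrow(annotated)
  prop <- vapply(seq_len(L), function(i) {
    w <- covering_windows(i, L)
    aggregate_scores(scores[w], scheme = scheme, k = k, offsets = w)
  }, numeric(1))
  out <- tibble::tibble(position = annotated$position,
                        residue = annotated$residue,
                        propensity = prop)
  attr(out, "id") <- attr(annotated, "id")
  attr(out, "scheme") <- scheme
  attr(out, "k") <- k
  class(out) <- c("epitope_profile", class(out))
  out
}
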