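#' Multi-mer similarity between two peptides
#'
#' Counts the identical substrings (multi-mers) shared by two peptides:
#' shared single residues, shared 2-mers, 3-mers, and so on, summed over all
#' substring lengths. Two counting semantics are provided:
#'
#' * `"distinct"` (default): for each length L, the number of distinct
#'   L-mers that occur in both peptides (set intersection).
#' * `"positional"`: the number of position pairs `(i, j)` at which equal
#'   L-mers start, summed over L, so repeated occurrences count multiply.
#'
#' The score is symmetric and non-negative; two peptides over disjoint
#' alphabets score 0, and two identical 20-mers with 20 distinct residues
#' score `sum(21 - L) = 210` under both semantics.
#'
#' @param a,b Peptide strings (any positive length; the predictor uses
#'   20-mers).
#' @param mode `"distinct"` or `"positional"`.
#' @return Non-negative integer.
#' @export
#' @examples
#' fragment_similarity("ACDEF", "ACDEF")   # 15
#' fragment_similarity("AAAAA", "CCCCA")   # 1: only the 1-mer "A" is shared
fragment_similarity <- function(a, b, mode = c("distinct", "positional")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty peptide", call. = FALSE)
  if (mode == "distinct") {
    return(length(intersect(substring_set(a), substring_set(b))))
  }
  na <- nchar(a); nb <- nchar(b)
  total <- 0L
  for (L in seq_len(min(na, nb))) {
    sa <- substring(a, 1:(na - L + 1), L:na)
    sb <- substring(b, 1:(nb - L + 1), L:nb)
    total <- total + sum(outer(sa, sb, "=="))
  }
  total
}

# All distinct substrings of a peptide, across every length, as one
# character vector (substrings of different lengths are distinct strings).
substring_set <- function(pep) {
  n <- nchar(pep)
  unique(unlist(lapply(seq_len(n), function(L) {
    unique(substring(pep, 1:(n - L + 1), L:n))
  }), use.names = FALSE))
}

#' Build a similarity reference library of labeled 20-mers
#'
#' The library holds the epitope and non-epitope fragments that queries are
#' scored against; substring sets are precomputed once so that repeated
#' scoring is fast.
#'
#' @param epitopes,non_epitopes Character vectors of 20-mer peptides. Either
#'   side may be empty (queries are then padded with zero scores).
#' @param id Optional provenance tag (e.g., a cross-validation fold id).
#' @return An object of class `fragment_library`.
#' @export
fragment_library <- function(epitopes, non_epitopes, id = NULL) {
  check_20mers <- function(x, side) {
    if (length(x) > 0 && any(nchar(x) != 20)) {
      stop("all ", side, " library peptides must be 20-mers", call. = FALSE)
    }
  }
  check_20mers(epitopes, "epitope")
  check_20mers(non_epitopes, "non-epitope")
  structure(
    list(
      epitopes = epitopes,
      non_epitopes = non_epitopes,
      sets_e = lapply(epitopes, substring_set),
      sets_ne = lapply(non_epitopes, substring_set),
      id = id
    ),
    class = "fragment_library"
  )
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("<fragment_library> ", length(x$epitopes), " epitopes, ",
      length(x$non_epitopes), " non-epitopes",
      if (!is.null(x$id)) paste0(" (", x$id, ")"), "\n", sep = "")
  invisible(x)
}

#' Rebuild a similarity library from a fragment table
#'
#' Builds a [fragment_library()] from the peptides of a labeled fragment
#' tibble and rewrites the `.lib_side` / `.lib_index` provenance columns so
#' that featurizing these same fragments excludes self-matches correctly.
#' Use this after subsetting a dataset (e.g., taking a training fold), when
#' the original provenance no longer matches the library.
#'
#' @param fragments Tibble with `peptide` and `label` columns.
#' @param id Optional provenance tag.
#' @return List with the updated `fragments` and the `library`.
#' @export
library_from_fragments <- function(fragments, id = NULL) {
  is_epi <- as.character(fragments$label) == "epitope"
  lib <- fragment_library(fragments$peptide[is_epi],
                          fragments$peptide[!is_epi], id = id)
  fragments$.lib_side <- ifelse(is_epi, "epitope", "non-epitope")
  fragments$.lib_index <- NA_integer_
  fragments$.lib_index[is_epi] <- seq_len(sum(is_epi))
  fragments$.lib_index[!is_epi] <- seq_len(sum(!is_epi))
  list(fragments = fragments, library = lib)
}

#' Top-k similarity features against a fragment library
#'
#' Computes the k highest multi-mer similarity scores between a query 20-mer
#' and each side of the library (epitopes and non-epitopes), sorted
#' descending. Sides with fewer than k members are padded with 0 ("no
#' similarity"). Under cross-validation a library member must not be scored
#' against itself; pass its index in `exclude_epitope` /
#' `exclude_non_epitope` (exact duplicates at other indices still count).
#'
#' @param query Peptide string.
#' @param library A [fragment_library()].
#' @param k Number of order statistics per side (default 5).
#' @param exclude_epitope,exclude_non_epitope Optional member indices to
#'   leave out.
#' @param mode Counting semantics, see [fragment_similarity()].
#' @return Named numeric vector of length `2k`:
#'   `max_similarity_epitope_1..k`, then `max_similarity_non_epitope_1..k`.
#' @export
topk_similarity <- function(query, library, k = 5,
                            exclude_epitope = NULL,
                            exclude_non_epitope = NULL,
                            mode = c("distinct", "positional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "fragment_library"))
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  qset <- if (mode == "distinct") substring_set(query) else NULL
  side_scores <- function(peps, sets, exclude) {
    idx <- seq_along(peps)
    if (!is.null(exclude)) idx <- setdiff(idx, exclude)
    if (length(idx) == 0) return(numeric(0))
    if (mode == "distinct") {
      vapply(idx, function(i) length(intersect(qset, sets[[i]])), numeric(1))
    } else {
      vapply(idx, function(i) as.numeric(fragment_similarity(query, peps[i],
                                                             mode = mode)),
             numeric(1))
    }
  }
  top <- function(s) {
    s <- sort(s, decreasing = TRUE)
    out <- c(s, rep(0, k))[seq_len(k)]
    out
  }
  e <- top(side_scores(library$epitopes, library$sets_e, exclude_epitope))
  ne <- top(side_scores(library$non_epitopes, library$sets_ne,
                        exclude_non_epitope))
  stats::setNames(c(e, ne),
                  c(paste0("max_similarity_epitope_", seq_len(k)),
                    paste0("max_similarity_non_epitope_", seq_len(k))))
}
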