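#' Profile conservation score for one residue
#'
#' Computes `sum_i P_i * log2(P_i / P_ib)` over the 20 amino acids, where
#' `P_i` is the WOP percentage divided by 100 and `P_ib` the background
#' probability of residue i. Terms with `P_i = 0` contribute 0. When the WOP
#' row is a proper distribution this is the Kullback--Leibler divergence of
#' the profile column from the background; raw WOP rows are used as written
#' (divided by 100, not renormalized), so no sign guarantee is made for rows
#' that do not sum to 100.
#'
#' All-zero rows are not scoreable: replace them first with
#' [apply_wop_fallback()].
#'
#' @param wop_row Numeric vector of 20 percentages in `[0, 100]`, named by
#'   residue or given in [aa_alphabet()] order.
#' @param background Named background probabilities (default
#'   [background_freqs()]).
#' @return A finite real.
#' @export
#' @examples
#' row <- rep(5, 20)                       # matches a uniform background
#' conservation_score(row, background_freqs("uniform"))  # 0
conservation_score <- function(wop_row, background = background_freqs()) {
  background <- validate_background(background)
  if (length(wop_row) != 20) stop("WOP row must have 20 entries", call. = FALSE)
  if (any(wop_row < 0)) stop("negative WOP entry", call. = FALSE)
  if (!is.null(names(wop_row))) wop_row <- wop_row[aa_alphabet()]
  if (sum(wop_row) == 0) {
    stop("all-zero WOP row: apply the fallback table before scoring",
         call. = FALSE)
  }
  p <- wop_row / 100
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / background[nz]))
}

#' Per-residue conservation profile for a chain
#'
#' @param wop An `L x 20` WOP matrix ([read_wop()]); zero rows must already
#'   have been replaced via [apply_wop_fallback()].
#' @param background Named background probabilities.
#' @return Numeric vector of length `L`.
#' @export
conservation_profile <- function(wop, background = background_freqs()) {
  background <- validate_background(background)
  if (any(rowSums(unclass(wop)) == 0)) {
    stop("WOP matrix still contains all-zero rows; apply_wop_fallback() first",
         call. = FALSE)
  }
  apply(unclass(wop), 1, conservation_score, background = background)
}

#' Build and apply the fallback table for all-zero WOP rows
#'
#' PSI-BLAST occasionally emits all-zero WOP rows. For such a residue the
#' conservation input is replaced by the average WOP vector of all residues
#' of the same amino-acid type whose rows are non-zero, computed over the
#' training chains. `wop_fallback_table()` builds that 20 x 20 table
#' (rows = residue type, columns = WOP entries); `apply_wop_fallback()`
#' substitutes it into flagged rows.
#'
#' @param wops A `wop_matrix` or list of them.
#' @param sequences Chain sequence (string) or list of them, parallel to
#'   `wops`.
#' @return For `wop_fallback_table()`: a 20 x 20 matrix; residue types never
#'   observed with a non-zero row have `NA` rows.
#' @export
wop_fallback_table <- function(wops, sequences) {
  if (inherits(wops, "wop_matrix") || (is.matrix(wops) && !is.list(wops))) {
    wops <- list(wops)
  }
  if (is.character(sequences)) sequences <- as.list(sequences)
  stopifnot(length(wops) == length(sequences))
  sums <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  counts <- stats::setNames(rep(0L, 20), aa_alphabet())
  for (i in seq_along(wops)) {
    m <- unclass(wops[[i]])
    res <- strsplit(sequences[[i]], "")[[1]]
    if (nrow(m) != length(res)) {
      stop("WOP row count does not match sequence length (entry ", i, ")",
           call. = FALSE)
    }
    keep <- rowSums(m) > 0 & res %in% aa_alphabet()
    for (j in which(keep)) {
      sums[res[j], ] <- sums[res[j], ] + m[j, ]
      counts[res[j]] <- counts[res[j]] + 1L
    }
  }
  out <- sums / ifelse(counts > 0, counts, NA_real_)
  out
}

#' @rdname wop_fallback_table
#' @param wop A single `wop_matrix`.
#' @param sequence The matching chain sequence.
#' @param fallback_table Table from `wop_fallback_table()`.
#' @return For `apply_wop_fallback()`: the matrix with zero rows replaced and
#'   the `zero_row` attribute cleared.
#' @export
apply_wop_fallback <- function(wop, sequence, fallback_table) {
  m <- unclass(wop)
  res <- strsplit(sequence, "")[[1]]
  stopifnot(nrow(m) == length(res))
  zero <- rowSums(m) == 0
  for (j in which(zero)) {
    row <- fallback_table[res[j], ]
    if (anyNA(row)) {
      stop("no fallback WOP vector available for residue type ", res[j],
           call. = FALSE)
    }
    m[j, ] <- row
  }
  as_wop_matrix(m)
}

#' Normalize absolute ASA to relative solvent accessibility
#'
#' Divides a predicted accessible surface area by the residue's reference
#' area in an extended Ala-X-Ala tripeptide and clips the ratio to `[0, 1]`
#' (predictors occasionally emit areas above the reference).
#'
#' @param asa Non-negative ASA value(s) in square Angstroms.
#' @param residue Parallel residue one-letter code(s).
#' @param reference Named reference-area vector (default
#'   [axa_reference_areas()]).
#' @return RSA value(s) in `[0, 1]`.
#' @export
normalize_rsa <- function(asa, residue, reference = axa_reference_areas()) {
  stopifnot(length(asa) == length(residue))
  if (any(asa < 0)) stop("ASA must be non-negative", call. = FALSE)
  unknown <- setdiff(unique(residue), names(reference))
  if (length(unknown) > 0) {
    stop("no reference area for residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pmin(1, pmax(0, asa / reference[residue]))
}

#' Buried/exposed call from relative solvent accessibility
#'
#' A residue is buried if its predicted RSA is below 25%, solvent exposed
#' otherwise (the boundary value 0.25 is exposed).
#'
#' @param rsa RSA value(s) in `[0, 1]`.
#' @return Character vector of `"buried"` / `"exposed"`.
#' @export
exposure_call <- function(rsa) {
  stopifnot(all(rsa >= 0 & rsa <= 1))
  ifelse(rsa < 0.25, "buried", "exposed")
}

#' Assemble a fully annotated chain
#'
#' Aligns a raw chain with its predicted secondary structure, solvent
#' accessibility, and PSI-BLAST profile into one per-residue table, deriving
#' RSA (normalizing ASA if needed), the buried/exposed call, and the profile
#' conservation score. Every channel is validated against the chain length
#' with a diagnostic naming the offending channel.
#'
#' @param chain One-row tibble (or list) with `id` and `sequence`.
#' @param ss_rsa Table from [read_ss_rsa()] (or a tibble with `ss`, `value`
#'   and a `kind` attribute).
#' @param wop WOP matrix from [read_wop()].
#' @param background Background frequencies for conservation.
#' @param fallback_table Optional table from [wop_fallback_table()]; required
#'   if `wop` has all-zero rows. When omitted and zero rows are present, a
#'   fallback table is computed from the chain's own non-zero rows.
#' @param reference Reference areas for ASA normalization.
#' @return Tibble of class `annotated_chain` with columns `position`,
#'   `residue`, `ss`, `rsa`, `exposure`, `conservation`; attributes `id` and
#'   `sequence`.
#' @export
annotate_chain <- function(chain, ss_rsa, wop,
                           background = background_freqs(),
                           fallback_table = NULL,
                           reference = axa_reference_areas()) {
  seq <- chain$sequence[[1]]
  id <- chain$id[[1]]
  L <- nchar(seq)
  res <- strsplit(seq, "")[[1]]
  if (nrow(ss_rsa) != L) {
    stop("SS/RSA channel length (", nrow(ss_rsa),
         ") does not match chain length (", L, ")", call. = FALSE)
  }
  if (nrow(wop) != L) {
    stop("WOP channel length (", nrow(wop),
         ") does not match chain length (", L, ")", call. = FALSE)
  }
  kind <- attr(ss_rsa, "kind") %||% "rsa"
  rsa <- if (kind == "asa") {
    as.numeric(normalize_rsa(ss_rsa$value, res, reference))
  } else {
    if (any(ss_rsa$value > 1)) {
      stop("RSA channel holds values above 1; pass kind = \"asa\"",
           call. = FALSE)
    }
    ss_rsa$value
  }
  if (any(rowSums(unclass(wop)) == 0)) {
    if (is.null(fallback_table)) {
      # no training-derived table supplied: average over this chain's own
      # non-zero rows, completing never-observed types with the background
      fallback_table <- wop_fallback_table(wop, seq)
      incomplete <- apply(fallback_table, 1, anyNA)
      if (any(incomplete)) {
        bg_row <- 100 * validate_background(background)
        fallback_table[incomplete, ] <- rep(bg_row, each = sum(incomplete))
        message("fallback WOP vectors for ",
                paste(rownames(fallback_table)[incomplete], collapse = ", "),
                " taken from the background (no non-zero rows observed)")
      }
    }
    wop <- apply_wop_fallback(wop, seq, fallback_table)
  }
  con <- conservation_profile(wop, background)
  out <- tibble::tibble(
    position = seq_len(L),
    residue = res,
    ss = ss_rsa$ss,
    rsa = rsa,
    exposure = exposure_call(rsa),
    conservation = as.numeric(con)
  )
  attr(out, "id") <- id
  attr(out, "sequence") <- seq
  class(out) <- c("annotated_chain", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
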