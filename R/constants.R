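#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids, one-letter codes, alphabetical order. This is
#' the column order used for WOP (weighted observation percentage) matrices
#' and background-frequency tables throughout the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Column order of the two 20-column blocks in PSI-BLAST ASCII PSSM output.
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Background amino-acid frequencies
#'
#' Per-residue background probabilities used in the profile conservation
#' score. The default is the Robinson--Robinson frequency table (the
#' background also used by BLAST); a uniform 1/20 table is available, and any
#' custom named vector over the 20 canonical residues is accepted by the
#' conservation functions.
#'
#' @param table `"robinson"` (default) or `"uniform"`.
#' @return Named numeric vector of length 20 summing to 1, in
#'   [aa_alphabet()] order.
#' @export
#' @examples
#' background_freqs("uniform")["A"]
background_freqs <- function(table = c("robinson", "uniform")) {
  table <- match.arg(table)
  if (table == "uniform") {
    p <- rep(1 / 20, 20)
    names(p) <- aa_alphabet()
    return(p)
  }
  p <- c(
    A = 0.078047, R = 0.051269, N = 0.044873, D = 0.053640, C = 0.019246,
    Q = 0.042644, E = 0.062949, G = 0.073772, H = 0.021992, I = 0.051420,
    L = 0.090191, K = 0.057438, M = 0.022425, F = 0.038556, P = 0.052028,
    S = 0.071198, T = 0.058413, W = 0.013298, Y = 0.032165, V = 0.064409
  )
  p <- p / sum(p)
  p[aa_alphabet()]
}

#' Ala-X-Ala reference solvent-accessible areas
#'
#' Maximum solvent-accessible surface areas (in square Angstroms) of residue X
#' in an extended Ala-X-Ala tripeptide, used to convert absolute ASA values
#' from a structure predictor into relative solvent accessibility. The table
#' can be overridden with any named vector covering the residues present.
#'
#' @return Named numeric vector of length 20 (square Angstroms).
#' @export
axa_reference_areas <- function() {
  a <- c(
    A = 110.2, C = 140.4, D = 144.1, E = 174.7, F = 200.7,
    G = 78.7,  H = 181.9, I = 185.0, K = 205.7, L = 183.1,
    M = 200.1, N = 146.4, P = 141.9, Q = 178.6, R = 229.0,
    S = 117.2, T = 138.7, V = 153.7, W = 240.5, Y = 213.7
  )
  a[aa_alphabet()]
}

validate_background <- function(p) {
  if (!is.numeric(p) || is.null(names(p))) {
    stop("background must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(aa_alphabet(), names(p))
  if (length(missing) > 0) {
    stop("background is missing residues: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p <- p[aa_alphabet()]
  if (any(p <= 0)) stop("background probabilities must be > 0", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6) {
    stop("background probabilities must sum to 1 (got ", sum(p), ")",
         call. = FALSE)
  }
  p
}
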