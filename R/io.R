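#' Read antigen chains from a FASTA file
#'
#' Reads protein sequences, uppercases them, and validates the residue
#' alphabet. In strict mode (the default) any character outside the 20
#' canonical amino acids is an error; in lenient mode the ambiguity codes
#' X/B/Z/U/J/O are replaced by `ambiguous_to` so that downstream scale and
#' profile lookups stay total, and any other character still errors.
#'
#' @param path Path to a FASTA file.
#' @param strict Reject non-canonical residues? Default `TRUE`.
#' @param ambiguous_to Residue substituted for ambiguity codes in lenient
#'   mode. Default `"A"`.
#' @return A tibble with columns `id` and `sequence`, one row per record, in
#'   file order.
#' @export
read_fasta <- function(path, strict = TRUE, ambiguous_to = "A") {
  stopifnot(file.exists(path))
  dropped <- FALSE
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      # Biostrings silently drops characters outside the AA alphabet
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        dropped <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (dropped) {
    stop("illegal residue character(s) in FASTA sequences (outside the ",
         "amino-acid alphabet)", call. = FALSE)
  }
  if (length(set) == 0) stop("FASTA file contains no records: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (any(!nzchar(seqs))) {
    stop("FASTA record with empty sequence: ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  seqs <- vapply(seqs, sanitize_sequence, character(1),
                 strict = strict, ambiguous_to = ambiguous_to,
                 USE.NAMES = FALSE)
  tibble::tibble(id = unname(ids), sequence = seqs)
}

sanitize_sequence <- function(seq, strict = TRUE, ambiguous_to = "A") {
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% aa_alphabet())
  if (!any(bad)) return(seq)
  if (strict) {
    stop("illegal residue character(s): ",
         paste(unique(chars[bad]), collapse = ", "),
         " (use strict = FALSE to map ambiguity codes)", call. = FALSE)
  }
  ambiguous <- chars %in% c("X", "B", "Z", "U", "J", "O")
  if (any(bad & !ambiguous)) {
    stop("illegal residue character(s): ",
         paste(unique(chars[bad & !ambiguous]), collapse = ", "), call. = FALSE)
  }
  chars[bad] <- ambiguous_to
  paste(chars, collapse = "")
}

#' Read a WOP (weighted observation percentage) matrix
#'
#' Parses the per-residue weighted observation percentages emitted by
#' PSI-BLAST, either from the classic ASCII PSSM (`-Q`) layout -- where the
#' WOP percentages are the second block of 20 numeric columns -- or from a
#' plain 20-column TSV. Rows whose 20 entries are all zero are flagged; these
#' must be replaced via [apply_wop_fallback()] before conservation scoring.
#'
#' @param path Input file.
#' @param dialect `"auto"` (default), `"psiblast-ascii"`, or `"tsv"`.
#' @param chain Optional sequence (string) to validate the row count against.
#' @return An `L x 20` numeric matrix of percentages in `[0, 100]`, columns
#'   named by [aa_alphabet()], with a logical attribute `zero_row` marking
#'   all-zero rows.
#' @export
read_wop <- function(path, dialect = c("auto", "psiblast-ascii", "tsv"),
                     chain = NULL) {
  stopifnot(file.exists(path))
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "auto") {
    dialect <- if (any(grepl("^\\s*\\d+\\s+[A-Z]\\s+-?\\d", lines)))
      "psiblast-ascii" else "tsv"
  }
  m <- if (dialect == "psiblast-ascii") parse_pssm_wop(lines)
       else parse_tsv_wop(lines)
  if (any(m < 0 | m > 100)) {
    stop("WOP entries must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(chain) && nrow(m) != nchar(chain)) {
    stop("WOP channel length (", nrow(m), ") does not match chain length (",
         nchar(chain), ")", call. = FALSE)
  }
  as_wop_matrix(m)
}

as_wop_matrix <- function(m) {
  colnames(m) <- aa_alphabet()
  attr(m, "zero_row") <- rowSums(m) == 0
  class(m) <- c("wop_matrix", class(m))
  m
}

parse_pssm_wop <- function(lines) {
  data_lines <- grep("^\\s*\\d+\\s+[A-Z](\\s+-?\\d+(\\.\\d+)?){20,}", lines,
                     value = TRUE)
  if (length(data_lines) == 0) {
    stop("no PSSM data rows found (expected '<pos> <aa> <40 numbers> ...')",
         call. = FALSE)
  }
  rows <- lapply(data_lines, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (length(num) < 40 || anyNA(num[1:40])) {
      stop("malformed PSSM row (need 40 numeric columns after position and ",
           "residue): ", substr(l, 1, 60), call. = FALSE)
    }
    num[21:40]
  })
  m <- do.call(rbind, rows)
  # reorder from PSSM column order to the alphabetical convention
  colnames(m) <- PSSM_AA_ORDER
  m[, aa_alphabet(), drop = FALSE]
}

parse_tsv_wop <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty WOP file", call. = FALSE)
  first <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  header <- NULL
  if (all(first %in% aa_alphabet()) && length(first) == 20) {
    header <- first
    lines <- lines[-1]
  }
  rows <- lapply(lines, function(l) {
    num <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (length(num) != 20 || anyNA(num)) {
      stop("WOP TSV row must hold exactly 20 numeric values: ",
           substr(l, 1, 60), call. = FALSE)
    }
    num
  })
  m <- do.call(rbind, rows)
  colnames(m) <- if (is.null(header)) aa_alphabet() else header
  m[, aa_alphabet(), drop = FALSE]
}

#' Write a WOP matrix as a 20-column TSV
#'
#' @param wop Matrix as returned by [read_wop()].
#' @param path Output path.
#' @export
write_wop <- function(wop, path) {
  utils::write.table(rbind(aa_alphabet(), format(unclass(wop), trim = TRUE)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-residue secondary structure and solvent accessibility
#'
#' Reads the two-column-per-residue table produced by a structure predictor:
#' a secondary-structure label in `{H, E, C}` and a solvent-accessibility
#' value, which is either an absolute ASA in square Angstroms (normalized
#' later against the Ala-X-Ala reference areas) or an already-relative RSA in
#' `[0, 1]`. A header line `ss<TAB>rsa` / `ss<TAB>asa` is accepted; with
#' `values = "auto"` any value above 1 marks the file as ASA.
#'
#' @param path Input TSV.
#' @param values `"auto"` (default), `"rsa"`, or `"asa"`.
#' @param chain Optional sequence to validate the row count against.
#' @return Tibble with columns `position`, `ss`, `value`; attribute `kind`
#'   is `"rsa"` or `"asa"`.
#' @export
read_ss_rsa <- function(path, values = c("auto", "rsa", "asa"), chain = NULL) {
  stopifnot(file.exists(path))
  values <- match.arg(values)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty SS/RSA file", call. = FALSE)
  tok1 <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (tolower(tok1[1]) == "ss") {
    if (values == "auto" && length(tok1) >= 2 &&
        tolower(tok1[2]) %in% c("rsa", "asa")) {
      values <- tolower(tok1[2])
    }
    lines <- lines[-1]
  }
  rows <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (any(lengths(rows) < 2)) {
    stop("each SS/RSA row needs a label and a value", call. = FALSE)
  }
  ss <- toupper(vapply(rows, `[`, character(1), 1))
  val <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 2)))
  if (anyNA(val)) stop("non-numeric accessibility value", call. = FALSE)
  if (any(!(ss %in% c("H", "E", "C")))) {
    stop("secondary-structure labels must be H, E, or C (ss channel)",
         call. = FALSE)
  }
  if (any(val < 0)) stop("accessibility values must be non-negative", call. = FALSE)
  if (values == "auto") values <- if (any(val > 1)) "asa" else "rsa"
  if (!is.null(chain) && length(ss) != nchar(chain)) {
    stop("SS/RSA channel length (", length(ss),
         ") does not match chain length (", nchar(chain), ")", call. = FALSE)
  }
  out <- tibble::tibble(position = seq_along(ss), ss = ss, value = val)
  attr(out, "kind") <- values
  out
}

#' Read or build a dipeptide propensity scale
#'
#' A dipeptide scale maps each ordered amino-acid pair (400 keys) to a real
#' antigenicity propensity. The on-disk form is a 3-column TSV
#' (`aa1 aa2 value`). A complete scale whose values all lie inside
#' `(-1, 1)` is marked as normalized; [normalize_dipeptide_scale()] maps an
#' arbitrary scale into that interval linearly.
#'
#' @param path Input TSV (optional header line accepted).
#' @return Named numeric vector of class `dipeptide_scale`; names are the
#'   concatenated pairs (`"AC"` etc.), attribute `normalized` a flag.
#' @export
read_dipeptide_scale <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("aa1", "aa2", "value"),
                          colClasses = c("character", "character", "numeric"))
  dipeptide_scale(stats::setNames(df$value, paste0(toupper(df$aa1),
                                                   toupper(df$aa2))))
}

#' @rdname read_dipeptide_scale
#' @param values Named numeric vector keyed by ordered pairs such as `"AC"`.
#' @export
dipeptide_scale <- function(values) {
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("dipeptide scale needs unique pair names", call. = FALSE)
  }
  bad <- !grepl("^[A-Z]{2}$", names(values))
  if (any(bad)) stop("malformed dipeptide keys: ",
                     paste(utils::head(names(values)[bad]), collapse = ", "),
                     call. = FALSE)
  structure(values,
            normalized = length(values) == 400 && all(abs(values) < 1),
            class = "dipeptide_scale")
}

#' @rdname read_dipeptide_scale
#' @param scale A `dipeptide_scale`.
#' @export
normalize_dipeptide_scale <- function(scale) {
  v <- unclass(scale)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    v[] <- 0
  } else {
    # linear min-max map into (-1, 1); shrink keeps the endpoints interior
    v <- (2 * (v - rng[1]) / (rng[2] - rng[1]) - 1) * (1 - 1e-9)
  }
  dipeptide_scale(v)
}

#' @rdname read_dipeptide_scale
#' @param path Output TSV path.
#' @export
write_dipeptide_scale <- function(scale, path) {
  nm <- names(scale)
  utils::write.table(
    data.frame(aa1 = substr(nm, 1, 1), aa2 = substr(nm, 2, 2),
               value = as.numeric(scale)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a labeled 20-mer fragment dataset
#'
#' One record per line: a 20-residue peptide, whitespace, and a label.
#' Accepted epitope tokens: `1`, `epitope`, `E`, `pos`; non-epitope tokens:
#' `0`, `non-epitope`, `non_epitope`, `N`, `neg` (case-insensitive).
#'
#' @param path Input file.
#' @return Tibble with columns `peptide` and `label` (factor with levels
#'   `"non-epitope"`, `"epitope"`). An empty file yields an empty tibble with
#'   a warning.
#' @export
read_fragments <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("fragment dataset is empty: ", path, call. = FALSE)
    return(tibble::tibble(peptide = character(0), label = fragment_label(character(0))))
  }
  tok <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(tok) < 2)) {
    stop("each fragment record needs a peptide and a label", call. = FALSE)
  }
  pep <- toupper(vapply(tok, `[`, character(1), 1))
  if (any(nchar(pep) != 20)) {
    stop("fragment peptides must be exactly 20 residues (offending line ",
         which(nchar(pep) != 20)[1], ")", call. = FALSE)
  }
  lab <- vapply(tok, `[`, character(1), 2)
  tibble::tibble(peptide = pep, label = parse_fragment_label(lab))
}

parse_fragment_label <- function(x) {
  x0 <- tolower(x)
  out <- ifelse(x0 %in% c("1", "epitope", "e", "pos"), "epitope",
         ifelse(x0 %in% c("0", "non-epitope", "non_epitope", "n", "neg"),
                "non-epitope", NA_character_))
  if (anyNA(out)) {
    stop("unknown label token(s): ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  fragment_label(out)
}

fragment_label <- function(x) factor(x, levels = c("non-epitope", "epitope"))

#' @rdname read_fragments
#' @param fragments Tibble with `peptide` and `label` columns.
#' @param path Output path.
#' @export
write_fragments <- function(fragments, path) {
  lab <- ifelse(as.character(fragments$label) == "epitope", "1", "0")
  writeLines(paste(fragments$peptide, lab), path)
  invisible(path)
}

#' Write and read per-residue propensity profiles
#'
#' Profiles are stored as a TSV with header `position  residue  propensity`,
#' positions 1-based, propensities printed at fixed decimal precision.
#'
#' @param profile Tibble with columns `position`, `residue`, `propensity`.
#' @param path Output path.
#' @param digits Decimal places for the propensity column (default 6).
#' @export
write_profile <- function(profile, path, digits = 6) {
  stopifnot(all(c("position", "residue", "propensity") %in% names(profile)))
  df <- data.frame(position = profile$position, residue = profile$residue,
                   propensity = formatC(profile$propensity, digits = digits,
                                        format = "f"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  class(out) <- c("epitope_profile", class(out))
  out
}

#' Save or restore a trained epitope model
#'
#' The model artifact bundles the SVM fit, its hyperparameters, the feature
#' manifest, the WOP fallback table, the dipeptide scale, and the similarity
#' library, so a saved model reproduces its predictions exactly on reload.
#'
#' @param model An `epitope_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "epitope_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "epitope_model"))
  model
}

#' Read a two-column residue/value override table
#'
#' Used for background-frequency and reference-area overrides.
#'
#' @param path TSV with residue one-letter code and numeric value.
#' @return Named numeric vector.
#' @export
read_residue_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("residue", "value"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$value, toupper(df$residue))
}
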