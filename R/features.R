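SLIDE_SIZES <- 5:18
SS_CLASSES <- c("H", "E", "C")

#' Canonical feature names and groups
#'
#' The full encoding of a 20-mer has exactly 198 named features in 11
#' groups: secondary structure (SS, 8), solvent accessibility (RA, 33),
#' dipeptide antigenicity (RP, 30), conservation (CS, 29), SS+RA (12),
#' SS+CS (6), SS+RP (6), RP+RA (30), RP+CS (28), SS+RA+RP (6), and
#' similarity (SIM, 10). The order is frozen -- group order as above, listing
#' order within a group, sliding-window features by window size ascending
#' with max before min -- because trained models refer to features by name
#' and selection manifests by position in this order.
#'
#' @return `feature_names()`: character vector of length 198.
#' @export
feature_names <- function() feature_groups()$name

#' @rdname feature_names
#' @return `feature_groups()`: tibble with columns `name` and `group`.
#' @export
feature_groups <- function() {
  slide <- function(prefix, suffix = NULL) {
    as.vector(vapply(SLIDE_SIZES, function(n) {
      paste0(c("max_", "min_"), prefix, "_slide_", n, suffix)
    }, character(2)))
  }
  cross_slide <- function(chan) {
    as.vector(vapply(SLIDE_SIZES, function(n) {
      paste0("avg_RAAP_", c("max_", "min_"), chan, "_slide_", n)
    }, character(2)))
  }
  per_class <- function(prefix) paste0(prefix, "_", SS_CLASSES)
  groups <- list(
    "SS" = c(per_class("content"), "entropy_SS", per_class("NumSeg"),
             "NumSeg_SS"),
    "RA" = c("content_Bd", "content_Ed", "entropy_RSA", "RSA_Bd", "RSA_Ed",
             slide("RSA")),
    "RP" = c("avg_RAAP", "sd_RAAP", slide("RAAP")),
    "CS" = c("avg_CON", slide("CON")),
    "SS+RA" = c(as.vector(t(outer(SS_CLASSES, c("Bd", "Ed"),
                                  function(a, b) paste0("Num_", a, "_", b)))),
                per_class("RSA"), per_class("RSA_max_segment")),
    "SS+CS" = c(per_class("CON"), per_class("CON_max_segment")),
    "SS+RP" = c(per_class("RAAP"), per_class("RAAP_max_segment")),
    "RP+RA" = c("RAAP_Bd", "RAAP_Ed", cross_slide("RSA")),
    "RP+CS" = cross_slide("CON"),
    "SS+RA+RP" = as.vector(t(outer(SS_CLASSES, c("Bd", "Ed"),
                                   function(a, b) paste0("RAAP_", a, "_", b)))),
    "SIM" = c(paste0("max_similarity_epitope_", 1:5),
              paste0("max_similarity_non_epitope_", 1:5))
  )
  tibble::tibble(
    name = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups))
  )
}

#' Count secondary-structure segments
#'
#' A segment is a maximal stretch of consecutive residues sharing the same
#' secondary-structure label. For the string
#' `"HHHCEEEEEEEECCCHHHCCCECC"` the counts are H = 2, E = 2, C = 4
#' (total 8). Defined for labels strings of any length.
#'
#' @param ss String (or character vector) over the labels `H`, `E`, `C`.
#' @return Named numeric vector `c(H=, E=, C=, total=)`.
#' @export
segment_counts <- function(ss) {
  chars <- if (length(ss) == 1 && nchar(ss[1]) > 1) strsplit(ss, "")[[1]] else ss
  if (length(chars) == 0 || any(!(chars %in% SS_CLASSES))) {
    stop("secondary-structure labels must be a non-empty string over H/E/C",
         call. = FALSE)
  }
  runs <- rle(chars)
  counts <- vapply(SS_CLASSES, function(cl) sum(runs$values == cl), numeric(1))
  c(counts, total = sum(counts))
}

#' Class contents and entropy of a label sequence
#'
#' Computes the fraction of positions in each class and the entropy
#' `sum_c p_c * ln(p_c)` with the convention `0 * ln(0) = 0`. The sum is
#' reported with this sign (values are at most 0); a single-class sequence
#' has entropy 0.
#'
#' @param labels Character vector (or single string) of class labels.
#' @param classes The class universe (order fixes the output order).
#' @return List with `content` (named fractions summing to 1) and `entropy`.
#' @export
class_content_entropy <- function(labels, classes) {
  chars <- if (length(labels) == 1 && nchar(labels[1]) > 1)
    strsplit(labels, "")[[1]] else labels
  if (length(chars) == 0) stop("empty label sequence", call. = FALSE)
  content <- vapply(classes, function(cl) mean(chars == cl), numeric(1))
  nz <- content > 0
  list(content = content, entropy = sum(content[nz] * log(content[nz])))
}

# Means of all contiguous windows of `n` values.
sliding_window_means <- function(values, n) {
  m <- length(values)
  if (n > m) stop("window size ", n, " exceeds sequence length ", m,
                  call. = FALSE)
  cs <- c(0, cumsum(values))
  (cs[(n + 1):(m + 1)] - cs[1:(m - n + 1)]) / n
}

#' Sliding-window extremum of a per-residue channel
#'
#' The maximum (or minimum) over all contiguous windows of size `n` of the
#' window mean. Used with window sizes 5..18 inside a 20-mer to locate
#' shorter sub-fragments with extreme accessibility, antigenicity, or
#' conservation.
#'
#' @param values Numeric channel.
#' @param n Window size (in production 5--18; any `1 <= n <= length` works).
#' @param which `"max"` or `"min"`.
#' @return The extremal window mean.
#' @export
sliding_stat <- function(values, n, which = c("max", "min")) {
  which <- match.arg(which)
  means <- sliding_window_means(values, n)
  if (which == "max") max(means) else min(means)
}

#' Dipeptide antigenicity values of a peptide
#'
#' `raap_scores()` returns the 19 overlapping-dipeptide scale values of a
#' 20-mer (n-1 values for an n-mer). `raap_residue_values()` maps those onto
#' residues: each residue's value is the mean of its incident dipeptide
#' scores (one at either terminus, two in the interior), giving the
#' per-residue antigenicity channel used by class- and exposure-restricted
#' averages.
#'
#' @param peptide Peptide string.
#' @param scale A [dipeptide_scale()].
#' @param strict Error on dipeptides missing from the scale (default);
#'   otherwise missing pairs score 0.
#' @return Numeric vector (length n-1 and n respectively).
#' @export
raap_scores <- function(peptide, scale, strict = TRUE) {
  n <- nchar(peptide)
  if (n < 2) stop("peptide too short for dipeptide scores", call. = FALSE)
  pairs <- substring(peptide, 1:(n - 1), 2:n)
  v <- unclass(scale)[pairs]
  if (anyNA(v)) {
    if (strict) {
      stop("dipeptide(s) missing from scale: ",
           paste(unique(pairs[is.na(v)]), collapse = ", "), call. = FALSE)
    }
    v[is.na(v)] <- 0
  }
  unname(v)
}

#' @rdname raap_scores
#' @export
raap_residue_values <- function(peptide, scale, strict = TRUE) {
  d <- raap_scores(peptide, scale, strict)
  n <- nchar(peptide)
  left <- c(NA, d)   # dipeptide ending at residue i
  right <- c(d, NA)  # dipeptide starting at residue i
  vapply(seq_len(n), function(i) {
    mean(c(left[i], right[i]), na.rm = TRUE)
  }, numeric(1))
}

# Positions of the leftmost longest run of class `cl`; integer(0) if absent.
longest_segment_positions <- function(chars, cl) {
  runs <- rle(chars)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sel <- which(runs$values == cl)
  if (length(sel) == 0) return(integer(0))
  best <- sel[which.max(runs$lengths[sel])]  # which.max -> leftmost tie win
  seq(starts[best], ends[best])
}

mean0 <- function(x) if (length(x) == 0) 0 else mean(x)

# The full 198-dimensional encoding of one annotated 20-mer.
features_one <- function(peptide, ss, rsa, con, scale, sim_scores) {
  ss_chars <- if (nchar(ss[1]) > 1) strsplit(ss, "")[[1]] else ss
  n <- nchar(peptide)
  stopifnot(length(ss_chars) == n, length(rsa) == n, length(con) == n)
  buried <- rsa < 0.25
  d <- raap_scores(peptide, scale)       # 19 dipeptide scores
  r <- raap_residue_values(peptide, scale)  # per-residue channel
  out <- numeric(0)

  # --- SS group
  ce <- class_content_entropy(ss_chars, SS_CLASSES)
  seg <- segment_counts(ss_chars)
  out <- c(out,
           stats::setNames(ce$content, paste0("content_", SS_CLASSES)),
           entropy_SS = ce$entropy,
           stats::setNames(seg[SS_CLASSES], paste0("NumSeg_", SS_CLASSES)),
           NumSeg_SS = unname(seg["total"]))

  # --- RA group
  exp_lab <- ifelse(buried, "Bd", "Ed")
  ce_r <- class_content_entropy(exp_lab, c("Bd", "Ed"))
  out <- c(out,
           content_Bd = unname(ce_r$content["Bd"]),
           content_Ed = unname(ce_r$content["Ed"]),
           entropy_RSA = ce_r$entropy,
           RSA_Bd = mean0(rsa[buried]), RSA_Ed = mean0(rsa[!buried]))
  for (w in SLIDE_SIZES) {
    out <- c(out,
             stats::setNames(c(sliding_stat(rsa, w, "max"),
                               sliding_stat(rsa, w, "min")),
                             paste0(c("max_", "min_"), "RSA_slide_", w)))
  }

  # --- RP group (window of w residues -> w-1 dipeptide scores)
  out <- c(out, avg_RAAP = mean(d), sd_RAAP = stats::sd(d))
  for (w in SLIDE_SIZES) {
    out <- c(out,
             stats::setNames(c(sliding_stat(d, w - 1, "max"),
                               sliding_stat(d, w - 1, "min")),
                             paste0(c("max_", "min_"), "RAAP_slide_", w)))
  }

  # --- CS group
  out <- c(out, avg_CON = mean(con))
  for (w in SLIDE_SIZES) {
    out <- c(out,
             stats::setNames(c(sliding_stat(con, w, "max"),
                               sliding_stat(con, w, "min")),
                             paste0(c("max_", "min_"), "CON_slide_", w)))
  }

  # --- SS+RA group
  for (cl in SS_CLASSES) {
    out <- c(out,
             stats::setNames(c(sum(ss_chars == cl & buried),
                               sum(ss_chars == cl & !buried)),
                             paste0("Num_", cl, c("_Bd", "_Ed"))))
  }
  for (cl in SS_CLASSES) {
    out <- c(out, stats::setNames(mean0(rsa[ss_chars == cl]),
                                  paste0("RSA_", cl)))
  }
  for (cl in SS_CLASSES) {
    out <- c(out, stats::setNames(mean0(rsa[longest_segment_positions(ss_chars, cl)]),
                                  paste0("RSA_max_segment_", cl)))
  }

  # --- SS+CS group
  for (cl in SS_CLASSES) {
    out <- c(out, stats::setNames(mean0(con[ss_chars == cl]),
                                  paste0("CON_", cl)))
  }
  for (cl in SS_CLASSES) {
    out <- c(out, stats::setNames(mean0(con[longest_segment_positions(ss_chars, cl)]),
                                  paste0("CON_max_segment_", cl)))
  }

  # --- SS+RP group
  for (cl in SS_CLASSES) {
    out <- c(out, stats::setNames(mean0(r[ss_chars == cl]),
                                  paste0("RAAP_", cl)))
  }
  for (cl in SS_CLASSES) {
    out <- c(out, stats::setNames(mean0(r[longest_segment_positions(ss_chars, cl)]),
                                  paste0("RAAP_max_segment_", cl)))
  }

  # --- RP+RA group: window located on the RSA channel, RAAP reported over
  # the window's w-1 interior dipeptides; leftmost window wins ties.
  out <- c(out, RAAP_Bd = mean0(r[buried]), RAAP_Ed = mean0(r[!buried]))
  dip_window_mean <- function(start, w) mean(d[start:(start + w - 2)])
  for (w in SLIDE_SIZES) {
    means_rsa <- sliding_window_means(rsa, w)
    out <- c(out, stats::setNames(
      c(dip_window_mean(which.max(means_rsa), w),
        dip_window_mean(which.min(means_rsa), w)),
      paste0("avg_RAAP_", c("max_", "min_"), "RSA_slide_", w)))
  }

  # --- RP+CS group
  for (w in SLIDE_SIZES) {
    means_con <- sliding_window_means(con, w)
    out <- c(out, stats::setNames(
      c(dip_window_mean(which.max(means_con), w),
        dip_window_mean(which.min(means_con), w)),
      paste0("avg_RAAP_", c("max_", "min_"), "CON_slide_", w)))
  }

  # --- SS+RA+RP group
  for (cl in SS_CLASSES) {
    out <- c(out,
             stats::setNames(c(mean0(r[ss_chars == cl & buried]),
                               mean0(r[ss_chars == cl & !buried])),
                             paste0("RAAP_", cl, c("_Bd", "_Ed"))))
  }

  # --- SIM group
  out <- c(out, sim_scores)
  out
}

#' Encode annotated 20-mers as feature vectors
#'
#' Turns each fragment (a 20-mer with aligned secondary-structure, RSA, and
#' conservation channels) into the full 198-dimensional named feature vector,
#' or into the subset named by a selection `manifest`. Class- or
#' exposure-restricted means over an empty selection (e.g., the strand mean
#' when no residue is a strand) are 0, as are the matching counts.
#'
#' Similarity features are computed against `library`. With
#' `exclude = "auto"` a fragment that carries `.lib_side` / `.lib_index`
#' columns (as produced when the library was built from the same dataset) is
#' never scored against its own library entry -- the hygiene required when
#' featurizing training folds.
#'
#' @param fragments Tibble with columns `peptide` (string), `ss` (20-label
#'   string), `rsa` and `conservation` (list columns of length-20 numerics);
#'   optional `label` and provenance columns are carried through.
#' @param library A [fragment_library()].
#' @param scale A [dipeptide_scale()].
#' @param manifest Optional character vector of feature names to keep (in
#'   manifest order).
#' @param exclude `"auto"` (default) or `"none"`.
#' @param mode Similarity counting semantics, see [fragment_similarity()].
#' @return Tibble with one row per fragment: any `label` column first, then
#'   the feature columns in canonical (or manifest) order. The manifest used
#'   is attached as attribute `manifest`.
#' @export
extract_features <- function(fragments, library, scale, manifest = NULL,
                             exclude = c("auto", "none"),
                             mode = c("distinct", "positional")) {
  exclude <- match.arg(exclude)
  mode <- match.arg(mode)
  stopifnot(inherits(library, "fragment_library"))
  needed <- c("peptide", "ss", "rsa", "conservation")
  missing <- setdiff(needed, names(fragments))
  if (length(missing) > 0) {
    stop("fragments lack channel column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  has_prov <- all(c(".lib_side", ".lib_index") %in% names(fragments)) &&
    exclude == "auto"
  rows <- lapply(seq_len(nrow(fragments)), function(i) {
    ex_e <- ex_ne <- NULL
    if (has_prov && !is.na(fragments$.lib_side[i])) {
      if (fragments$.lib_side[i] == "epitope") {
        ex_e <- fragments$.lib_index[i]
      } else {
        ex_ne <- fragments$.lib_index[i]
      }
    }
    sim <- topk_similarity(fragments$peptide[i], library, k = 5,
                           exclude_epitope = ex_e,
                           exclude_non_epitope = ex_ne, mode = mode)
    tryCatch(
      features_one(fragments$peptide[i], fragments$ss[i],
                   fragments$rsa[[i]], fragments$conservation[[i]],
                   scale, sim),
      error = function(e) {
        stop("fragment ", i, ": ", conditionMessage(e), call. = FALSE)
      })
  })
  mat <- do.call(rbind, rows)
  canon <- feature_names()
  if (!identical(colnames(mat), canon)) {
    mat <- mat[, canon, drop = FALSE]
  }
  if (!is.null(manifest)) {
    unknown <- setdiff(manifest, canon)
    if (length(unknown) > 0) {
      stop("manifest names unknown features: ",
           paste(utils::head(unknown), collapse = ", "), call. = FALSE)
    }
    mat <- mat[, manifest, drop = FALSE]
  }
  out <- tibble::as_tibble(mat)
  if ("label" %in% names(fragments)) {
    out <- dplyr::bind_cols(tibble::tibble(label = fragments$label), out)
  }
  attr(out, "manifest") <- manifest %||% canon
  out
}

#' Write a feature matrix as TSV
#'
#' Header holds feature names; a trailing `label` column is written last
#' when present.
#'
#' @param features Tibble from [extract_features()].
#' @param path Output path.
#' @export
write_feature_matrix <- function(features, path) {
  df <- as.data.frame(features)
  if ("label" %in% names(df)) {
    df <- df[, c(setdiff(names(df), "label"), "label")]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a feature-selection manifest (one feature name per line)
#'
#' @param path File path.
#' @export
read_manifest <- function(path) {
  nm <- trimws(readLines(path))
  nm[nzchar(nm)]
}

#' @rdname read_manifest
#' @param manifest Character vector of feature names.
#' @export
write_manifest <- function(manifest, path) {
  writeLines(manifest, path)
  invisible(path)
}
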