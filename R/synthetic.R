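# Residues favored in synthetic epitopes: hydrophilic/charged types that
# drive the planted dipeptide-scale and composition signal.
EPI_RESIDUES <- c("D", "E", "K", "N", "Q", "R", "S", "T")

#' Specification for the synthetic-data generator
#'
#' Defines the conditions under which every pipeline stage is exercised
#' without external data: fragment counts, chain sizes, and the planted
#' effect sizes that separate epitopes from non-epitopes. With all effect
#' sizes 0 and no motifs the two classes are exchangeable by construction.
#'
#' The planted signals are:
#' * `delta_raap`: additive shift of the toy dipeptide scale for pairs of
#'   epitope-favored residues; epitope fragments are simultaneously enriched
#'   in those residues, so class-conditional mean `avg_RAAP` separates.
#' * `delta_rsa`: upward shift of the mean relative solvent accessibility of
#'   epitope residues (epitopes are exposed).
#' * `delta_con`: extra concentration of epitope WOP rows on the native
#'   residue, raising their conservation score.
#' * `delta_ss`: shift of epitope secondary structure toward coil.
#' * `motifs`: peptides pasted into epitope fragments, driving the
#'   similarity features.
#'
#' @param seed Integer seed; every derived stream stays below `2^31`.
#' @param n_epitope,n_non_epitope Fragment counts (default 200 + 200).
#' @param n_chains Number of chains for chain-level fixtures.
#' @param chain_length Length range (inclusive) for generated chains.
#' @param delta_raap,delta_rsa,delta_con,delta_ss Effect sizes (see above).
#' @param motifs Character vector of epitope motifs (possibly empty).
#' @param epitope_length Length of each planted chain epitope segment.
#' @param zero_row_rate Fraction of WOP rows injected as all-zero to
#'   exercise the fallback path.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_epitope = 200, n_non_epitope = 200,
                         n_chains = 1, chain_length = c(60, 100),
                         delta_raap = 0.6, delta_rsa = 0.2, delta_con = 2,
                         delta_ss = 0.3,
                         motifs = c("KDRENQSTK", "QNSTKDREN"),
                         epitope_length = 15, zero_row_rate = 0.05) {
  if (length(motifs) > 0 && any(nchar(motifs) > 20)) {
    stop("motifs must fit inside a 20-mer", call. = FALSE)
  }
  if (length(chain_length) == 1) chain_length <- rep(chain_length, 2)
  structure(
    list(seed = as.integer(seed), n_epitope = n_epitope,
         n_non_epitope = n_non_epitope, n_chains = n_chains,
         chain_length = chain_length, delta_raap = delta_raap,
         delta_rsa = delta_rsa, delta_con = delta_con, delta_ss = delta_ss,
         motifs = motifs, epitope_length = epitope_length,
         zero_row_rate = zero_row_rate),
    class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
null_fixture_spec <- function(seed = 1, n_epitope = 200,
                              n_non_epitope = 200, ...) {
  fixture_spec(seed = seed, n_epitope = n_epitope,
               n_non_epitope = n_non_epitope,
               delta_raap = 0, delta_rsa = 0, delta_con = 0, delta_ss = 0,
               motifs = character(0), ...)
}

# Toy dipeptide scale: uniform noise plus delta_raap on favored-favored
# pairs, clipped into (-1, 1). Deterministic given spec$seed.
gen_scale <- function(spec) {
  set.seed(spec$seed)
  pairs <- as.vector(outer(aa_alphabet(), aa_alphabet(), paste0))
  v <- stats::runif(400, -0.3, 0.3)
  names(v) <- pairs
  favored <- outer(aa_alphabet() %in% EPI_RESIDUES,
                   aa_alphabet() %in% EPI_RESIDUES, "&")
  v[as.vector(favored)] <- v[as.vector(favored)] + spec$delta_raap
  dipeptide_scale(pmax(pmin(v, 0.99), -0.99))
}

# Per-residue sampling distribution for a class: a mixture of the favored
# set and the background. Effects off => both classes use the background.
residue_probs <- function(spec, epitope) {
  bg <- background_freqs()
  if (spec$delta_raap == 0) return(bg)
  s_prob <- if (epitope) 0.85 else 0.25
  p <- (1 - s_prob) * bg
  p[EPI_RESIDUES] <- p[EPI_RESIDUES] + s_prob / length(EPI_RESIDUES)
  p / sum(p)
}

sample_residues <- function(n, probs) {
  sample(aa_alphabet(), n, replace = TRUE, prob = probs)
}

# Markov secondary-structure labels with class-dependent composition.
gen_ss <- function(n, spec, epitope) {
  p0 <- c(H = 0.35, E = 0.25, C = 0.40)
  p <- if (epitope) {
    (1 - spec$delta_ss) * p0 + spec$delta_ss * c(H = 0.10, E = 0.10, C = 0.80)
  } else p0
  out <- character(n)
  out[1] <- sample(names(p), 1, prob = p)
  for (i in seq_len(n)[-1]) {
    out[i] <- if (stats::runif(1) < 0.75) out[i - 1] else
      sample(names(p), 1, prob = p)
  }
  out
}

# RSA coupled to the secondary structure (coil is more exposed) and shifted
# upward inside epitopes.
gen_rsa <- function(ss, spec, epitope) {
  mu <- 0.30 + 0.10 * (ss == "C") + if (epitope) spec$delta_rsa else 0
  mu <- pmin(0.92, pmax(0.05, mu))
  conc <- 8
  stats::rbeta(length(ss), mu * conc, (1 - mu) * conc)
}

# One WOP row (percentages): mass q on the native residue, the rest spread
# over a jittered background; all-zero with probability zero_row_rate.
gen_wop_rows <- function(residues, spec, epitope) {
  bg <- background_freqs()
  q <- 0.10 + if (epitope) 0.15 * spec$delta_con else 0
  q <- min(0.9, q)
  rows <- t(vapply(residues, function(res) {
    if (stats::runif(1) < spec$zero_row_rate) return(rep(0, 20))
    noise <- stats::rgamma(20, shape = 20, rate = 20)
    spread <- bg * noise
    spread <- spread / sum(spread) * (1 - q)
    p <- spread
    p[res] <- p[res] + q
    100 * p
  }, numeric(20)))
  rownames(rows) <- NULL
  rows
}

gen_peptide <- function(spec, epitope) {
  probs <- residue_probs(spec, epitope)
  pep <- sample_residues(20, probs)
  if (epitope && length(spec$motifs) > 0) {
    motif <- strsplit(sample(spec$motifs, 1), "")[[1]]
    off <- sample.int(20 - length(motif) + 1, 1)
    pep[off:(off + length(motif) - 1)] <- motif
  }
  paste(pep, collapse = "")
}

#' Generate a labeled synthetic fragment dataset with planted structure
#'
#' Draws epitope and non-epitope 20-mers with the class signals described in
#' [fixture_spec()], generates their per-residue channels jointly (so that
#' combined features carry real signal), computes the conservation channel
#' through the package's own WOP fallback machinery, and assembles the
#' similarity library from the same fragments (with provenance columns so
#' featurization can exclude self-matches under cross-validation).
#'
#' @param spec A [fixture_spec()].
#' @return List with `fragments` (tibble: `peptide`, `label`, `ss`, `rsa`,
#'   `conservation`, `.lib_side`, `.lib_index`), `scale`, `library`, and
#'   `fallback_table`.
#' @export
gen_fragment_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  scale <- gen_scale(spec)
  set.seed(spec$seed + 1L)
  n <- spec$n_epitope + spec$n_non_epitope
  is_epi <- rep(c(TRUE, FALSE), c(spec$n_epitope, spec$n_non_epitope))
  peptides <- vapply(is_epi, function(e) gen_peptide(spec, e), character(1))
  ss <- vapply(is_epi, function(e) paste(gen_ss(20, spec, e), collapse = ""),
               character(1))
  rsa <- lapply(seq_len(n), function(i) {
    gen_rsa(strsplit(ss[i], "")[[1]], spec, is_epi[i])
  })
  wops <- lapply(seq_len(n), function(i) {
    gen_wop_rows(strsplit(peptides[i], "")[[1]], spec, is_epi[i])
  })
  fallback <- wop_fallback_table(lapply(wops, as_wop_matrix),
                                 as.list(peptides))
  conservation <- lapply(seq_len(n), function(i) {
    m <- as_wop_matrix(wops[[i]])
    if (any(attr(m, "zero_row"))) {
      m <- apply_wop_fallback(m, peptides[i], fallback)
    }
    as.numeric(conservation_profile(m))
  })
  fragments <- tibble::tibble(
    peptide = peptides,
    label = fragment_label(ifelse(is_epi, "epitope", "non-epitope")),
    ss = ss, rsa = rsa, conservation = conservation,
    .lib_side = ifelse(is_epi, "epitope", "non-epitope"),
    .lib_index = c(seq_len(spec$n_epitope), seq_len(spec$n_non_epitope))
  )
  list(fragments = fragments, scale = scale,
       library = fragment_library(peptides[is_epi], peptides[!is_epi],
                                  id = "synthetic"),
       fallback_table = fallback)
}

#' Generate synthetic antigen chains with embedded epitope segments
#'
#' Each chain carries one or more epitope intervals (1-based, inclusive)
#' whose residues receive the planted composition, structure, accessibility,
#' and conservation signals; a motif is pasted inside each epitope when
#' motifs are configured. The WOP matrix includes all-zero rows at the
#' configured rate so the fallback path is exercised end to end.
#'
#' @param spec A [fixture_spec()].
#' @return List of `n_chains` elements, each a list with `chain` (tibble
#'   `id`, `sequence`), `ss_rsa` (tibble as from [read_ss_rsa()]), `wop`
#'   (a `wop_matrix`), `truth` (tibble `start`, `end`), and the shared
#'   `scale`.
#' @export
gen_chain_with_epitopes <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  scale <- gen_scale(spec)
  set.seed(spec$seed + 2L)
  lapply(seq_len(spec$n_chains), function(ci) {
    lens <- spec$chain_length[1]:spec$chain_length[2]
    L <- lens[sample.int(length(lens), 1)]
    if (L < 20) stop("chain length must be at least 20", call. = FALSE)
    elen <- min(spec$epitope_length, L - 2)
    start <- sample.int(L - elen + 1, 1)
    truth <- tibble::tibble(start = start, end = start + elen - 1)
    is_epi <- intervals_to_truth(truth, L)
    res <- character(L)
    res[!is_epi] <- sample_residues(sum(!is_epi), residue_probs(spec, FALSE))
    res[is_epi] <- sample_residues(sum(is_epi), residue_probs(spec, TRUE))
    if (length(spec$motifs) > 0) {
      motif <- strsplit(sample(spec$motifs, 1), "")[[1]]
      mlen <- min(length(motif), elen)
      res[start:(start + mlen - 1)] <- motif[seq_len(mlen)]
    }
    ss <- character(L)
    ss[!is_epi] <- gen_ss(sum(!is_epi), spec, FALSE)
    ss[is_epi] <- gen_ss(sum(is_epi), spec, TRUE)
    rsa <- numeric(L)
    rsa[!is_epi] <- gen_rsa(ss[!is_epi], spec, FALSE)
    rsa[is_epi] <- gen_rsa(ss[is_epi], spec, TRUE)
    wop <- matrix(0, L, 20)
    wop[!is_epi, ] <- gen_wop_rows(res[!is_epi], spec, FALSE)
    wop[is_epi, ] <- gen_wop_rows(res[is_epi], spec, TRUE)
    ss_rsa <- tibble::tibble(position = seq_len(L), ss = ss, value = rsa)
    attr(ss_rsa, "kind") <- "rsa"
    list(chain = tibble::tibble(id = paste0("synthetic_chain_", ci),
                                sequence = paste(res, collapse = "")),
         ss_rsa = ss_rsa, wop = as_wop_matrix(wop), truth = truth,
         scale = scale)
  })
}

#' Write a complete fixture set to disk
#'
#' Materializes everything the command-line pipeline consumes: a FASTA of
#' chains, per-chain SS/RSA and WOP TSVs, the dipeptide scale, the labeled
#' fragment dataset, and the per-chain truth intervals.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frag <- gen_fragment_dataset(spec)
  write_fragments(frag$fragments, file.path(dir, "fragments.txt"))
  write_dipeptide_scale(frag$scale, file.path(dir, "scale.tsv"))
  chains <- gen_chain_with_epitopes(spec)
  fasta <- unlist(lapply(chains, function(ch) {
    c(paste0(">", ch$chain$id), ch$chain$sequence)
  }))
  writeLines(fasta, file.path(dir, "chains.fasta"))
  for (ch in chains) {
    id <- ch$chain$id
    utils::write.table(
      data.frame(ss = ch$ss_rsa$ss,
                 rsa = formatC(ch$ss_rsa$value, digits = 6, format = "f")),
      file.path(dir, paste0(id, ".ssrsa.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = c("ss", "rsa"))
    write_wop(ch$wop, file.path(dir, paste0(id, ".wop.tsv")))
    utils::write.table(ch$truth, file.path(dir, paste0(id, ".truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
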