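# Independent brute-force oracles and small random-data builders used across
# the suite. These deliberately avoid the package's own helpers: similarity
# is recounted by explicit substring enumeration, features by straight-line
# loops.

random_peptide <- function(n = 20) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

random_ss <- function(n = 20) {
  paste(sample(c("H", "E", "C"), n, replace = TRUE), collapse = "")
}

# distinct-counting oracle: enumerate every distinct substring of `a` by
# explicit loops and test each for occurrence anywhere in `b`.
oracle_similarity_distinct <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  seen <- character(0)
  count <- 0L
  for (L in 1:na) {
    for (i in 1:(na - L + 1)) {
      sub <- substr(a, i, i + L - 1)
      if (sub %in% seen) next
      seen <- c(seen, sub)
      found <- FALSE
      if (L <= nb) {
        for (j in 1:(nb - L + 1)) {
          if (substr(b, j, j + L - 1) == sub) { found <- TRUE; break }
        }
      }
      if (found) count <- count + 1L
    }
  }
  count
}

# positional oracle: count every matching (i, j, L) triple.
oracle_similarity_positional <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  count <- 0L
  for (L in 1:min(na, nb)) {
    for (i in 1:(na - L + 1)) {
      for (j in 1:(nb - L + 1)) {
        if (substr(a, i, i + L - 1) == substr(b, j, j + L - 1)) {
          count <- count + 1L
        }
      }
    }
  }
  count
}

# uniform toy dipeptide scale over all 400 ordered pairs
toy_scale <- function(seed = 1, lo = -0.9, hi = 0.9) {
  set.seed(seed)
  pairs <- as.vector(outer(aa_alphabet(), aa_alphabet(), paste0))
  dipeptide_scale(stats::setNames(runif(400, lo, hi), pairs))
}

constant_scale <- function(v) {
  pairs <- as.vector(outer(aa_alphabet(), aa_alphabet(), paste0))
  dipeptide_scale(stats::setNames(rep(v, 400), pairs))
}

# random fully annotated fragments as a tibble
random_fragment_tbl <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    peptide = replicate(n, random_peptide()),
    ss = replicate(n, random_ss()),
    rsa = replicate(n, runif(20), simplify = FALSE),
    conservation = replicate(n, rnorm(20, 1, 1), simplify = FALSE)
  )
}

# a tiny annotated chain built directly (no files)
toy_annotated <- function(L, seed = 1) {
  set.seed(seed)
  res <- strsplit(random_peptide(L), "")[[1]]
  out <- tibble::tibble(
    position = seq_len(L), residue = res,
    ss = strsplit(random_ss(L), "")[[1]],
    rsa = runif(L), conservation = rnorm(L, 1))
  out$exposure <- exposure_call(out$rsa)
  attr(out, "id") <- "toy"
  attr(out, "sequence") <- paste(res, collapse = "")
  class(out) <- c("annotated_chain", class(out))
  out
}

tiny_library <- function(seed = 1, n_e = 4, n_ne = 4) {
  set.seed(seed)
  fragment_library(replicate(n_e, random_peptide()),
                   replicate(n_ne, random_peptide()))
}

# Straight-line reference for every non-similarity feature of one fragment.
# Written with explicit loops, independently of the package internals.
ref_features <- function(pep, ss, rsa, con, scale) {
  sv <- strsplit(ss, "")[[1]]
  out <- c()
  win_mean <- function(v, n, i) mean(v[i:(i + n - 1)])
  all_win_means <- function(v, n) {
    sapply(1:(length(v) - n + 1), function(i) win_mean(v, n, i))
  }
  # dipeptide scores and per-residue raap
  d <- numeric(19)
  for (i in 1:19) d[i] <- unclass(scale)[[substr(pep, i, i + 1)]]
  r <- numeric(20)
  r[1] <- d[1]; r[20] <- d[19]
  for (i in 2:19) r[i] <- (d[i - 1] + d[i]) / 2
  buried <- rsa < 0.25
  restricted_mean <- function(v, sel) if (sum(sel) == 0) 0 else mean(v[sel])
  # segments: manual scan
  seg_of <- function(cl) {
    runs <- list(); cur <- 0
    for (i in seq_along(sv)) {
      if (sv[i] == cl && (i == 1 || sv[i - 1] != cl)) cur <- cur + 1
    }
    cur
  }
  longest_pos <- function(cl) {
    best_len <- 0; best_start <- 0
    i <- 1
    while (i <= length(sv)) {
      if (sv[i] == cl) {
        j <- i
        while (j < length(sv) && sv[j + 1] == cl) j <- j + 1
        if (j - i + 1 > best_len) { best_len <- j - i + 1; best_start <- i }
        i <- j + 1
      } else i <- i + 1
    }
    if (best_len == 0) integer(0) else best_start:(best_start + best_len - 1)
  }
  ent <- function(p) { s <- 0; for (q in p) if (q > 0) s <- s + q * log(q); s }
  # SS
  for (cl in c("H", "E", "C")) out[paste0("content_", cl)] <- mean(sv == cl)
  out["entropy_SS"] <- ent(sapply(c("H", "E", "C"), function(cl) mean(sv == cl)))
  for (cl in c("H", "E", "C")) out[paste0("NumSeg_", cl)] <- seg_of(cl)
  out["NumSeg_SS"] <- seg_of("H") + seg_of("E") + seg_of("C")
  # RA
  out["content_Bd"] <- mean(buried); out["content_Ed"] <- mean(!buried)
  out["entropy_RSA"] <- ent(c(mean(buried), mean(!buried)))
  out["RSA_Bd"] <- restricted_mean(rsa, buried)
  out["RSA_Ed"] <- restricted_mean(rsa, !buried)
  for (n in 5:18) {
    out[paste0("max_RSA_slide_", n)] <- max(all_win_means(rsa, n))
    out[paste0("min_RSA_slide_", n)] <- min(all_win_means(rsa, n))
  }
  # RP
  out["avg_RAAP"] <- mean(d); out["sd_RAAP"] <- sd(d)
  for (n in 5:18) {
    out[paste0("max_RAAP_slide_", n)] <- max(all_win_means(d, n - 1))
    out[paste0("min_RAAP_slide_", n)] <- min(all_win_means(d, n - 1))
  }
  # CS
  out["avg_CON"] <- mean(con)
  for (n in 5:18) {
    out[paste0("max_CON_slide_", n)] <- max(all_win_means(con, n))
    out[paste0("min_CON_slide_", n)] <- min(all_win_means(con, n))
  }
  # SS+RA
  for (cl in c("H", "E", "C")) {
    out[paste0("Num_", cl, "_Bd")] <- sum(sv == cl & buried)
    out[paste0("Num_", cl, "_Ed")] <- sum(sv == cl & !buried)
  }
  for (cl in c("H", "E", "C")) {
    out[paste0("RSA_", cl)] <- restricted_mean(rsa, sv == cl)
  }
  for (cl in c("H", "E", "C")) {
    pos <- longest_pos(cl)
    out[paste0("RSA_max_segment_", cl)] <-
      if (length(pos) == 0) 0 else mean(rsa[pos])
  }
  # SS+CS
  for (cl in c("H", "E", "C")) {
    out[paste0("CON_", cl)] <- restricted_mean(con, sv == cl)
  }
  for (cl in c("H", "E", "C")) {
    pos <- longest_pos(cl)
    out[paste0("CON_max_segment_", cl)] <-
      if (length(pos) == 0) 0 else mean(con[pos])
  }
  # SS+RP
  for (cl in c("H", "E", "C")) {
    out[paste0("RAAP_", cl)] <- restricted_mean(r, sv == cl)
  }
  for (cl in c("H", "E", "C")) {
    pos <- longest_pos(cl)
    out[paste0("RAAP_max_segment_", cl)] <-
      if (length(pos) == 0) 0 else mean(r[pos])
  }
  # RP+RA
  out["RAAP_Bd"] <- restricted_mean(r, buried)
  out["RAAP_Ed"] <- restricted_mean(r, !buried)
  dip_mean_at <- function(start, n) mean(d[start:(start + n - 2)])
  for (n in 5:18) {
    wm <- all_win_means(rsa, n)
    out[paste0("avg_RAAP_max_RSA_slide_", n)] <- dip_mean_at(which.max(wm), n)
    out[paste0("avg_RAAP_min_RSA_slide_", n)] <- dip_mean_at(which.min(wm), n)
  }
  # RP+CS
  for (n in 5:18) {
    wm <- all_win_means(con, n)
    out[paste0("avg_RAAP_max_CON_slide_", n)] <- dip_mean_at(which.max(wm), n)
    out[paste0("avg_RAAP_min_CON_slide_", n)] <- dip_mean_at(which.min(wm), n)
  }
  # SS+RA+RP
  for (cl in c("H", "E", "C")) {
    out[paste0("RAAP_", cl, "_Bd")] <- restricted_mean(r, sv == cl & buried)
    out[paste0("RAAP_", cl, "_Ed")] <- restricted_mean(r, sv == cl & !buried)
  }
  out
}
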