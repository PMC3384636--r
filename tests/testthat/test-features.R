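test_that("segment counting reproduces the worked example and run structure", {
  s <- segment_counts("HHHCEEEEEEEECCCHHHCCCECC")
  expect_equal(unname(s["H"]), 2)
  expect_equal(unname(s["C"]), 4)
  expect_equal(unname(s["E"]), 2)
  expect_equal(unname(s["total"]), 8)
  expect_equal(unname(segment_counts(strrep("H", 20))),
               c(1, 0, 0, 1))
  expect_equal(unname(segment_counts(strrep("HE", 10))),
               c(10, 10, 0, 20))
  expect_error(segment_counts("HHQX"), "H/E/C")
})

test_that("class contents sum to 1 and entropy follows sum(p ln p)", {
  ce <- class_content_entropy(strrep("H", 20), c("H", "E", "C"))
  expect_equal(unname(ce$content), c(1, 0, 0))
  expect_equal(ce$entropy, 0)
  ce2 <- class_content_entropy(paste0(strrep("H", 10), strrep("C", 10)),
                               c("H", "E", "C"))
  expect_equal(ce2$entropy, 2 * 0.5 * log(0.5), tolerance = 1e-12)
  expect_lte(ce2$entropy, 0)  # printed sign convention
  set.seed(5)
  for (i in 1:10) {
    ce3 <- class_content_entropy(random_ss(20), c("H", "E", "C"))
    expect_equal(sum(ce3$content), 1)
  }
})

test_that("sliding statistics take extrema of window means", {
  expect_equal(sliding_stat(rep(0.5, 20), 7, "max"), 0.5)
  expect_equal(sliding_stat(1:20, 5, "max"), 18)  # mean of 16..20
  expect_equal(sliding_stat(1:20, 5, "min"), 3)   # mean of 1..5
  v <- runif(12)
  expect_equal(sliding_stat(v, 12, "max"), mean(v))
  expect_equal(sliding_stat(v, 12, "min"), mean(v))
  expect_error(sliding_stat(1:5, 6, "max"), "exceeds")
})

test_that("dipeptide statistics follow the 19 overlapping pairs", {
  sc <- constant_scale(0.4)
  pep <- random_peptide()
  expect_equal(raap_scores(pep, sc), rep(0.4, 19))
  expect_equal(raap_residue_values(pep, sc), rep(0.4, 20))
  # hand-checked toy: alternating peptide over a two-value scale
  sc2 <- toy_scale(seed = 8)
  pep2 <- strrep("AC", 10)
  d <- raap_scores(pep2, sc2)
  expect_equal(d, rep(c(unclass(sc2)[["AC"]], unclass(sc2)[["CA"]]),
                      10)[1:19])
  # affine property: shifting the scale shifts the mean, not the sd
  shifted <- dipeptide_scale(unclass(sc2) + 1)
  expect_equal(mean(raap_scores(pep, shifted)),
               mean(raap_scores(pep, sc2)) + 1, tolerance = 1e-12)
  expect_equal(sd(raap_scores(pep, shifted)), sd(raap_scores(pep, sc2)),
               tolerance = 1e-12)
  # strict mode errors on incomplete scales
  partial <- dipeptide_scale(c(AC = 0.5))
  expect_error(raap_scores("ACD", partial), "missing from scale")
})

test_that("the encoding has exactly 198 features with the fixed group sizes", {
  fg <- feature_groups()
  expect_equal(nrow(fg), 198)
  counts <- table(factor(fg$group, levels = unique(fg$group)))
  expect_equal(unname(as.integer(counts)),
               c(8, 33, 30, 29, 12, 6, 6, 30, 28, 6, 10))
  expect_false(anyDuplicated(fg$name) > 0)
  # frozen name manifest: models refer to features by these exact names
  frozen <- readLines(system.file("extdata", "feature_names.txt",
                                  package = "episvm"))
  expect_equal(feature_names(), frozen)
})

test_that("extract_features emits the canonical vector and honors manifests", {
  frag <- random_fragment_tbl(3, seed = 13)
  lib <- tiny_library(13)
  sc <- toy_scale(13)
  f <- extract_features(frag, lib, sc)
  expect_equal(names(f), feature_names())
  expect_equal(nrow(f), 3)
  # determinism: identical fragments give identical vectors
  f2 <- extract_features(frag[c(1, 1), ], lib, sc)
  expect_equal(as.numeric(f2[1, ]), as.numeric(f2[2, ]))
  # manifest subsetting preserves manifest order
  man <- c("avg_RAAP", "content_H", "max_similarity_epitope_1")
  fm <- extract_features(frag, lib, sc, manifest = man)
  expect_equal(names(fm), man)
  expect_equal(fm$avg_RAAP, f$avg_RAAP)
  expect_error(extract_features(frag, lib, sc, manifest = "no_such"),
               "unknown features")
})

test_that("feature vectors agree with a straight-line reference implementation", {
  lib <- tiny_library(99)
  sc <- toy_scale(99)
  frag <- random_fragment_tbl(20, seed = 99)
  f <- extract_features(frag, lib, sc)
  for (i in seq_len(nrow(frag))) {
    ref <- ref_features(frag$peptide[i], frag$ss[i], frag$rsa[[i]],
                        frag$conservation[[i]], sc)
    got <- as.numeric(f[i, names(ref)])
    expect_equal(got, unname(ref), tolerance = 1e-12)
  }
})

test_that("feature invariants hold on random fragments", {
  lib <- tiny_library(55)
  sc <- toy_scale(55)
  frag <- random_fragment_tbl(15, seed = 55)
  f <- extract_features(frag, lib, sc)
  expect_equal(f$content_H + f$content_E + f$content_C, rep(1, nrow(f)))
  expect_equal(f$content_Bd + f$content_Ed, rep(1, nrow(f)))
  expect_equal(f$NumSeg_SS, f$NumSeg_H + f$NumSeg_E + f$NumSeg_C)
  expect_true(all(f$NumSeg_SS >= 1 & f$NumSeg_SS <= 20))
  # window sizes that tile the 20-mer: the overall mean is then an average
  # of disjoint window means, so it must lie between the min and max
  # sliding-window means (for non-divisor sizes this can fail at the edges)
  for (n in c(5, 10)) {
    for (chan in c("RSA", "CON")) {
      avg <- if (chan == "RSA") sapply(frag$rsa, mean)
             else sapply(frag$conservation, mean)
      expect_true(all(f[[paste0("min_", chan, "_slide_", n)]] <= avg + 1e-12))
      expect_true(all(f[[paste0("max_", chan, "_slide_", n)]] >= avg - 1e-12))
    }
  }
})

test_that("empty-class and empty-exposure selections encode as zero", {
  frag <- tibble::tibble(
    peptide = random_peptide(),
    ss = paste0(strrep("H", 12), strrep("C", 8)),  # no strand
    rsa = list(rep(0.9, 20)),                      # nothing buried
    conservation = list(rep(1, 20)))
  f <- extract_features(frag, tiny_library(1), toy_scale(1))
  expect_equal(f$RSA_E, 0)
  expect_equal(f$CON_E, 0)
  expect_equal(f$RAAP_E, 0)
  expect_equal(f$RSA_max_segment_E, 0)
  expect_equal(f$Num_E_Bd + f$Num_E_Ed, 0)
  expect_equal(f$RSA_Bd, 0)
  expect_equal(f$RAAP_Bd, 0)
  expect_equal(f$content_Bd, 0)
})

test_that("longest-segment features average over the leftmost longest run", {
  # one helix run of 5 (positions 4..8), a later run of equal length ignored
  ss <- paste0("CCC", "HHHHH", "EEEE", "HHHHH", "CCC")
  rsa <- seq(0.01, 0.20, by = 0.01)
  frag <- tibble::tibble(peptide = random_peptide(), ss = ss,
                         rsa = list(rsa), conservation = list(1:20 / 10))
  f <- extract_features(frag, tiny_library(2), toy_scale(2))
  expect_equal(f$RSA_max_segment_H, mean(rsa[4:8]))
  expect_equal(f$CON_max_segment_H, mean((1:20 / 10)[4:8]))
  expect_equal(f$RSA_max_segment_E, mean(rsa[9:12]))
})

test_that("cross-channel window features use constant propagation correctly", {
  # constant RAAP scale: any selected window reports the constant
  frag <- random_fragment_tbl(1, seed = 77)
  f <- extract_features(frag, tiny_library(3), constant_scale(0.25))
  for (n in 5:18) {
    expect_equal(f[[paste0("avg_RAAP_max_RSA_slide_", n)]], 0.25)
    expect_equal(f[[paste0("avg_RAAP_min_CON_slide_", n)]], 0.25)
  }
})
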