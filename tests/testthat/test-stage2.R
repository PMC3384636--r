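test_that("window count and per-residue coverage laws hold for L in 20..60", {
  for (L in 20:60) {
    n_win <- L - 19
    ann <- toy_annotated(L, seed = L)
    w <- make_windows(ann)
    expect_equal(nrow(w), n_win)
    expect_equal(w$offset, seq_len(n_win))
    cov <- vapply(seq_len(L), function(i) length(covering_windows(i, L)),
                  numeric(1))
    expect_true(all(cov >= 1 & cov <= 20))
    interior <- seq_len(L) >= 20 & seq_len(L) <= L - 19
    expect_true(all(cov[interior] == 20))
    expect_equal(cov[1], 1)   # terminus
    expect_equal(cov[L], 1)
  }
})

test_that("window channels are sliced consistently", {
  ann <- toy_annotated(25, seed = 3)
  w <- make_windows(ann)
  expect_equal(nrow(w), 6)
  expect_equal(w$peptide[3], paste(ann$residue[3:22], collapse = ""))
  expect_equal(w$ss[6], paste(ann$ss[6:25], collapse = ""))
  expect_equal(w$rsa[[2]], ann$rsa[2:21])
  expect_equal(w$conservation[[4]], ann$conservation[4:23])
  expect_error(make_windows(toy_annotated(19)), "shorter than 20")
})

test_that("aggregation schemes match their definitions", {
  expect_equal(aggregate_scores(c(0.9, 0.5), "max"), 0.9)
  expect_equal(aggregate_scores(c(0.9, 0.5), "median"), 0.7)
  expect_equal(aggregate_scores(c(0.1, 0.45, 0.55, 0.95), "distance", k = 2),
               mean(c(0.1, 0.95)))
  expect_equal(aggregate_scores(c(0.2, 0.6, 0.7), "average"),
               mean(c(0.2, 0.6, 0.7)))
  # fewer than k scores: use all of them
  expect_equal(aggregate_scores(c(0.8, 0.3), "distance", k = 16),
               mean(c(0.8, 0.3)))
  # ties in |s - 0.5| include by ascending offset
  expect_equal(aggregate_scores(c(0.6, 0.4, 0.9), "distance", k = 2,
                                offsets = 1:3), mean(c(0.9, 0.6)))
  expect_error(aggregate_scores(numeric(0), "max"), "empty")
  expect_error(aggregate_scores(0.5, "distance", k = 0), "k must lie")
  expect_error(aggregate_scores(0.5, "distance", k = 21), "k must lie")
})

test_that("the distance scheme with k = 20 equals the average scheme", {
  set.seed(77)
  for (i in 1:100) {
    m <- sample(1:20, 1)
    s <- runif(m)
    expect_identical(aggregate_scores(s, "distance", k = 20),
                     aggregate_scores(s, "average"))
  }
})

test_that("max scheme dominates the average scheme residue-wise", {
  set.seed(78)
  for (i in 1:50) {
    s <- runif(sample(1:20, 1))
    expect_gte(aggregate_scores(s, "max"), aggregate_scores(s, "average"))
    d <- aggregate_scores(s, "distance", k = 7)
    expect_gte(d, min(s)); expect_lte(d, max(s))
  }
})

# model fixture shared by the profile tests
chain_model <- function(seed = 91) {
  d <- random_fragment_tbl(20, seed = seed)
  d$label <- factor(rep(c("epitope", "non-epitope"), 10),
                    levels = c("non-epitope", "epitope"))
  lib <- tiny_library(seed)
  sc <- toy_scale(seed)
  svm_train(extract_features(d, lib, sc), seed = 1, library = lib, scale = sc)
}

test_that("whole-chain prediction yields a bounded per-residue profile", {
  m <- chain_model()
  ann <- toy_annotated(32, seed = 5)
  prof <- predict_chain(ann, m, scheme = "distance", k = 16)
  expect_s3_class(prof, "epitope_profile")
  expect_equal(nrow(prof), 32)
  expect_equal(prof$residue, ann$residue)
  # aggregation bounds: within the range of the window scores
  w <- make_windows(ann)
  scores <- predict_fragments(
    m, extract_features(w, m$library, m$scale, exclude = "none"))$score
  expect_true(all(prof$propensity >= min(scores) - 1e-12 &
                  prof$propensity <= max(scores) + 1e-12))
  # max scheme dominates average scheme per residue
  p_max <- predict_chain(ann, m, scheme = "max")
  p_avg <- predict_chain(ann, m, scheme = "average")
  expect_true(all(p_max$propensity >= p_avg$propensity - 1e-12))
  # interior residues: distance k = 20 identical to average
  p_d20 <- predict_chain(ann, m, scheme = "distance", k = 20)
  interior <- prof$position >= 20 & prof$position <= nrow(prof) - 19
  expect_identical(p_d20$propensity[interior], p_avg$propensity[interior])
})

test_that("reversing a chain with reversed channels reverses the profile", {
  m <- chain_model(93)
  # a palindromically annotated chain is invariant under reversal, so its
  # profile must be mirror-symmetric
  pal <- toy_annotated(28, seed = 6)
  half <- 1:14
  pal$residue[29 - half] <- pal$residue[half]
  pal$ss[29 - half] <- pal$ss[half]
  pal$rsa[29 - half] <- pal$rsa[half]
  pal$conservation[29 - half] <- pal$conservation[half]
  pal_rev <- pal[rev(seq_len(28)), ]
  pal_rev$position <- 1:28
  class(pal_rev) <- class(pal)
  p1 <- predict_chain(pal, m, scheme = "average")
  p2 <- predict_chain(pal_rev, m, scheme = "average")
  # reversing a palindromic chain reproduces the same annotated chain, so
  # the profile is reproduced exactly; full mirror symmetry of the profile
  # itself is not implied because dipeptide features are directional
  expect_equal(p2$propensity, p1$propensity, tolerance = 1e-10)
})

test_that("a constant scorer propagates to a flat profile under every scheme", {
  m <- chain_model(95)
  ann <- toy_annotated(26, seed = 8)
  # force identical windows: constant channels and a homopolymer chain
  ann$residue <- rep("A", 26)
  ann$ss <- rep("C", 26)
  ann$rsa <- rep(0.5, 26)
  ann$conservation <- rep(1, 26)
  ann$exposure <- exposure_call(ann$rsa)
  for (scheme in c("max", "average", "median", "distance")) {
    prof <- predict_chain(ann, m, scheme = scheme)
    expect_equal(diff(range(prof$propensity)), 0)
  }
})

test_that("chain prediction requires the model's bundled artifacts", {
  d <- random_fragment_tbl(8, seed = 97)
  d$label <- factor(rep(c("epitope", "non-epitope"), 4),
                    levels = c("non-epitope", "epitope"))
  feats <- extract_features(d, tiny_library(1), toy_scale(1))
  bare <- svm_train(feats, seed = 1)  # no library/scale bundled
  expect_error(predict_chain(toy_annotated(22), bare), "bundle")
})
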