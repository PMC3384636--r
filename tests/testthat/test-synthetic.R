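small_spec <- function(seed = 5, ...) {
  fixture_spec(seed = seed, n_epitope = 40, n_non_epitope = 40,
               chain_length = c(60, 60), ...)
}

test_that("fixture generation is bit-reproducible under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixtures(small_spec(seed = 9, n_chains = 2), d1)
  write_fixtures(small_spec(seed = 9, n_chains = 2), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_fixtures(small_spec(seed = 10, n_chains = 2), d3)
  expect_false(identical(readLines(file.path(d1, "fragments.txt")),
                         readLines(file.path(d3, "fragments.txt"))))
})

test_that("fragment counts, lengths, and labels follow the specification", {
  d <- gen_fragment_dataset(small_spec())
  expect_equal(nrow(d$fragments), 80)
  expect_equal(sum(d$fragments$label == "epitope"), 40)
  expect_true(all(nchar(d$fragments$peptide) == 20))
  expect_true(all(nchar(d$fragments$ss) == 20))
  expect_true(all(vapply(d$fragments$rsa, length, numeric(1)) == 20))
  expect_equal(length(d$library$epitopes), 40)
  expect_error(fixture_spec(motifs = strrep("A", 25)), "fit inside")
})

test_that("planted effects shift the class-conditional feature distributions", {
  spec <- small_spec(seed = 12)
  d <- gen_fragment_dataset(spec)
  is_epi <- d$fragments$label == "epitope"
  # dipeptide signal: mean avg_RAAP separates by at least delta_raap / 2
  avg_raap <- vapply(d$fragments$peptide,
                     function(p) mean(raap_scores(p, d$scale)), numeric(1))
  expect_gte(mean(avg_raap[is_epi]) - mean(avg_raap[!is_epi]),
             spec$delta_raap / 2)
  # conservation signal: epitope residues are more conserved
  con_mean <- vapply(d$fragments$conservation, mean, numeric(1))
  expect_gt(mean(con_mean[is_epi]), mean(con_mean[!is_epi]))
  # exposure signal
  rsa_mean <- vapply(d$fragments$rsa, mean, numeric(1))
  expect_gt(mean(rsa_mean[is_epi]), mean(rsa_mean[!is_epi]))
})

test_that("null effects make the classes exchangeable in their channels", {
  d <- gen_fragment_dataset(null_fixture_spec(seed = 13, n_epitope = 60,
                                              n_non_epitope = 60))
  is_epi <- d$fragments$label == "epitope"
  avg_raap <- vapply(d$fragments$peptide,
                     function(p) mean(raap_scores(p, d$scale)), numeric(1))
  # class difference is pure noise: bounded by a few standard errors
  se <- sd(avg_raap) * sqrt(2 / 60)
  expect_lt(abs(mean(avg_raap[is_epi]) - mean(avg_raap[!is_epi])), 4 * se)
})

test_that("zero WOP rows are injected at the configured rate and handled", {
  spec <- fixture_spec(seed = 17, n_epitope = 100, n_non_epitope = 100,
                       zero_row_rate = 0.05)
  chains <- gen_chain_with_epitopes(
    fixture_spec(seed = 17, n_chains = 10, chain_length = c(80, 80),
                 zero_row_rate = 0.05))
  rates <- vapply(chains, function(ch) mean(attr(ch$wop, "zero_row")),
                  numeric(1))
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.09)
  # conservation channel of generated fragments is always finite
  d <- gen_fragment_dataset(spec)
  expect_true(all(is.finite(unlist(d$fragments$conservation))))
})

test_that("generated chains carry in-range truth intervals and window counts", {
  chains <- gen_chain_with_epitopes(small_spec(seed = 19, n_chains = 3))
  for (ch in chains) {
    L <- nchar(ch$chain$sequence)
    expect_equal(L, 60)
    expect_equal(nrow(ch$ss_rsa), L)
    expect_equal(nrow(ch$wop), L)
    expect_gte(ch$truth$start, 1)
    expect_lte(ch$truth$end, L)
    expect_equal(ch$truth$end - ch$truth$start + 1, 15)
    ann <- annotate_chain(ch$chain, ch$ss_rsa, ch$wop)
    expect_equal(nrow(make_windows(ann)), L - 19)  # 41 windows at L = 60
  }
})

test_that("conservation is elevated inside epitope segments when planted", {
  chains <- gen_chain_with_epitopes(
    fixture_spec(seed = 23, n_chains = 6, chain_length = c(80, 120),
                 delta_con = 2))
  diffs <- vapply(chains, function(ch) {
    ann <- suppressMessages(annotate_chain(ch$chain, ch$ss_rsa, ch$wop))
    truth <- intervals_to_truth(ch$truth, nrow(ann))
    mean(ann$conservation[truth]) - mean(ann$conservation[!truth])
  }, numeric(1))
  expect_gt(mean(diffs), 0.3)
})

test_that("fixture files parse back through the io layer", {
  dir <- withr::local_tempdir()
  write_fixtures(small_spec(seed = 29), dir)
  frags <- read_fragments(file.path(dir, "fragments.txt"))
  expect_equal(nrow(frags), 80)
  sc <- read_dipeptide_scale(file.path(dir, "scale.tsv"))
  expect_equal(length(sc), 400)
  chains <- read_fasta(file.path(dir, "chains.fasta"))
  id <- chains$id[1]
  ssr <- read_ss_rsa(file.path(dir, paste0(id, ".ssrsa.tsv")),
                     chain = chains$sequence[1])
  expect_equal(attr(ssr, "kind"), "rsa")
  wop <- read_wop(file.path(dir, paste0(id, ".wop.tsv")),
                  chain = chains$sequence[1])
  ann <- suppressMessages(
    annotate_chain(chains[1, ], ssr, wop))
  expect_equal(nrow(ann), nchar(chains$sequence[1]))
})
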