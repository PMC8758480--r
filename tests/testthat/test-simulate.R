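test_that("identical seeds give byte-identical outputs", {
  a <- small_sim(seed = 31, dropout = 0.05, subst_rate = 0.02)
  b <- small_sim(seed = 31, dropout = 0.05, subst_rate = 0.02)
  for (f in c("maf", "bed", "truth", "target_ids")) {
    expect_identical(readLines(a$sim$paths[[f]]),
                     readLines(b$sim$paths[[f]]), label = f)
  }
  c2 <- small_sim(seed = 32, dropout = 0.05, subst_rate = 0.02)
  expect_false(identical(readLines(a$sim$paths$maf),
                         readLines(c2$sim$paths$maf)))
})

test_that("zero loss and zero dropout conserve every site everywhere", {
  x <- small_sim(seed = 33, lambda_bg = 0, lambda_target = 0)
  expect_true(all(x$sim$truth$status == "conserved"))
  idx <- read_maf(x$sim$paths$maf, ref_species = "hg38")
  ex <- read_bed12(x$sim$paths$bed)
  cons <- run_conservation(ex, idx, verbose = FALSE)
  expect_true(all(cons$transcripts$complete))
})

test_that("an effectively infinite branch loses all its sites, others none", {
  cfg <- sim_config(seed = 34, species = c("close", "doomed"),
                    distances = c(0.001, 2000),
                    n_target = 5, n_background = 20,
                    lambda_bg = 0.01, lambda_target = 0.01,
                    dropout = 0, subst_rate = 0)
  tr <- simulate_truth(cfg)
  doomed <- tr$truth[tr$truth$species == "doomed", ]
  close <- tr$truth[tr$truth$species == "close", ]
  expect_true(all(doomed$status == "lost"))
  expect_gt(mean(close$status == "conserved"), 0.99)
})

test_that("site survival follows the per-branch exponential decay", {
  # pooled over three replicates so the 99% band check is stable
  n <- 0; k <- 0
  for (s in 1:3) {
    cfg <- sim_config(seed = 34 + s, species = "sp1", distances = 1.0,
                      n_target = 1, n_background = 120, kmax = 8,
                      lambda_bg = 0.5, lambda_target = 0.5,
                      dropout = 0, subst_rate = 0)
    tr <- simulate_truth(cfg)
    n <- n + nrow(tr$sites)
    k <- k + sum(tr$truth$status == "conserved")
  }
  expect_gt(n, 1000)
  p <- exp(-0.5)
  band <- 2.576 * sqrt(n * p * (1 - p))
  expect_lt(abs(k - n * p), band + 1e-9)
})

test_that("expected_rates follows the closed-form survival arithmetic", {
  # two exons always: 2 sites; p = exp(-lambda d)
  cfg <- sim_config(seed = 36, species = "sp1",
                    distances = -log(0.8) / 0.25,   # p = 0.8 exactly
                    n_target = 1, n_background = 1, kmax = 2,
                    lambda_bg = 0.25, lambda_target = 0.5)
  comp <- expected_rates(cfg, "complete")
  expect_equal(comp$expected_rate, 0.8^2, tolerance = 1e-12)
  pres <- expected_rates(cfg, "present")
  expect_equal(pres$expected_rate, 1 - 0.2^2, tolerance = 1e-12)
  # degenerate rates
  cfg0 <- sim_config(seed = 36, species = "sp1", distances = 1,
                     n_target = 1, n_background = 1, kmax = 2,
                     lambda_bg = 0, lambda_target = 0)
  expect_equal(expected_rates(cfg0, "complete")$expected_rate, 1)
  cfg1 <- sim_config(seed = 36, species = "sp1", distances = 1e9,
                     n_target = 1, n_background = 1, kmax = 2,
                     lambda_bg = 1, lambda_target = 1)
  expect_equal(expected_rates(cfg1, "present")$expected_rate, 0)
  # marginalization over exon counts: uniform mixture of per-k terms
  cfg3 <- sim_config(seed = 36, species = "sp1",
                     distances = -log(0.8) / 0.25,
                     n_target = 1, n_background = 1, kmax = 4,
                     lambda_bg = 0.25, lambda_target = 0.25)
  expect_equal(expected_rates(cfg3, "complete")$expected_rate,
               mean(0.8^c(2, 4, 6)), tolerance = 1e-12)
})

test_that("dropout is the only source of not_alignable", {
  x0 <- small_sim(seed = 37, dropout = 0)
  expect_false(any(x0$sim$truth$status == "not_alignable"))
  x1 <- small_sim(seed = 37, dropout = 0.3)
  expect_true(any(x1$sim$truth$status == "not_alignable"))
  # dropped species rows are absent from the emitted blocks
  idx <- read_maf(x1$sim$paths$maf, ref_species = "hg38")
  na_truth <- x1$sim$truth[x1$sim$truth$status == "not_alignable", ][1, ]
  bid <- maf_query(idx, na_truth$chrom, na_truth$boundary_pos,
                   na_truth$boundary_pos + 2L)
  b <- maf_block(idx, bid[1])
  expect_false(na_truth$species %in% b$species)
})

test_that("whole-locus blocks carry several sites and classify exactly", {
  cfg <- sim_config(seed = 38, species = c("spA", "spB"),
                    distances = c(0.3, 0.9), n_target = 5,
                    n_background = 15, kmax = 5, dropout = 0.05,
                    subst_rate = 0.01, block_style = "per_transcript")
  dir <- tempfile("pt")
  sim <- simulate_ss_evolution(cfg, dir)
  idx <- read_maf(sim$paths$maf, ref_species = "hg38")
  expect_equal(nrow(idx$blocks), 20L)   # one block per transcript
  ex <- read_bed12(sim$paths$bed)
  cons <- run_conservation(ex, idx, verbose = FALSE)
  m <- dplyr::inner_join(
    cons$calls, sim$truth,
    by = c("transcript_id", "site_kind", "intron_index", "species"),
    suffix = c(".call", ".truth"))
  expect_equal(nrow(m), nrow(cons$calls))
  expect_equal(mean(m$status.call == m$status.truth), 1)
})

test_that("a tree without the reference leaf is rejected", {
  expect_error(
    sim_config(seed = 39, tree = "(a:1,b:1);", ref_species = "hg38"),
    "hg38")
})
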