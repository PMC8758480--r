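test_that("balanced 2x2 tables give p = 1 and perfect separation tiny p", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 1)
  p_sep <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(p_sep, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("implementation matches exhaustive enumeration and fisher.test", {
  set.seed(101)
  for (i in 1:60) {
    repeat {
      tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
    }
    p <- fisher_exact_2x2(tab)
    p_or <- oracle_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p, p_or, tolerance = 1e-11)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-6)
  }
  expect_equal(fisher_exact_2x2(matrix(c(3, 7, 50, 50), 2, byrow = TRUE)),
               oracle_fisher(3, 7, 50, 50), tolerance = 1e-11)
})

test_that("degenerate tables are rejected", {
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero margin")
  expect_error(fisher_exact_2x2(matrix(c(1, 0, 3, 0), 2)), "zero margin")
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("ladder trees reproduce the requested patristic distances", {
  d <- c(0.25, 0.5, 1, 2)
  nwk <- ladder_tree(paste0("sp", 1:4), d, ref_species = "hg38")
  got <- species_distances(nwk, "hg38")
  expect_equal(got$distance, d, tolerance = 1e-9)
  expect_equal(got$species, paste0("sp", 1:4))
  expect_error(species_distances(nwk, "notthere"), "notthere")
})

toy_tc <- function() {
  # 10 transcripts, 2 species; 7 complete in near species, 2 in far
  tibble::tibble(
    transcript_id = rep(sprintf("t%02d", 1:10), 2),
    species = rep(c("near", "far"), each = 10),
    n_sites = 4L,
    n_conserved = c(rep(4L, 7), 2L, 1L, 0L, rep(4L, 2), rep(1L, 7), 0L),
    n_alignable = 4L
  ) |>
    dplyr::mutate(fraction_conserved = n_conserved / n_sites,
                  present = n_conserved >= 1L,
                  intermediate_0.5 = fraction_conserved >= 0.5,
                  complete = n_conserved == n_sites)
}

test_that("conservation_rate counts level attainment", {
  tc <- toy_tc()
  r <- conservation_rate(tc, sprintf("t%02d", 1:10), "near", "complete")
  expect_equal(r$k, 7L)
  expect_equal(r$n, 10L)
  expect_equal(r$rate, 0.7)
  expect_error(conservation_rate(tc, character(0), "near", "complete"),
               "empty")
  expect_error(conservation_rate(tc, c("t01", "ghost"), "near", "complete"),
               "ghost")
  expect_error(conservation_rate(tc, "t01", "near", "supreme"), "level")
})

test_that("conditioned mode drops poorly alignable transcripts", {
  tc <- toy_tc()
  tc$n_alignable[tc$transcript_id == "t01"] <- 1L
  r <- conservation_rate(tc, sprintf("t%02d", 1:10), "near", "complete",
                         mode = "conditioned")
  expect_equal(r$n, 9L)
  expect_equal(r$k, 6L)
})

test_that("compare_sets orders species by distance and flags raw p", {
  tc <- toy_tc()
  nwk <- ladder_tree(c("far", "near"), c(1.5, 0.1), ref_species = "hg38")
  cmp <- compare_sets(tc, sprintf("t%02d", 1:5), sprintf("t%02d", 6:10),
                      nwk, "hg38")
  tt <- tidy(cmp)
  expect_equal(levels(tt$species), c("near", "far"))
  expect_true(all(tt$p > 0 & tt$p <= 1))
  expect_true(all(tt$significant == (tt$p < 0.05)))
  expect_true(all(c("p_adj", "distance") %in% names(tt)))
  # rates are monotone in level stringency for every species and set
  rr <- cmp$rates |>
    dplyr::group_by(species, set) |>
    dplyr::summarise(mono = all(diff(rate[order(match(level,
      c("present", "intermediate_0.5", "complete")))]) <= 1e-12),
      .groups = "drop")
  expect_true(all(rr$mono))
})

test_that("overlapping sets are pruned from the background with a warning", {
  tc <- toy_tc()
  nwk <- ladder_tree(c("far", "near"), c(1.5, 0.1), ref_species = "hg38")
  expect_warning(
    cmp <- compare_sets(tc, sprintf("t%02d", 1:5), sprintf("t%02d", 1:10),
                        nwk, "hg38"),
    "removed from background")
  expect_equal(unique(tidy(cmp)$n_bg), 5L)
  expect_error(
    suppressWarnings(compare_sets(tc, sprintf("t%02d", 1:10),
                                  sprintf("t%02d", 1:10), nwk, "hg38")),
    "background set empty")
})

test_that("species absent from the tree abort the comparison", {
  tc <- toy_tc()
  nwk <- ladder_tree("near", 0.1, ref_species = "hg38")
  expect_error(compare_sets(tc, sprintf("t%02d", 1:5),
                            sprintf("t%02d", 6:10), nwk, "hg38"),
               "missing from tree")
})

test_that("tidy, glance and autoplot expose the comparison", {
  tc <- toy_tc()
  nwk <- ladder_tree(c("far", "near"), c(1.5, 0.1), ref_species = "hg38")
  cmp <- compare_sets(tc, sprintf("t%02d", 1:5), sprintf("t%02d", 6:10),
                      nwk, "hg38")
  g <- glance(cmp)
  expect_equal(g$n_species, 2L)
  expect_true(all(c("n_sig_complete", "n_sig_present") %in% names(g)))
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
  expect_output(print(cmp), "ss_comparison")
})
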