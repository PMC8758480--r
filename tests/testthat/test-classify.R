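site_row <- function(kind = "donor", strand = "+") {
  tibble::tibble(transcript_id = "t", site_kind = kind, chrom = "chr1",
                 boundary_pos = 100L, strand = strand, intron_index = 1L,
                 expected_dinucleotide = ifelse(kind == "donor", "GT", "AG"))
}
mapped_row <- function(context, offset, species = "mm10",
                       aligned = TRUE) {
  tibble::tibble(species = species, aligned = aligned,
                 target_char = substr(context, offset + 1, offset + 1),
                 target_context = context, context_offset = offset,
                 column = offset + 1L)
}

test_that("a donor GT at the mapped boundary is conserved with shift 0", {
  call <- classify_site(site_row(), mapped_row("AAGTAAG", 2L))
  expect_equal(call$status, "conserved")
  expect_equal(call$shift, 0L)
})

test_that("missing species rows and empty contexts are not alignable", {
  gone <- mapped_row("", NA_integer_, aligned = FALSE)
  expect_equal(classify_site(site_row(), gone)$status, "not_alignable")
  empty <- mapped_row("", 0L)
  expect_equal(classify_site(site_row(), empty)$status, "not_alignable")
})

test_that("no allowed dinucleotide within the window means lost", {
  call <- classify_site(site_row(), mapped_row("AGCCA", 1L), max_shift = 0L)
  expect_equal(call$status, "lost")
  # AG is present but this is a donor site: kinds are not interchangeable
  expect_equal(classify_site(site_row("acceptor"),
                             mapped_row("AGCCA", 0L))$status, "conserved")
})

test_that("shifted dinucleotides are found at the offset the oracle finds", {
  # GT only at +3 relative to the boundary
  ctx <- "AAACCCGTAAAA"
  call <- classify_site(site_row(), mapped_row(ctx, 3L), max_shift = 6L)
  expect_equal(call$status, "conserved")
  expect_equal(call$shift, oracle_scan(ctx, 3L, "GT", 6L))
  expect_equal(call$shift, 3L)
  # outside the window it stays lost
  expect_equal(classify_site(site_row(), mapped_row(ctx, 3L),
                             max_shift = 2L)$status, "lost")
})

test_that("shift search matches the brute-force oracle on random contexts", {
  set.seed(11)
  for (i in 1:200) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
                 collapse = "")
    off <- sample(0:13, 1)
    s <- sample(0:6, 1)
    call <- classify_site(site_row(), mapped_row(ctx, off), max_shift = s)
    exp_shift <- oracle_scan(ctx, off, "GT", s)
    if (is.na(exp_shift)) {
      expect_equal(call$status, "lost")
    } else {
      expect_equal(call$shift, exp_shift)
    }
  }
})

test_that("equidistant matches resolve to the negative shift", {
  # GT at -2 and +2 around offset 4: ..GT..GT..
  ctx <- "AAGTAAGTAA"
  call <- classify_site(site_row(), mapped_row(ctx, 4L), max_shift = 3L)
  expect_equal(call$shift, -2L)
})

test_that("minus-strand sites are matched in reference orientation", {
  # donor on '-': reference shows the reverse complement AC
  call <- classify_site(site_row(strand = "-"), mapped_row("GGACGG", 2L))
  expect_equal(call$status, "conserved")
  call2 <- classify_site(site_row(strand = "-"), mapped_row("GGGTGG", 2L))
  expect_equal(call2$status, "lost")
})

test_that("transcript roll-up counts levels with nested flags", {
  calls <- tibble::tibble(
    transcript_id = "t", species = "mm10",
    status = c("conserved", "conserved", "lost", "not_alignable"))
  tc <- classify_transcripts(calls, min_present = 1,
                             thresholds = c(0.25, 0.5, 0.75))
  expect_equal(tc$n_sites, 4L)
  expect_equal(tc$n_conserved, 2L)
  expect_equal(tc$n_alignable, 3L)
  expect_equal(tc$fraction_conserved, 0.5)
  expect_true(tc$present)
  expect_true(tc$intermediate_0.5)
  expect_false(tc$intermediate_0.75)
  expect_false(tc$complete)

  all_cons <- tibble::tibble(transcript_id = "t", species = "mm10",
                             status = rep("conserved", 4))
  tca <- classify_transcripts(all_cons)
  expect_true(tca$complete && tca$present && tca$intermediate_0.75)
  expect_equal(tca$fraction_conserved, 1)

  none <- tibble::tibble(transcript_id = "t", species = "mm10",
                         status = rep("not_alignable", 4))
  tcn <- classify_transcripts(none)
  expect_equal(tcn$n_alignable, 0L)
  expect_false(any(tcn$present, tcn$complete, tcn$intermediate_0.25))
})

test_that("incomplete call sets are rejected when sites are supplied", {
  ss <- extract_splice_sites(tx3())
  calls <- tibble::tibble(transcript_id = "tx1", species = "mm10",
                          status = rep("conserved", 3))   # one site short
  expect_error(classify_transcripts(calls, sites = ss), "incomplete")
})

test_that("level flags nest on simulated data", {
  x <- small_sim(seed = 21, dropout = 0.1)
  idx <- read_maf(x$sim$paths$maf, ref_species = "hg38")
  ex <- read_bed12(x$sim$paths$bed)
  cons <- run_conservation(ex, idx, verbose = FALSE)
  tc <- cons$transcripts
  expect_true(all(!tc$complete | tc$intermediate_0.75))
  expect_true(all(!tc$intermediate_0.75 | tc$intermediate_0.5))
  expect_true(all(!tc$intermediate_0.5 | tc$intermediate_0.25))
  expect_true(all(!tc$intermediate_0.25 | tc$present))
  expect_true(all(tc$n_conserved <= tc$n_alignable))
  expect_true(all(tc$n_alignable <= tc$n_sites))
})

test_that("the reference species conserves every site of itself", {
  x <- small_sim(seed = 22)
  idx <- read_maf(x$sim$paths$maf, ref_species = "hg38")
  ex <- read_bed12(x$sim$paths$bed)
  cons <- run_conservation(ex, idx, species = c("hg38", "spA"),
                           verbose = FALSE)
  self <- cons$transcripts[cons$transcripts$species == "hg38", ]
  expect_true(all(self$fraction_conserved == 1))
  expect_true(all(self$complete))
})

test_that("widening the shift window never loses conserved sites", {
  x <- small_sim(seed = 23, subst_rate = 0.05)
  idx <- read_maf(x$sim$paths$maf, ref_species = "hg38")
  ex <- read_bed12(x$sim$paths$bed)
  sites <- suppressMessages(extract_splice_sites(ex))
  counts <- lapply(c(0L, 3L, 6L), function(s) {
    calls <- classify_sites(sites, idx, max_shift = s)
    classify_transcripts(calls)$n_conserved
  })
  expect_true(all(counts[[1]] <= counts[[2]]))
  expect_true(all(counts[[2]] <= counts[[3]]))
})

test_that("unknown species are warned about and scored not_alignable", {
  x <- small_sim(seed = 24)
  idx <- read_maf(x$sim$paths$maf, ref_species = "hg38")
  ex <- read_bed12(x$sim$paths$bed)
  sites <- suppressMessages(extract_splice_sites(ex))
  expect_warning(calls <- classify_sites(sites, idx,
                                         species = c("spA", "dodo")),
                 "dodo")
  expect_true(all(calls$status[calls$species == "dodo"] == "not_alignable"))
})
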