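# in-code fixtures shared across test files

# a three-exon transcript on the given strand
tx3 <- function(strand = "+", id = "tx1") {
  tibble::tibble(
    transcript_id = id, chrom = "chr1", strand = strand,
    start = c(100L, 300L, 500L), end = c(200L, 400L, 600L),
    exon_rank = 1:3, biotype = "noncoding"
  )
}

# random exon chains for property tests; returns an exon tibble
random_transcripts <- function(n, kmax = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_len(n), function(i) {
    k <- sample(2:kmax, 1)
    lens <- sample(50:200, k, replace = TRUE)
    gaps <- sample(50:400, k - 1, replace = TRUE)
    st <- 1000L + cumsum(c(0L, lens[-k] + gaps))
    tibble::tibble(
      transcript_id = sprintf("rt%03d", i), chrom = "chr1",
      strand = sample(c("+", "-"), 1),
      start = as.integer(st), end = as.integer(st + lens),
      exon_rank = seq_len(k), biotype = "unknown"
    )
  })
}

# write a small MAF from a list of blocks; each block is a character
# matrix-like list of c(src, start, size, strand, srcSize, text) rows
write_test_maf <- function(blocks, path = tempfile(fileext = ".maf")) {
  con <- file(path, "wt")
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("", con)
    writeLines("a score=0", con)
    for (r in b) writeLines(paste("s", paste(r, collapse = " ")), con)
  }
  close(con)
  path
}

# small noiseless simulation used by several files
small_sim <- function(seed = 5, n_target = 10, n_background = 40,
                      dropout = 0, subst_rate = 0, ...) {
  cfg <- sim_config(seed = seed, species = c("spA", "spB", "spC"),
                    distances = c(0.2, 0.6, 1.2),
                    n_target = n_target, n_background = n_background,
                    kmax = 5, dropout = dropout, subst_rate = subst_rate,
                    ...)
  dir <- tempfile("sim")
  sim <- simulate_ss_evolution(cfg, dir)
  list(cfg = cfg, sim = sim, dir = dir)
}

# independent brute-force dinucleotide scan used as oracle for the
# shift-window classifier: tries every offset in -s..s on the gap-stripped
# context, smallest |shift| first, ties negative
oracle_scan <- function(context, offset, patterns, s) {
  best <- NA_integer_
  for (sh in seq(-s, s)) {
    cand <- substr(context, offset + sh + 1, offset + sh + 2)
    if (nchar(cand) == 2 && cand %in% patterns) {
      if (is.na(best) || abs(sh) < abs(best) ||
          (abs(sh) == abs(best) && sh < best)) {
        best <- sh
      }
    }
  }
  best
}

# exhaustive two-sided Fisher p via log-gamma enumeration, independent of
# both the package implementation and stats::fisher.test
oracle_fisher <- function(a, b, c, d, tol = 1e-12) {
  lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  m1 <- a + b; m2 <- c + d; k <- a + c
  denom <- lchoose2(m1 + m2, k)
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose2(m1, xs) + lchoose2(m2, k - xs) - denom
  p_obs <- logp[xs == a]
  sum(exp(logp[logp <= p_obs + log1p(tol)]))
}
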