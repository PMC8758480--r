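#' Extract splice sites from transcript models
#'
#' Every intron of a multi-exonic transcript contributes two splice sites: a
#' donor (5' end of the intron, canonically `GT` on the transcript strand)
#' and an acceptor (3' end, canonically `AG`). `boundary_pos` is the 0-based
#' reference coordinate of the first base of the intronic dinucleotide in
#' reference orientation: for a `+` transcript the donor dinucleotide
#' occupies `[exon_end, exon_end + 2)` and the acceptor
#' `[next_exon_start - 2, next_exon_start)`; on the `-` strand donor and
#' acceptor swap ends and the dinucleotides are read as the reverse
#' complement of the reference.
#'
#' Single-exon transcripts carry no splice site and are excluded with a
#' message; their ids are attached as attribute `excluded_single_exon`.
#'
#' @param ex An exon tibble as returned by [read_annotation()].
#' @return A tibble of class `ss_sites` with columns `transcript_id`,
#'   `site_kind` (`"donor"`/`"acceptor"`), `chrom`, `boundary_pos`,
#'   `strand`, `intron_index` and `expected_dinucleotide` (on the
#'   transcript strand). A transcript with `k` exons yields exactly
#'   `2 * (k - 1)` rows.
#' @examples
#' ex <- tibble::tibble(
#'   transcript_id = "tx1", chrom = "chr1", strand = "+",
#'   start = c(100L, 300L, 500L), end = c(200L, 400L, 600L),
#'   exon_rank = 1:3, biotype = "noncoding"
#' )
#' extract_splice_sites(ex)
#' @export
extract_splice_sites <- function(ex) {
  validate_transcripts(ex)
  n_ex <- table(ex$transcript_id)
  single <- names(n_ex)[n_ex == 1L]
  if (length(single) > 0L) {
    inform(sprintf("excluding %d single-exon transcript(s)", length(single)))
  }
  multi <- ex[!ex$transcript_id %in% single, , drop = FALSE]
  if (nrow(multi) == 0L) {
    out <- tibble(transcript_id = character(), site_kind = character(),
                  chrom = character(), boundary_pos = integer(),
                  strand = character(), intron_index = integer(),
                  expected_dinucleotide = character())
    attr(out, "excluded_single_exon") <- single
    class(out) <- c("ss_sites", class(out))
    return(out)
  }
  # exons of one transcript occupy contiguous rows in genomic order, so
  # intron i sits between row j (non-last) and row j + 1
  nr <- nrow(multi)
  not_last <- c(multi$transcript_id[-nr] == multi$transcript_id[-1L], FALSE)
  j <- which(not_last)
  introns <- tibble(
    transcript_id = multi$transcript_id[j],
    chrom = multi$chrom[j],
    strand = multi$strand[j],
    intron_index = multi$exon_rank[j],
    donor_end = multi$end[j],             # exon end flanking the intron
    acceptor_start = multi$start[j + 1L]  # next exon start
  )
  plus <- introns$strand == "+"
  donors <- introns |>
    mutate(site_kind = "donor",
           boundary_pos = ifelse(plus, .data$donor_end,
                                 .data$acceptor_start - 2L))
  acceptors <- introns |>
    mutate(site_kind = "acceptor",
           boundary_pos = ifelse(plus, .data$acceptor_start - 2L,
                                 .data$donor_end))
  out <- bind_rows(donors, acceptors) |>
    mutate(boundary_pos = as.integer(.data$boundary_pos),
           expected_dinucleotide = ifelse(.data$site_kind == "donor",
                                          "GT", "AG")) |>
    select("transcript_id", "site_kind", "chrom", "boundary_pos",
           "strand", "intron_index", "expected_dinucleotide") |>
    arrange(.data$transcript_id, .data$intron_index, .data$site_kind)
  attr(out, "excluded_single_exon") <- single
  class(out) <- c("ss_sites", class(out))
  out
}

#' Write the splice-site table as TSV
#'
#' @param sites A site tibble from [extract_splice_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(as_tibble(sites), path)
  invisible(path)
}
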