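#' Read transcript models from a BED12 or GTF annotation
#'
#' Parses transcript annotations into a tidy exon table, the package's
#' native representation of gene structure: one row per exon, 0-based
#' half-open coordinates on the reference genome (the BED convention; GTF's
#' 1-based closed exons are converted on read).
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (default, decided from the file extension),
#'   `"bed12"` or `"gtf"`.
#' @return A tibble of class `ss_transcripts` with columns `transcript_id`,
#'   `chrom`, `strand`, `start`, `end`, `exon_rank` (1-based, in genomic
#'   order) and `biotype` (`"coding"`, `"noncoding"` or `"unknown"`).
#'   Transcripts are ordered by chromosome, start and id; exons by rank.
#' @examples
#' bed <- system.file("extdata", "example_synthetic.bed",
#'                    package = "splicecons")
#' read_annotation(bed)
#' @export
read_annotation <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  switch(format, bed12 = read_bed12(path), gtf = read_gtf(path))
}

#' @rdname read_annotation
#' @export
read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    warn(paste0("no records in ", path, "; returning empty transcript table"))
    return(empty_transcripts())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    abort(sprintf("malformed BED12 line %d in %s: expected 12 fields, got %d",
                  which(nf < 12L)[1], path, nf[which(nf < 12L)[1]]))
  }
  ids <- vapply(fields, `[`, character(1), 4L)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)]
    uniq <- !duplicated(lines)
    if (anyDuplicated(ids[uniq])) {
      abort(paste0("duplicate transcript_id with conflicting exons: ",
                   ids[uniq][duplicated(ids[uniq])][1], " in ", path))
    }
    fields <- fields[uniq]     # identical duplicate lines: keep one
  }
  rec <- purrr::imap(fields, function(f, i) {
    n_blocks <- suppressWarnings(as.integer(f[10]))
    sizes  <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
    starts <- suppressWarnings(as.integer(strsplit(f[12], ",")[[1]]))
    chrom_start <- suppressWarnings(as.integer(f[2]))
    if (is.na(n_blocks) || is.na(chrom_start) ||
        anyNA(sizes) || anyNA(starts) ||
        length(sizes) != n_blocks || length(starts) != n_blocks) {
      abort(sprintf("malformed BED12 line %d in %s: bad block definition",
                    i, path))
    }
    thick <- suppressWarnings(as.integer(f[7:8]))
    biotype <- if (anyNA(thick)) "unknown"
               else if (thick[2] > thick[1]) "coding" else "noncoding"
    tibble(
      transcript_id = f[4],
      chrom  = f[1],
      strand = f[6],
      start  = chrom_start + starts,
      end    = chrom_start + starts + sizes,
      biotype = biotype
    )
  })
  finish_transcripts(bind_rows(rec), path)
}

#' @rdname read_annotation
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warn(paste0("no records in ", path, "; returning empty transcript table"))
    return(empty_transcripts())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    abort(sprintf("malformed GTF line %d in %s: expected 9 fields, got %d",
                  lineno[bad], path, nf[bad]))
  }
  m <- do.call(rbind, fields)
  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) {
    warn(paste0("no exon records in ", path,
                "; returning empty transcript table"))
    return(empty_transcripts())
  }
  m <- m[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]
  tid <- stringr::str_match(m[, 9], 'transcript_id "([^"]+)"')[, 2]
  if (anyNA(tid)) {
    abort(sprintf("GTF line %d in %s: exon record lacks transcript_id",
                  lineno[which(is.na(tid))[1]], path))
  }
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1   <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- which(is.na(start1) | is.na(end1))[1]
    abort(sprintf("malformed GTF line %d in %s: non-numeric coordinates",
                  lineno[bad], path))
  }
  bt <- stringr::str_match(m[, 9],
                           '(?:transcript_biotype|gene_biotype|transcript_type|gene_type) "([^"]+)"')[, 2]
  biotype <- dplyr::case_when(
    is.na(bt) ~ "unknown",
    bt == "protein_coding" ~ "coding",
    grepl("lncRNA|lincRNA|noncoding|antisense", bt) ~ "noncoding",
    TRUE ~ "unknown"
  )
  ex <- tibble(
    transcript_id = tid,
    chrom  = m[, 1],
    strand = m[, 7],
    start  = start1 - 1L,   # 1-based closed -> 0-based half-open
    end    = end1,
    biotype = biotype
  )
  finish_transcripts(ex, path)
}

# sort, rank, deduplicate and validate an exon table read from disk
finish_transcripts <- function(ex, path) {
  ex <- distinct(ex) |>
    arrange(.data$transcript_id, .data$start)
  # conflicting duplicate ids: same id, different chrom/strand or exon chains
  key <- ex |>
    group_by(.data$transcript_id) |>
    summarise(
      sig = paste(.data$chrom[1], .data$strand[1],
                  paste(.data$start, .data$end, collapse = ";")),
      n_chrom = dplyr::n_distinct(.data$chrom),
      .groups = "drop"
    )
  if (any(key$n_chrom > 1L)) {
    abort(paste0("duplicate transcript_id with conflicting exons: ",
                 key$transcript_id[key$n_chrom > 1L][1], " in ", path))
  }
  ex <- ex |>
    group_by(.data$transcript_id) |>
    mutate(exon_rank = dplyr::row_number()) |>
    ungroup()
  validate_transcripts(ex)
  tx_order <- ex |>
    group_by(.data$transcript_id) |>
    summarise(chrom = .data$chrom[1], tss = min(.data$start),
              .groups = "drop") |>
    arrange(.data$chrom, .data$tss, .data$transcript_id)
  ex <- ex |>
    mutate(transcript_id = factor(.data$transcript_id,
                                  levels = tx_order$transcript_id)) |>
    arrange(.data$transcript_id, .data$exon_rank) |>
    mutate(transcript_id = as.character(.data$transcript_id))
  class(ex) <- c("ss_transcripts", class(ex))
  ex
}

empty_transcripts <- function() {
  ex <- tibble(transcript_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer(),
               exon_rank = integer(), biotype = character())
  class(ex) <- c("ss_transcripts", class(ex))
  ex
}

#' Validate an exon table
#'
#' Checks the structural invariants of a transcript exon table: exons sorted
#' and non-overlapping within a transcript, `end > start`, strand one of
#' `+`/`-`, at least one exon per transcript.
#'
#' @param ex An exon tibble as returned by [read_annotation()].
#' @return `ex`, invisibly, if valid; otherwise an error.
#' @export
validate_transcripts <- function(ex) {
  stopifnot(all(c("transcript_id", "chrom", "strand", "start", "end") %in%
                  names(ex)))
  if (nrow(ex) == 0L) return(invisible(ex))
  if (!all(ex$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every exon")
  }
  if (any(ex$end <= ex$start)) {
    bad <- which(ex$end <= ex$start)[1]
    abort(sprintf("exon with end <= start in transcript %s",
                  ex$transcript_id[bad]))
  }
  # adjacent-exon checks, vectorized over within-transcript neighbours
  n <- nrow(ex)
  if (n > 1L) {
    same <- ex$transcript_id[-n] == ex$transcript_id[-1L]
    bad <- same & (ex$start[-1L] < ex$end[-n])
    if (any(bad)) {
      abort(paste0("overlapping or unsorted exons in transcript ",
                   ex$transcript_id[which(bad)[1]]))
    }
  }
  invisible(ex)
}

#' Write an exon table as BED12
#'
#' @param ex An exon tibble as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(ex, path) {
  validate_transcripts(ex)
  bed <- ex |>
    group_by(.data$transcript_id) |>
    summarise(
      chrom = .data$chrom[1],
      chromStart = min(.data$start),
      chromEnd = max(.data$end),
      strand = .data$strand[1],
      biotype = .data$biotype[1],
      blockCount = n(),
      blockSizes = paste0(paste(.data$end - .data$start, collapse = ","), ","),
      blockStarts = paste0(paste(.data$start - min(.data$start),
                                 collapse = ","), ","),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$chromStart, .data$transcript_id)
  # thick region encodes biotype: coding transcripts get a full-span CDS
  thickEnd <- ifelse(bed$biotype == "coding", bed$chromEnd, bed$chromStart)
  out <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                 bed$chrom, bed$chromStart, bed$chromEnd, bed$transcript_id,
                 bed$strand, bed$chromStart, thickEnd, bed$blockCount,
                 bed$blockSizes, bed$blockStarts)
  writeLines(out, path)
  invisible(path)
}
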