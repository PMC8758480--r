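#' Read and index a MAF multiple alignment
#'
#' Parses a multiz-style MAF file (`a` block lines, `s` sequence lines) into
#' an interval-indexed object keyed by reference coordinates. The reference
#' species is a required argument and is never inferred from the file; its
#' rows must be on the `+` strand.
#'
#' @param path Path to a MAF file.
#' @param ref_species Name of the reference species (the part of the `s`
#'   line source field before the first dot, e.g. `"hg38"`).
#' @return An object of class `ss_maf`: a list with `rows` (one tibble row
#'   per `s` line: `block_id`, `species`, `seq_name`, `start`, `size`,
#'   `strand`, `src_size`, `text`), `blocks` (per block: reference `chrom`,
#'   `ref_start`, `ref_end`, 0-based half-open) and `ref_species`.
#' @examples
#' maf <- system.file("extdata", "example_synthetic.maf",
#'                    package = "splicecons")
#' idx <- read_maf(maf, ref_species = "hg38")
#' idx$blocks
#' @export
read_maf <- function(path, ref_species) {
  stopifnot(is.character(ref_species), length(ref_species) == 1L)
  lines <- readLines(path)
  tag <- substr(lines, 1L, 2L)
  is_a <- tag == "a " | lines == "a"
  is_s <- tag == "s "
  if (!any(is_a)) abort(paste0("no alignment blocks in ", path))
  block_id <- cumsum(is_a)
  s_lines <- lines[is_s]
  s_block <- block_id[is_s]
  if (any(s_block == 0L)) {
    abort(sprintf("malformed MAF %s: 's' line before first 'a' line", path))
  }
  f <- strsplit(trimws(s_lines), "[ \t]+")
  if (any(lengths(f) != 7L)) {
    abort(sprintf("malformed MAF %s: 's' line with %d fields",
                  path, lengths(f)[lengths(f) != 7L][1]))
  }
  m <- do.call(rbind, f)
  src <- m[, 2]
  dot <- regexpr(".", src, fixed = TRUE)
  species <- ifelse(dot > 0, substr(src, 1L, dot - 1L), src)
  seq_name <- ifelse(dot > 0, substring(src, dot + 1L), src)
  rows <- tibble(
    block_id = s_block,
    species = species,
    seq_name = seq_name,
    start = as.integer(m[, 3]),
    size = as.integer(m[, 4]),
    strand = m[, 5],
    src_size = as.integer(m[, 6]),
    text = m[, 7]
  )
  # within-block consistency
  tlen <- nchar(rows$text)
  len_by_block <- tapply(tlen, rows$block_id, function(x) length(unique(x)))
  if (any(len_by_block > 1L)) {
    abort(sprintf("MAF %s: unequal row lengths in block %s", path,
                  names(len_by_block)[len_by_block > 1L][1]))
  }
  ungapped <- tlen - vapply(gregexpr("-", rows$text, fixed = TRUE),
                            function(g) sum(g > 0), numeric(1))
  if (any(ungapped != rows$size)) {
    bad <- which(ungapped != rows$size)[1]
    abort(sprintf("MAF %s: row size %d does not match ungapped length %d in block %d",
                  path, rows$size[bad], ungapped[bad], rows$block_id[bad]))
  }
  ref <- rows[rows$species == ref_species, , drop = FALSE]
  if (nrow(ref) == 0L) {
    abort(sprintf("reference species '%s' absent from every block of %s",
                  ref_species, path))
  }
  if (any(ref$strand != "+")) {
    abort(sprintf("reference rows must be '+' strand (block %d)",
                  ref$block_id[ref$strand != "+"][1]))
  }
  missing_ref <- setdiff(unique(rows$block_id), ref$block_id)
  if (length(missing_ref) > 0L) {
    abort(sprintf("block %d of %s lacks a reference (%s) row",
                  missing_ref[1], path, ref_species))
  }
  blocks <- tibble(
    block_id = ref$block_id,
    chrom = ref$seq_name,
    ref_start = ref$start,
    ref_end = ref$start + ref$size
  )
  idx <- lapply(split(blocks, blocks$chrom), function(b) {
    list(ranges = IRanges::IRanges(start = b$ref_start + 1L, end = b$ref_end),
         block_id = b$block_id)
  })
  structure(list(rows = rows, blocks = blocks, index = idx,
                 ref_species = ref_species, path = path),
            class = "ss_maf")
}

#' @export
print.ss_maf <- function(x, ...) {
  cat(sprintf("<ss_maf> %d blocks, %d species, reference %s\n",
              nrow(x$blocks), length(unique(x$rows$species)), x$ref_species))
  invisible(x)
}

#' Query MAF blocks overlapping a reference interval
#'
#' @param maf An `ss_maf` object from [read_maf()].
#' @param chrom Reference sequence name.
#' @param start,end 0-based half-open reference interval.
#' @return Integer block ids overlapping the interval, in file order
#'   (possibly empty).
#' @export
maf_query <- function(maf, chrom, start, end) {
  ix <- maf$index[[chrom]]
  if (is.null(ix)) return(integer(0))
  q <- IRanges::IRanges(start = start + 1L, end = end)
  hits <- IRanges::findOverlaps(q, ix$ranges)
  sort(ix$block_id[S4Vectors::subjectHits(hits)])
}

#' Extract one alignment block as a tibble of rows
#'
#' @param maf An `ss_maf` object.
#' @param block_id Block number (1-based file order).
#' @return The block's rows as a tibble.
#' @export
maf_block <- function(maf, block_id) {
  b <- maf$rows[maf$rows$block_id == block_id, , drop = FALSE]
  if (nrow(b) == 0L) abort(sprintf("no block %s", block_id))
  b
}

#' Map a reference position to a species row of an alignment block
#'
#' Locates the alignment column of a reference coordinate by counting
#' non-gap reference characters, then reports the aligned character and the
#' gap-stripped sequence context of a target species around that column.
#'
#' @param block A block tibble from [maf_block()].
#' @param ref_pos 0-based reference coordinate; must lie within the block's
#'   reference row span.
#' @param species Target species name.
#' @param ref_species Reference species name (required, never inferred).
#' @param w Window half-width in alignment columns for the context.
#' @return A one-row tibble: `species`, `aligned`, `target_char`,
#'   `target_context` (gap-stripped), `context_offset` (0-based position of
#'   the mapped column within `target_context`) and `column` (1-based
#'   alignment column). If the species has no row in the block,
#'   `aligned = FALSE` and the character fields are empty.
#' @export
map_position <- function(block, ref_pos, species, ref_species, w = 8L) {
  ref <- block[block$species == ref_species, , drop = FALSE]
  if (nrow(ref) == 0L) abort(sprintf("reference species '%s' not in block",
                                     ref_species))
  ref <- ref[1L, ]
  if (ref_pos < ref$start || ref_pos >= ref$start + ref$size) {
    abort(sprintf("ref_pos %d outside block reference span [%d, %d)",
                  ref_pos, ref$start, ref$start + ref$size))
  }
  rchars <- strsplit(ref$text, "", fixed = TRUE)[[1]]
  nongap <- rchars != "-"
  cum <- cumsum(nongap)
  col <- which(nongap & cum == (ref_pos - ref$start + 1L))[1]
  trow <- block[block$species == species, , drop = FALSE]
  if (nrow(trow) == 0L) {
    return(tibble(species = species, aligned = FALSE, target_char = "",
                  target_context = "", context_offset = NA_integer_,
                  column = NA_integer_))
  }
  tchars <- strsplit(trow$text[1L], "", fixed = TRUE)[[1]]
  lo <- max(1L, col - w)
  hi <- min(length(tchars), col + w)
  win <- tchars[lo:hi]
  ctx <- win[win != "-"]
  before <- tchars[lo:col][-(col - lo + 1L)]
  tibble(species = species, aligned = TRUE,
         target_char = tchars[col],
         target_context = paste(ctx, collapse = ""),
         context_offset = sum(before != "-"),
         column = col)
}

#' Write alignment rows as a MAF file
#'
#' @param rows A tibble in the layout of `ss_maf$rows` (`block_id`,
#'   `species`, `seq_name`, `start`, `size`, `strand`, `src_size`, `text`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(rows, path) {
  stopifnot(all(c("block_id", "species", "seq_name", "start", "size",
                  "strand", "src_size", "text") %in% names(rows)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  src <- paste0(rows$species, ".", rows$seq_name)
  body <- sprintf("s %s %d %d %s %d %s", src, rows$start, rows$size,
                  rows$strand, rows$src_size, rows$text)
  pieces <- split(body, rows$block_id)
  out <- unlist(lapply(pieces, function(p) c("", "a score=0", p)),
                use.names = FALSE)
  writeLines(out, con)
  invisible(path)
}
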