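#' Default allowed splice-site dinucleotides
#'
#' Canonical `GT` donors and `AG` acceptors. With `minor = TRUE` the minor
#' spliceosomal / non-canonical classes (`GC` and `AT` donors, `AC`
#' acceptors) are also accepted.
#'
#' @param minor Include minor-class dinucleotides.
#' @return Named list with `donor` and `acceptor` character vectors, on the
#'   transcript strand.
#' @export
allowed_dinucleotides <- function(minor = FALSE) {
  if (minor) list(donor = c("GT", "GC", "AT"), acceptor = c("AG", "AC"))
  else list(donor = "GT", acceptor = "AG")
}

# search a gap-stripped context for any pattern at offsets 0,-1,+1,...,-s,+s;
# returns the first (smallest |shift|, ties negative) matching shift, or NA
.search_dinuc <- function(context, offset, patterns, max_shift) {
  shifts <- c(0L, as.vector(rbind(-seq_len(max_shift), seq_len(max_shift))))
  for (sh in shifts) {
    p <- offset + sh        # 0-based start of candidate dinucleotide
    cand <- substr(context, p + 1L, p + 2L)
    if (nchar(cand) == 2L && cand %in% patterns) return(sh)
  }
  NA_integer_
}

#' Classify one splice site in one species
#'
#' A site is `conserved` in a species if an allowed dinucleotide of its kind
#' occurs in the species' aligned context within `max_shift` nucleotides of
#' the mapped boundary (smallest absolute shift wins; ties resolve to the
#' negative shift). It is `not_alignable` if the species has no row in the
#' alignment block or its context is all gaps, and `lost` otherwise.
#' Matching is performed in reference orientation: for `-`-strand
#' transcripts the allowed dinucleotides are reverse-complemented before the
#' scan, and the reported shift is in reference orientation.
#'
#' @param site One row of an [extract_splice_sites()] table.
#' @param mapped One row from [map_position()] at `site$boundary_pos`.
#' @param max_shift Maximum absolute shift, in nucleotides (`0` disables the
#'   shift search).
#' @param allowed Allowed dinucleotides, see [allowed_dinucleotides()].
#' @return One-row tibble: `transcript_id`, `site_kind`, `species`,
#'   `status` (`conserved`/`lost`/`not_alignable`) and `shift` (`NA` unless
#'   conserved).
#' @export
classify_site <- function(site, mapped, max_shift = 0L,
                          allowed = allowed_dinucleotides()) {
  pats <- allowed[[site$site_kind]]
  if (site$strand == "-") pats <- revcomp(pats)
  if (!isTRUE(mapped$aligned) || !nzchar(mapped$target_context)) {
    status <- "not_alignable"; shift <- NA_integer_
  } else {
    shift <- .search_dinuc(mapped$target_context, mapped$context_offset,
                           pats, max_shift)
    status <- if (is.na(shift)) "lost" else "conserved"
  }
  tibble(transcript_id = site$transcript_id, site_kind = site$site_kind,
         species = mapped$species, status = status, shift = shift)
}

#' Classify all splice sites across species of a MAF alignment
#'
#' The vectorized whole-table equivalent of [map_position()] plus
#' [classify_site()]: every site of the table is located in the alignment
#' (first covering block in file order; an `ambiguous_block` flag marks
#' sites covered by more than one block) and classified in every species.
#' Sites outside any block are `not_alignable` in all species.
#'
#' @param sites Site table from [extract_splice_sites()].
#' @param maf An `ss_maf` object from [read_maf()].
#' @param species Character vector of species to score; defaults to all
#'   non-reference species observed in the alignment.
#' @param max_shift,allowed See [classify_site()].
#' @param w Context window half-width in alignment columns; defaults to
#'   `max_shift + 6`.
#' @return A tibble with one row per (site, species): the site identifier
#'   columns plus `species`, `status`, `shift`, `ambiguous_block`.
#' @export
classify_sites <- function(sites, maf, species = NULL, max_shift = 0L,
                           allowed = allowed_dinucleotides(), w = NULL) {
  stopifnot(inherits(maf, "ss_maf"))
  if (is.null(species)) {
    species <- setdiff(unique(maf$rows$species), maf$ref_species)
  }
  seen <- unique(maf$rows$species)
  unseen <- setdiff(species, seen)
  if (length(unseen) > 0L) {
    warn(paste0("species never observed in any alignment block: ",
                paste(unseen, collapse = ", ")))
  }
  w <- max(w %||% (max_shift + 6L), max_shift + 2L)
  n_site <- nrow(sites)
  n_sp <- length(species)
  # reference-orientation patterns per site
  pat_by_kind <- list(donor = allowed$donor, acceptor = allowed$acceptor)
  pat_minus <- lapply(pat_by_kind, revcomp)
  # locate each site's block (first in file order over the dinucleotide start)
  site_block <- rep(NA_integer_, n_site)
  site_ambig <- rep(FALSE, n_site)
  for (ch in unique(sites$chrom)) {
    ix <- maf$index[[ch]]
    sel <- which(sites$chrom == ch)
    if (is.null(ix) || length(sel) == 0L) next
    q <- IRanges::IRanges(start = sites$boundary_pos[sel] + 1L,
                          end = sites$boundary_pos[sel] + 1L)
    hits <- IRanges::findOverlaps(q, ix$ranges)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (length(qh) > 0L) {
      first <- tapply(ix$block_id[sh], qh, min)
      nhit <- tapply(sh, qh, length)
      idx <- as.integer(names(first))
      site_block[sel[idx]] <- as.integer(first)
      site_ambig[sel[idx]] <- nhit > 1L
    }
  }
  status <- matrix("not_alignable", nrow = n_site, ncol = n_sp)
  shift <- matrix(NA_integer_, nrow = n_site, ncol = n_sp)
  rows <- maf$rows
  row_block <- split(seq_len(nrow(rows)), rows$block_id)
  for (b in unique(site_block[!is.na(site_block)])) {
    ridx <- row_block[[as.character(b)]]
    bsp <- rows$species[ridx]
    ref_i <- match(maf$ref_species, bsp)
    rchars <- strsplit(rows$text[ridx[ref_i]], "", fixed = TRUE)[[1]]
    nongap <- rchars != "-"
    cum <- cumsum(nongap)
    ref_start <- rows$start[ridx[ref_i]]
    s_here <- which(site_block == b)
    cols <- vapply(sites$boundary_pos[s_here], function(bp) {
      which(nongap & cum == (bp - ref_start + 1L))[1]
    }, integer(1))
    tchar_cache <- vector("list", length(ridx))
    for (j in seq_len(n_sp)) {
      ti <- match(species[j], bsp)
      if (is.na(ti)) next                      # not_alignable stays
      if (is.null(tchar_cache[[ti]])) {
        tchar_cache[[ti]] <- strsplit(rows$text[ridx[ti]], "",
                                      fixed = TRUE)[[1]]
      }
      tchars <- tchar_cache[[ti]]
      for (k in seq_along(s_here)) {
        i <- s_here[k]; col <- cols[k]
        lo <- max(1L, col - w); hi <- min(length(tchars), col + w)
        win <- tchars[lo:hi]
        ctx <- win[win != "-"]
        if (length(ctx) == 0L) next            # all-gap context
        offset <- sum(win[seq_len(col - lo)] != "-")
        pats <- if (sites$strand[i] == "+") pat_by_kind[[sites$site_kind[i]]]
                else pat_minus[[sites$site_kind[i]]]
        sh2 <- .search_dinuc(paste(ctx, collapse = ""), offset, pats,
                             max_shift)
        if (is.na(sh2)) status[i, j] <- "lost"
        else { status[i, j] <- "conserved"; shift[i, j] <- sh2 }
      }
    }
  }
  out <- tibble(
    transcript_id = rep(sites$transcript_id, times = n_sp),
    site_kind = rep(sites$site_kind, times = n_sp),
    intron_index = rep(sites$intron_index, times = n_sp),
    chrom = rep(sites$chrom, times = n_sp),
    boundary_pos = rep(sites$boundary_pos, times = n_sp),
    strand = rep(sites$strand, times = n_sp),
    species = rep(species, each = n_site),
    status = as.vector(status),
    shift = as.vector(shift),
    ambiguous_block = rep(site_ambig, times = n_sp)
  )
  class(out) <- c("ss_site_calls", class(out))
  out
}

#' Aggregate site calls into graded transcript-level conservation
#'
#' For every (transcript, species) pair, counts conserved and alignable
#' sites and derives the graded conservation levels: `present` (at least
#' `min_present` conserved sites — the transcript is detectable as an
#' entity), `intermediate_f` (fraction conserved at least `f`, one column
#' per threshold) and `complete` (every splice site conserved, i.e. the
#' exact human intron-exon layout). Levels are nested by construction:
#' `complete` implies every `intermediate_f` implies `present`.
#'
#' @param calls Site-call table from [classify_sites()].
#' @param min_present Minimum conserved sites for the `present` level.
#' @param thresholds Numeric fractions in (0, 1] for intermediate levels.
#' @param sites Optional site table; if given, completeness of `calls` is
#'   checked against it and missing (site, species) pairs raise an error.
#' @return A tibble with one row per (transcript, species): `n_sites`,
#'   `n_conserved`, `n_alignable`, `fraction_conserved` and logical level
#'   columns.
#' @export
classify_transcripts <- function(calls, min_present = 1L,
                                 thresholds = c(0.25, 0.5, 0.75),
                                 sites = NULL) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  if (!is.null(sites)) {
    expected <- table(sites$transcript_id)
    got <- calls |> dplyr::count(.data$transcript_id, .data$species)
    bad <- got$n != as.vector(expected[got$transcript_id])
    if (any(bad)) {
      abort(paste0("site calls incomplete for: ",
                   paste(unique(got$transcript_id[bad]), collapse = ", ")))
    }
  }
  # C-level aggregation: one key per (transcript, species)
  key <- paste(calls$transcript_id, calls$species, sep = "\r")
  agg <- rowsum(cbind(n_sites = 1L,
                      n_conserved = as.integer(calls$status == "conserved"),
                      n_alignable = as.integer(calls$status !=
                                                 "not_alignable")),
                key, reorder = TRUE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  tc <- tibble(
    transcript_id = vapply(parts, `[`, character(1), 1L),
    species = vapply(parts, `[`, character(1), 2L),
    n_sites = as.integer(agg[, "n_sites"]),
    n_conserved = as.integer(agg[, "n_conserved"]),
    n_alignable = as.integer(agg[, "n_alignable"])
  ) |>
    mutate(
      fraction_conserved = .data$n_conserved / .data$n_sites,
      present = .data$n_conserved >= min_present,
      complete = .data$n_conserved == .data$n_sites
    )
  for (f in sort(thresholds)) {
    tc[[sprintf("intermediate_%g", f)]] <- tc$fraction_conserved >= f
  }
  tc <- tc |> dplyr::relocate("complete", .after = dplyr::last_col())
  class(tc) <- c("ss_transcript_conservation", class(tc))
  tc
}

#' Score splice-site conservation of a transcript set across species
#'
#' End-to-end conservation stage: extracts splice sites, classifies each in
#' every requested species of the alignment, and rolls calls up to graded
#' transcript-level conservation. Single-exon transcripts are excluded (and
#' counted in the log messages), matching the restriction of the analysis
#' to multi-exonic transcripts.
#'
#' @inheritParams classify_sites
#' @inheritParams classify_transcripts
#' @param ex Exon table from [read_annotation()].
#' @param verbose Emit per-stage and per-species summary messages.
#' @return A list of class `ss_conservation`: `sites`, `calls` and
#'   `transcripts` (the graded conservation table).
#' @export
run_conservation <- function(ex, maf, species = NULL, max_shift = 0L,
                             min_present = 1L,
                             thresholds = c(0.25, 0.5, 0.75),
                             allowed = allowed_dinucleotides(), w = NULL,
                             verbose = TRUE) {
  sites <- extract_splice_sites(ex)
  calls <- classify_sites(sites, maf, species = species,
                          max_shift = max_shift, allowed = allowed, w = w)
  tc <- classify_transcripts(calls, min_present = min_present,
                             thresholds = thresholds, sites = sites)
  if (verbose) {
    n_single <- length(attr(sites, "excluded_single_exon"))
    inform(sprintf("scored %d sites of %d transcripts in %d species (%d single-exon excluded)",
                   nrow(sites), length(unique(sites$transcript_id)),
                   length(unique(calls$species)), n_single))
    smry <- tc |>
      group_by(.data$species) |>
      summarise(complete_rate = mean(.data$complete),
                present_rate = mean(.data$present), .groups = "drop")
    for (i in seq_len(nrow(smry))) {
      inform(sprintf("  %s: complete %.3f, present %.3f", smry$species[i],
                     smry$complete_rate[i], smry$present_rate[i]))
    }
  }
  structure(list(sites = sites, calls = calls, transcripts = tc),
            class = "ss_conservation")
}

#' @export
print.ss_conservation <- function(x, ...) {
  cat(sprintf("<ss_conservation> %d transcripts x %d species (%d site calls)\n",
              length(unique(x$transcripts$transcript_id)),
              length(unique(x$transcripts$species)), nrow(x$calls)))
  invisible(x)
}
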