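#' Build a ladder ("caterpillar") tree with given distances to a reference
#'
#' Constructs a rooted newick tree in which each species attaches
#' successively further along the path away from the reference leaf, so
#' that its patristic distance to the reference equals the requested value.
#' Attachment points sit halfway (`d/2`), giving shared internal branches
#' and hence phylogenetically correlated site losses between related
#' species.
#'
#' @param species Character vector of species names.
#' @param distances Patristic distances to the reference, same length,
#'   strictly positive; sorted internally.
#' @param ref_species Reference leaf name.
#' @return A newick string.
#' @export
ladder_tree <- function(species, distances, ref_species = "hg38") {
  stopifnot(length(species) == length(distances), all(distances > 0),
            !ref_species %in% species)
  o <- order(distances, species)
  species <- species[o]; distances <- distances[o]
  x <- distances / 2                      # attachment point along ref path
  nwk <- sprintf("(%s:%.15g,%s:%.15g)", ref_species, x[1], species[1],
                 distances[1] - x[1])
  for (i in seq_along(species)[-1]) {
    nwk <- sprintf("(%s:%.15g,%s:%.15g)", nwk, x[i] - x[i - 1], species[i],
                   distances[i] - x[i])
  }
  paste0(nwk, ";")
}

# plausible vertebrate panel (UCSC-style assembly names) with rough
# neutral-distance placements; 18 species spanning primates to chicken
default_species_panel <- function() {
  tibble(
    species = c("panTro", "gorGor", "ponAbe", "nomLeu", "rheMac", "calJac",
                "tarSyr", "micMur", "tupBel", "canFam", "bosTau", "oryCun",
                "mm10", "rn6", "loxAfr", "monDom", "ornAna", "galGal"),
    distance = c(0.013, 0.018, 0.035, 0.05, 0.07, 0.12, 0.18, 0.25, 0.35,
                 0.40, 0.45, 0.50, 0.55, 0.60, 0.70, 1.40, 1.60, 1.90)
  )
}

#' Configuration for the splice-site turnover simulator
#'
#' Defaults are the "doubled-turnover" study conditions: 18 vertebrate species
#' on a ladder tree spanning patristic distances 0.013-1.9 from the
#' reference, 150 target and 2,000 background multi-exonic transcripts,
#' and a target-set turnover rate twice the background rate. A splice site
#' survives a branch of length `d` with probability `exp(-lambda * d)`,
#' independently per site and branch; once lost on a lineage it stays
#' lost. Alignment dropout is a per-branch event with probability
#' `dropout` per transcript, also heritable along the tree.
#'
#' @param seed Integer RNG seed (mandatory; the whole simulation is a
#'   deterministic function of the config).
#' @param species,distances Species panel and patristic distances used to
#'   build a ladder tree when `tree` is not supplied.
#' @param tree Optional newick string/`phylo` overriding the ladder.
#' @param ref_species Reference leaf name (must be in the tree).
#' @param n_target,n_background Transcript counts for the two sets.
#' @param kmax Exon counts are uniform on `2:kmax`.
#' @param exon_min,exon_mean,intron_min,intron_mean Exon/intron length
#'   model: `min + geometric`, with the stated mean (nt).
#' @param lambda_bg,lambda_target Site-loss rates per unit branch length.
#' @param dropout Per-branch, per-transcript alignment dropout probability.
#' @param subst_rate Substitution noise rate at non-site positions of
#'   emitted target rows.
#' @param flank Flanking bases around each site dinucleotide in emitted
#'   alignment blocks.
#' @param block_style `"per_site"` (default; one compact block per splice
#'   site) or `"per_transcript"` (one whole-locus block per transcript).
#' @return A list of class `ss_sim_config`.
#' @export
sim_config <- function(seed,
                       species = NULL, distances = NULL, tree = NULL,
                       ref_species = "hg38",
                       n_target = 150L, n_background = 2000L,
                       kmax = 15L,
                       exon_min = 50L, exon_mean = 150,
                       intron_min = 50L, intron_mean = 400,
                       lambda_bg = 0.25, lambda_target = 0.5,
                       dropout = 0.02, subst_rate = 0.01,
                       flank = 10L,
                       block_style = c("per_site", "per_transcript")) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            lambda_bg >= 0, lambda_target >= 0,
            dropout >= 0, dropout <= 1, subst_rate >= 0, subst_rate < 1,
            kmax >= 2, n_target >= 1, n_background >= 1,
            flank >= 4,
            # blocks around neighbouring sites must not overlap
            exon_min >= 2 * flank + 2, intron_min >= 2 * flank + 2)
  block_style <- match.arg(block_style)
  if (is.null(tree)) {
    if (is.null(species)) {
      panel <- default_species_panel()
      species <- panel$species; distances <- panel$distance
    }
    tree <- ladder_tree(species, distances, ref_species)
  }
  phy <- as_phylo(tree)
  if (!ref_species %in% phy$tip.label) {
    abort(sprintf("tree lacks the reference leaf '%s'", ref_species))
  }
  structure(list(
    seed = as.integer(seed), tree = tree, ref_species = ref_species,
    species = setdiff(phy$tip.label, ref_species),
    n_target = as.integer(n_target), n_background = as.integer(n_background),
    kmax = as.integer(kmax),
    exon_min = as.integer(exon_min), exon_mean = exon_mean,
    intron_min = as.integer(intron_min), intron_mean = intron_mean,
    lambda_bg = lambda_bg, lambda_target = lambda_target,
    dropout = dropout, subst_rate = subst_rate,
    flank = as.integer(flank), block_style = block_style
  ), class = "ss_sim_config")
}

#' The doubled-turnover preset
#'
#' Target turnover twice background, 18 species, 150 target / 2,000
#' background transcripts (the generator defaults).
#'
#' @param seed Integer RNG seed.
#' @param ... Overrides passed to [sim_config()].
#' @return An `ss_sim_config`.
#' @export
doubled_turnover_config <- function(seed, ...) sim_config(seed, ...)

# edges on the path from the reference leaf to every other leaf
path_edges <- function(phy, ref_species) {
  ref_i <- match(ref_species, phy$tip.label)
  ekey <- paste(pmin(phy$edge[, 1], phy$edge[, 2]),
                pmax(phy$edge[, 1], phy$edge[, 2]))
  tips <- setdiff(phy$tip.label, ref_species)
  paths <- lapply(tips, function(sp) {
    np <- ape::nodepath(phy, ref_i, match(sp, phy$tip.label))
    key <- paste(pmin(np[-length(np)], np[-1]),
                 pmax(np[-length(np)], np[-1]))
    match(key, ekey)
  })
  names(paths) <- tips
  paths
}

#' Simulate splice-site turnover along the tree (ground truth only)
#'
#' The fast core of the generator: draws transcript structures and the
#' per-(site, species) conservation status under the branch-survival model,
#' without emitting alignment files. [simulate_ss_evolution()] builds its
#' MAF/BED12 output from exactly this truth.
#'
#' @param config An [sim_config()] object.
#' @return A list: `exons` (transcript exon table), `sites`, `truth`
#'   (tibble per site x species with scripted `status` and set label),
#'   `dropout` (per transcript x species logical), `target_ids`,
#'   `background_ids`, `tree`, `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "ss_sim_config"))
  set.seed(config$seed)
  n_tx <- config$n_background + config$n_target
  set <- rep(c("background", "target"), c(config$n_background,
                                          config$n_target))
  ids <- sprintf("%s_%05d", ifelse(set == "background", "bg", "tgt"),
                 c(seq_len(config$n_background), seq_len(config$n_target)))
  k <- sample(2:config$kmax, n_tx, replace = TRUE)
  strand <- sample(c("+", "-"), n_tx, replace = TRUE)
  # exon/intron lengths: min + geometric with the configured mean
  gmean <- function(n, min, mean) {
    min + rgeom(n, prob = 1 / (mean - min + 1))
  }
  exon_len <- gmean(sum(k), config$exon_min, config$exon_mean)
  intron_len <- gmean(sum(k) - n_tx, config$intron_min, config$intron_mean)
  # lay transcripts head-to-tail on one chromosome with a margin
  pos <- 1000L
  ei <- 0L; ii <- 0L
  starts_ends <- vector("list", n_tx)
  for (t in seq_len(n_tx)) {
    kk <- k[t]
    el <- exon_len[(ei + 1L):(ei + kk)]; ei <- ei + kk
    il <- if (kk > 1L) intron_len[(ii + 1L):(ii + kk - 1L)] else integer(0)
    ii <- ii + kk - 1L
    st <- pos + cumsum(c(0L, el[-kk] + il))
    en <- st + el
    starts_ends[[t]] <- list(start = st, end = en)
    pos <- en[kk] + 500L
  }
  exons <- tibble(
    transcript_id = rep(ids, k),
    chrom = "chrSim",
    strand = rep(strand, k),
    start = as.integer(unlist(lapply(starts_ends, `[[`, "start"))),
    end = as.integer(unlist(lapply(starts_ends, `[[`, "end"))),
    biotype = "noncoding"
  ) |>
    group_by(.data$transcript_id) |>
    mutate(exon_rank = dplyr::row_number()) |>
    ungroup()
  class(exons) <- c("ss_transcripts", class(exons))
  sites <- suppressMessages(extract_splice_sites(exons))
  lambda_tx <- ifelse(set == "target", config$lambda_target,
                      config$lambda_bg)
  names(lambda_tx) <- ids
  lambda_site <- lambda_tx[sites$transcript_id]
  phy <- as_phylo(config$tree)
  paths <- path_edges(phy, config$ref_species)
  used <- sort(unique(unlist(paths)))
  elen <- phy$edge.length
  n_site <- nrow(sites)
  surv <- matrix(TRUE, n_site, max(used))
  drop_m <- matrix(FALSE, n_tx, max(used))
  for (e in used) {
    surv[, e] <- rbinom(n_site, 1L, exp(-lambda_site * elen[e])) == 1L
    if (config$dropout > 0) {
      drop_m[, e] <- rbinom(n_tx, 1L, config$dropout) == 1L
    }
  }
  tx_index <- match(sites$transcript_id, ids)
  species <- config$species
  status <- matrix("conserved", n_site, length(species))
  dropped <- matrix(FALSE, n_tx, length(species))
  for (j in seq_along(species)) {
    pe <- paths[[species[j]]]
    ok <- rowSums(surv[, pe, drop = FALSE]) == length(pe)
    status[!ok, j] <- "lost"
    dj <- rowSums(drop_m[, pe, drop = FALSE]) > 0L
    dropped[, j] <- dj
    status[dj[tx_index], j] <- "not_alignable"
  }
  rownames(dropped) <- ids
  colnames(dropped) <- species
  n_sp <- length(species)
  set_of_site <- set[tx_index]
  truth <- tibble(
    transcript_id = rep(sites$transcript_id, times = n_sp),
    site_kind = rep(sites$site_kind, times = n_sp),
    intron_index = rep(sites$intron_index, times = n_sp),
    chrom = rep(sites$chrom, times = n_sp),
    boundary_pos = rep(sites$boundary_pos, times = n_sp),
    strand = rep(sites$strand, times = n_sp),
    species = rep(species, each = n_site),
    status = as.vector(status),
    set = rep(set_of_site, times = n_sp)
  )
  list(exons = exons, sites = sites, truth = truth,
       dropout = dropped, target_ids = ids[set == "target"],
       background_ids = ids[set == "background"], tree = config$tree,
       config = config)
}

#' Simulate splice-site turnover and emit MAF + BED12 + ID lists
#'
#' Runs [simulate_truth()] and materializes it as the pipeline's input
#' files: a reference-anchored MAF whose target rows carry the scripted
#' conservation status (lost sites have their dinucleotide mutated to a
#' non-splice 2-mer, dropped species lack the row entirely), a BED12 of the
#' transcript models, the newick tree, the two ID lists and the
#' ground-truth TSV. Outputs are byte-identical for a given config.
#'
#' @param config An [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the output `paths` and the
#'   [simulate_truth()] result.
#' @export
simulate_ss_evolution <- function(config, dir) {
  tr <- simulate_truth(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- if (config$block_style == "per_site") {
    emit_per_site(tr, config)
  } else {
    emit_per_transcript(tr, config)
  }
  paths <- list(
    maf = file.path(dir, "alignment.maf"),
    bed = file.path(dir, "transcripts.bed"),
    tree = file.path(dir, "tree.nwk"),
    target_ids = file.path(dir, "target_ids.txt"),
    background_ids = file.path(dir, "background_ids.txt"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  write_maf(rows, paths$maf)
  write_bed12(tr$exons, paths$bed)
  writeLines(sub(";?$", ";", as_newick(config$tree)), paths$tree)
  writeLines(tr$target_ids, paths$target_ids)
  writeLines(tr$background_ids, paths$background_ids)
  readr::write_tsv(tr$truth, paths$truth)
  invisible(c(list(paths = paths), tr))
}

as_newick <- function(tree) {
  if (inherits(tree, "phylo")) ape::write.tree(tree) else tree
}

# one compact alignment block per splice site: dinucleotide +/- flank
emit_per_site <- function(tr, config) {
  sites <- tr$sites
  n_site <- nrow(sites)
  species <- config$species
  flank <- config$flank
  W <- 2L * flank + 2L
  # reference block sequences: random, with the true dinucleotide planted
  bases <- c("A", "C", "G", "T")
  ref_mat <- matrix(sample(bases, n_site * W, replace = TRUE), n_site, W)
  ref_texts <- do.call(paste0, as.data.frame(ref_mat,
                                             stringsAsFactors = FALSE))
  dinuc_tx <- ifelse(sites$site_kind == "donor", "GT", "AG")
  dinuc_ref <- ifelse(sites$strand == "+", dinuc_tx, revcomp(dinuc_tx))
  substr(ref_texts, flank + 1L, flank + 2L) <- dinuc_ref
  block_start <- sites$boundary_pos - flank
  status_m <- matrix(tr$truth$status, nrow = n_site)   # site x species
  rows_list <- vector("list", length(species) + 1L)
  src_size <- max(block_start) + W + 1000L
  rows_list[[1]] <- tibble(
    block_id = seq_len(n_site), species = config$ref_species,
    seq_name = sites$chrom, start = block_start, size = W,
    strand = "+", src_size = src_size, text = ref_texts
  )
  for (j in seq_along(species)) {
    st <- status_m[, j]
    keep <- st != "not_alignable"
    texts <- ref_texts[keep]
    lost <- st[keep] == "lost"
    # a lost site's dinucleotide becomes CC: matches no allowed splice
    # dinucleotide in either orientation
    substr(texts[lost], flank + 1L, flank + 2L) <- "CC"
    if (config$subst_rate > 0) {
      texts <- add_noise(texts, config$subst_rate,
                         avoid = list(c(flank + 1L, flank + 2L)))
    }
    rows_list[[j + 1L]] <- tibble(
      block_id = which(keep), species = species[j],
      seq_name = sites$chrom[keep], start = block_start[keep], size = W,
      strand = "+", src_size = src_size, text = texts
    )
  }
  bind_rows(rows_list) |> arrange(.data$block_id)
}

# one whole-locus block per transcript (multiple sites per block)
emit_per_transcript <- function(tr, config) {
  sites <- tr$sites
  species <- config$species
  flank <- config$flank
  bases <- c("A", "C", "G", "T")
  tx <- tr$exons |>
    group_by(.data$transcript_id) |>
    summarise(chrom = .data$chrom[1], lo = min(.data$start) - flank,
              hi = max(.data$end) + flank, .groups = "drop")
  tx$block_id <- seq_len(nrow(tx))
  tx$width <- tx$hi - tx$lo
  ref_texts <- vapply(tx$width, function(w) {
    paste(sample(bases, w, replace = TRUE), collapse = "")
  }, character(1))
  site_tx <- match(sites$transcript_id, tx$transcript_id)
  site_off <- sites$boundary_pos - tx$lo[site_tx] + 1L  # 1-based in block
  dinuc_tx <- ifelse(sites$site_kind == "donor", "GT", "AG")
  dinuc_ref <- ifelse(sites$strand == "+", dinuc_tx, revcomp(dinuc_tx))
  for (i in seq_len(nrow(sites))) {
    substr(ref_texts[site_tx[i]], site_off[i], site_off[i] + 1L) <-
      dinuc_ref[i]
  }
  n_site <- nrow(sites)
  status_m <- matrix(tr$truth$status, nrow = n_site)
  src_size <- max(tx$hi) + 1000L
  rows_list <- vector("list", length(species) + 1L)
  rows_list[[1]] <- tibble(
    block_id = tx$block_id, species = config$ref_species,
    seq_name = tx$chrom, start = tx$lo, size = tx$width,
    strand = "+", src_size = src_size, text = ref_texts
  )
  avoid <- cbind(site_off, site_off + 1L)
  for (j in seq_along(species)) {
    keep_tx <- which(!tr$dropout[tx$transcript_id, j])
    texts <- ref_texts[keep_tx]
    names(texts) <- as.character(keep_tx)
    lost <- which(status_m[, j] == "lost")
    for (i in lost) {
      t_id <- as.character(site_tx[i])
      if (!t_id %in% names(texts)) next
      substr(texts[[t_id]], site_off[i], site_off[i] + 1L) <- "CC"
    }
    if (config$subst_rate > 0) {
      for (ti in seq_along(texts)) {
        bid <- keep_tx[ti]
        av <- as.vector(t(avoid[site_tx == bid, , drop = FALSE]))
        texts[ti] <- add_noise(texts[ti], config$subst_rate,
                               avoid = list(av))
      }
    }
    rows_list[[j + 1L]] <- tibble(
      block_id = keep_tx, species = species[j],
      seq_name = tx$chrom[keep_tx], start = tx$lo[keep_tx],
      size = tx$width[keep_tx], strand = "+", src_size = src_size,
      text = unname(texts)
    )
  }
  bind_rows(rows_list) |> arrange(.data$block_id)
}

# substitute random positions of block texts, sparing the splice
# dinucleotides; `avoid` is a list of 1-based positions per text
# (recycled if of length 1)
add_noise <- function(texts, rate, avoid) {
  if (!is.list(avoid)) avoid <- list(as.integer(avoid))
  if (length(avoid) == 1L) avoid <- rep(avoid, length(texts))
  widths <- nchar(texts)
  n_mut <- rbinom(length(texts), pmax(widths - lengths(avoid), 0L), rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_mut > 0L)) {
    ok_pos <- setdiff(seq_len(widths[i]), avoid[[i]])
    pos <- sample(ok_pos, min(n_mut[i], length(ok_pos)))
    for (p in pos) {
      cur <- substr(texts[i], p, p)
      substr(texts[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  texts
}

#' Closed-form expected conservation rates under the survival model
#'
#' In the oracle regime (no dropout, no substitution noise) a site survives
#' to a species at patristic distance `d` with probability
#' `p = exp(-lambda * d)`. For a transcript with `k` exons (hence
#' `2(k-1)` sites), `P(complete) = p^(2(k-1))` and, with `min_present = 1`,
#' `P(present) = 1 - (1-p)^(2(k-1))`; intermediate levels follow the
#' binomial tail. Expectations are marginalized over the uniform exon-count
#' distribution of the config.
#'
#' @param config An [sim_config()] object.
#' @param level `"complete"`, `"present"` or a fraction threshold given as
#'   `"intermediate_<f>"`.
#' @param set `"background"` or `"target"` (selects the loss rate).
#' @param min_present Minimum conserved sites for `present`.
#' @return A tibble `species`, `distance`, `expected_rate`.
#' @export
expected_rates <- function(config, level = "complete",
                           set = c("background", "target"),
                           min_present = 1L) {
  set <- match.arg(set)
  lambda <- if (set == "target") config$lambda_target else config$lambda_bg
  dist <- species_distances(config$tree, config$ref_species) |>
    filter(.data$species %in% config$species)
  ks <- 2:config$kmax
  nsites <- 2L * (ks - 1L)
  rate_at <- function(p) {
    per_k <- if (level == "complete") {
      p ^ nsites
    } else if (level == "present") {
      1 - stats::pbinom(min_present - 1L, nsites, p)
    } else if (grepl("^intermediate_", level)) {
      f <- as.numeric(sub("intermediate_", "", level))
      1 - stats::pbinom(ceiling(f * nsites) - 1L, nsites, p)
    } else abort(sprintf("unknown level '%s'", level))
    mean(per_k)
  }
  dist |>
    mutate(expected_rate = vapply(exp(-lambda * .data$distance), rate_at,
                                  numeric(1)))
}
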