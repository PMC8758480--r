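#' Run the full gene-structure conservation analysis
#'
#' End-to-end orchestration: read the annotation, alignment, tree and ID
#' lists; extract and classify splice sites; roll up graded transcript
#' conservation; compare the target set against the background per species;
#' write every stage's table as TSV into `out_dir` together with a run log.
#' Outputs are deterministic for fixed inputs and parameters, and each
#' stage's TSV can be re-loaded and re-run individually.
#'
#' @param annotation Path to a BED12 or GTF annotation.
#' @param maf Path to the MAF alignment (reference rows on `+` strand).
#' @param tree Newick tree path or string, containing the reference leaf
#'   and every scored species.
#' @param target_ids,background_ids Paths to plain-text transcript-ID lists
#'   (one id per line), or character vectors of ids.
#' @param out_dir Output directory, created if absent.
#' @param ref_species Reference species name (never inferred).
#' @param species Species to score; default all non-reference species in
#'   the MAF.
#' @param max_shift,min_present,thresholds,mode,alpha,min_alignable_frac
#'   Conservation and comparison parameters, see [classify_sites()],
#'   [classify_transcripts()] and [compare_sets()].
#' @param minor_dinucleotides Also accept minor-class splice dinucleotides.
#' @param verbose Log progress messages.
#' @return Invisibly, a list of class `ss_pipeline`: `conservation` (the
#'   [run_conservation()] result), `comparison` (the [compare_sets()]
#'   result) and `paths` of the written tables.
#' @export
run_pipeline <- function(annotation, maf, tree, target_ids, background_ids,
                         out_dir, ref_species,
                         species = NULL, max_shift = 0L, min_present = 1L,
                         thresholds = c(0.25, 0.5, 0.75),
                         mode = c("strict", "conditioned"),
                         min_alignable_frac = 0.5,
                         minor_dinucleotides = FALSE, alpha = 0.05,
                         verbose = TRUE) {
  mode <- match.arg(mode)
  for (p in c(annotation, maf)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  read_ids <- function(x) {
    if (length(x) == 1L && file.exists(x)) readLines(x) else x
  }
  log_lines <- c(
    sprintf("splicecons %s | R %s",
            as.character(utils::packageVersion("splicecons")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("annotation=%s maf=%s", annotation, maf),
    sprintf("ref_species=%s max_shift=%d min_present=%d mode=%s alpha=%g",
            ref_species, max_shift, min_present, mode, alpha),
    sprintf("thresholds=%s", paste(thresholds, collapse = ","))
  )
  ex <- stage("read_annotation", read_annotation(annotation))
  idx <- stage("index_maf", read_maf(maf, ref_species = ref_species))
  tgt <- read_ids(target_ids)
  bg <- read_ids(background_ids)
  cons <- stage("conservation", run_conservation(
    ex, idx, species = species, max_shift = max_shift,
    min_present = min_present, thresholds = thresholds,
    allowed = allowed_dinucleotides(minor = minor_dinucleotides),
    verbose = verbose))
  cmp <- stage("compare_sets", compare_sets(
    cons$transcripts, tgt, bg, tree, ref_species, alpha = alpha,
    mode = mode, min_alignable_frac = min_alignable_frac))
  n_single <- length(attr(cons$sites, "excluded_single_exon"))
  log_lines <- c(log_lines,
    sprintf("transcripts_read=%d single_exon_excluded=%d",
            length(unique(ex$transcript_id)), n_single),
    sprintf("sites_extracted=%d species_scored=%d", nrow(cons$sites),
            length(unique(cons$calls$species))),
    sprintf("target_n=%d background_n=%d", length(tgt), length(bg)))
  paths <- list(
    site_calls = file.path(out_dir, "site_calls.tsv"),
    transcript_conservation = file.path(out_dir,
                                        "transcript_conservation.tsv"),
    rate_curves = file.path(out_dir, "rate_curves.tsv"),
    comparisons = file.path(out_dir, "comparisons.tsv"),
    log = file.path(out_dir, "run_log.txt")
  )
  readr::write_tsv(as_tibble(cons$calls), paths$site_calls)
  readr::write_tsv(as_tibble(cons$transcripts),
                   paths$transcript_conservation)
  readr::write_tsv(cmp$rates, paths$rate_curves)
  readr::write_tsv(tidy(cmp), paths$comparisons)
  writeLines(log_lines, paths$log)
  if (verbose) inform(paste0("pipeline outputs written to ", out_dir))
  invisible(structure(list(conservation = cons, comparison = cmp,
                           paths = paths), class = "ss_pipeline"))
}
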