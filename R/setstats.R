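#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value computed by summing the hypergeometric
#' probabilities of all tables with the observed margins that are at most
#' as probable as the observed table, using a relative tolerance of 1e-12
#' on "as probable".
#'
#' @param tab A 2x2 matrix of non-negative integer counts
#'   (rows = sets, columns = outcome); all four margins must be positive.
#' @param tol Relative tolerance for probability ties.
#' @return The two-sided p-value, in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))   # 1
#' @export
fisher_exact_2x2 <- function(tab, tol = 1e-12) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be non-negative integers")
  }
  r <- rowSums(tab); cl <- colSums(tab)
  if (any(r == 0) || any(cl == 0)) abort("zero margin in 2x2 table")
  m1 <- r[1]; m2 <- r[2]; k <- cl[1]; x <- tab[1, 1]
  support <- max(0, k - m2):min(k, m1)
  d <- dhyper(support, m1, m2, k)
  p_obs <- d[support == x]
  min(1, sum(d[d <= p_obs * (1 + tol)]))
}

#' Patristic distances of all species from a reference leaf
#'
#' @param tree An `ape::phylo` object, a newick string, or a path to a
#'   newick file.
#' @param ref_species Name of the reference leaf.
#' @return A tibble `species`, `distance` (sum of branch lengths on the
#'   path to the reference leaf), reference excluded, ordered by distance
#'   then name.
#' @export
species_distances <- function(tree, ref_species) {
  tree <- as_phylo(tree)
  if (!ref_species %in% tree$tip.label) {
    abort(sprintf("reference leaf '%s' not in tree", ref_species))
  }
  d <- ape::cophenetic.phylo(tree)[ref_species, ]
  out <- tibble(species = names(d), distance = unname(d)) |>
    filter(.data$species != ref_species) |>
    arrange(.data$distance, .data$species)
  out
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  stopifnot(is.character(tree), length(tree) == 1L)
  if (grepl("\\(", tree)) ape::read.tree(text = tree)
  else ape::read.tree(tree)
}

# resolve a level name to the logical column of the conservation table
level_column <- function(tc, level) {
  if (!level %in% names(tc)) {
    abort(sprintf("unknown conservation level '%s'; available: %s", level,
                  paste(grep("^present$|^complete$|^intermediate_",
                             names(tc), value = TRUE), collapse = ", ")))
  }
  level
}

#' Conservation rate of a transcript set at a level, in one species
#'
#' @param tc Transcript-conservation table from [classify_transcripts()].
#' @param ids Character vector of transcript ids (the set).
#' @param species One species name.
#' @param level Level column name: `"present"`, `"complete"` or an
#'   `"intermediate_<f>"` column.
#' @param mode `"strict"` (default): every transcript of the set counts in
#'   the denominator. `"conditioned"`: transcripts with fewer than
#'   `min_alignable_frac` of their sites alignable in that species are
#'   dropped from the denominator — a control for alignment/assembly
#'   quality confounding.
#' @param min_alignable_frac Alignability threshold for the conditioned
#'   mode.
#' @return A one-row tibble `k`, `n`, `rate` (`k / n`).
#' @export
conservation_rate <- function(tc, ids, species, level,
                              mode = c("strict", "conditioned"),
                              min_alignable_frac = 0.5) {
  mode <- match.arg(mode)
  if (length(ids) == 0L) abort("empty transcript set")
  present_ids <- unique(tc$transcript_id)
  missing <- setdiff(ids, present_ids)
  if (length(missing) > 0L) {
    abort(paste0("transcript ids absent from conservation table: ",
                 paste(head(missing, 10L), collapse = ", ")))
  }
  level <- level_column(tc, level)
  rows <- tc[tc$transcript_id %in% ids & tc$species == species, ,
             drop = FALSE]
  if (mode == "conditioned") {
    rows <- rows[rows$n_alignable / rows$n_sites >= min_alignable_frac, ,
                 drop = FALSE]
  }
  k <- sum(rows[[level]])
  n <- nrow(rows)
  tibble(k = k, n = n, rate = if (n > 0) k / n else NA_real_)
}

#' Compare conservation of a target set against a background set
#'
#' The statistical stage of the analysis: per species and per conservation
#' level, conservation rates of the two sets are tabulated and compared
#' with a two-sided Fisher's exact test, independently for each species.
#' Species are ordered by patristic distance from the reference leaf of the
#' tree (ties broken by name). Raw p-values are flagged significant at
#' `alpha`; Benjamini-Hochberg adjusted p-values across species within each
#' level are reported alongside.
#'
#' @inheritParams conservation_rate
#' @param target_ids,background_ids Transcript id vectors; overlapping ids
#'   are removed from the background with a warning.
#' @param tree Newick tree (object, string or path) containing the
#'   reference leaf and every species of `tc`.
#' @param ref_species Reference leaf name.
#' @param levels Level columns to compare; default all level columns of
#'   `tc`, ordered by stringency.
#' @param alpha Significance threshold on the raw p-value.
#' @return An object of class `ss_comparison`: list with `comparisons`
#'   (per species x level: counts, rates, `p`, `p_adj`, `significant`),
#'   `rates` (long per-set rate table for plotting) and `distances`.
#' @export
compare_sets <- function(tc, target_ids, background_ids, tree, ref_species,
                         levels = NULL, alpha = 0.05,
                         mode = c("strict", "conditioned"),
                         min_alignable_frac = 0.5) {
  mode <- match.arg(mode)
  overlap <- intersect(target_ids, background_ids)
  if (length(overlap) > 0L) {
    warn(sprintf("%d transcript(s) in both sets; removed from background",
                 length(overlap)))
    background_ids <- setdiff(background_ids, overlap)
  }
  if (length(target_ids) == 0L) abort("empty target set")
  if (length(background_ids) == 0L) {
    abort("background set empty after overlap removal")
  }
  if (is.null(levels)) {
    levels <- grep("^present$|^intermediate_|^complete$", names(tc),
                   value = TRUE)
    inter <- sort(as.numeric(sub("intermediate_", "",
                                 grep("^intermediate_", levels,
                                      value = TRUE))))
    levels <- c("present", sprintf("intermediate_%g", inter), "complete")
    levels <- levels[levels %in% names(tc)]
  }
  dist <- species_distances(tree, ref_species)
  sp_tab <- unique(tc$species)
  missing_sp <- setdiff(sp_tab, c(dist$species, ref_species))
  if (length(missing_sp) > 0L) {
    abort(paste0("species missing from tree: ",
                 paste(missing_sp, collapse = ", ")))
  }
  dist <- dist |> filter(.data$species %in% sp_tab)
  grid <- tidyr::expand_grid(species = dist$species, level = levels)
  cmp <- purrr::pmap(grid, function(species, level) {
    rs <- conservation_rate(tc, target_ids, species, level, mode = mode,
                            min_alignable_frac = min_alignable_frac)
    rb <- conservation_rate(tc, background_ids, species, level, mode = mode,
                            min_alignable_frac = min_alignable_frac)
    tab <- matrix(c(rs$k, rs$n - rs$k, rb$k, rb$n - rb$k), 2L, byrow = TRUE)
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
         else fisher_exact_2x2(tab)
    tibble(species = species, level = level,
           k_set = rs$k, n_set = rs$n, rate_set = rs$rate,
           k_bg = rb$k, n_bg = rb$n, rate_bg = rb$rate, p = p)
  }) |> bind_rows()
  cmp <- cmp |>
    left_join(dist, by = "species") |>
    group_by(.data$level) |>
    mutate(p_adj = p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    mutate(significant = .data$p < alpha,
           species = factor(.data$species, levels = dist$species),
           level = factor(.data$level, levels = levels)) |>
    arrange(.data$level, .data$species) |>
    dplyr::relocate("distance", .after = "species")
  rates <- cmp |>
    select("species", "distance", "level", dplyr::starts_with("k_"),
           dplyr::starts_with("n_"), dplyr::starts_with("rate_"),
           "p", "significant") |>
    tidyr::pivot_longer(c("k_set", "n_set", "rate_set",
                          "k_bg", "n_bg", "rate_bg"),
                        names_to = c(".value", "set"), names_sep = "_") |>
    mutate(set = ifelse(.data$set == "set", "target", "background"))
  structure(list(comparisons = cmp, rates = rates, distances = dist,
                 alpha = alpha, mode = mode, levels = levels),
            class = "ss_comparison")
}

#' @export
print.ss_comparison <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf("<ss_comparison> %d species x %d levels (alpha = %g, %s mode)\n",
              nrow(x$distances), length(x$levels), x$alpha, x$mode))
  cat(sprintf("  significant species at 'complete': %d/%d; at 'present': %d/%d\n",
              g$n_sig_complete, g$n_species, g$n_sig_present, g$n_species))
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-species comparison table
#'
#' @param x An `ss_comparison` object.
#' @param ... Unused.
#' @return The comparison tibble: one row per (species, level) with counts,
#'   rates, raw and BH-adjusted p-values and the significance flag.
#' @method tidy ss_comparison
#' @export
tidy.ss_comparison <- function(x, ...) x$comparisons

#' One-row summary of a set comparison
#'
#' @param x An `ss_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble: number of species, number significant at the
#'   `complete` and `present` levels, and how many of those significant
#'   species have the target below the background.
#' @method glance ss_comparison
#' @export
glance.ss_comparison <- function(x, ...) {
  cc <- x$comparisons
  at <- function(lv) cc[cc$level == lv, , drop = FALSE]
  comp <- at("complete"); pres <- at("present")
  tibble(
    n_species = nrow(x$distances),
    n_levels = length(x$levels),
    n_sig_complete = sum(comp$significant),
    n_sig_complete_lower = sum(comp$significant &
                                 comp$rate_set < comp$rate_bg),
    n_sig_present = sum(pres$significant),
    median_rate_gap_complete = stats::median(comp$rate_bg - comp$rate_set)
  )
}

#' Conservation-rate curves over phylogenetic distance
#'
#' Draws the characteristic two-set decay curves: conservation rate against
#' patristic distance from the reference, one panel per level, filled
#' points where the per-species test is significant.
#'
#' @param object An `ss_comparison` object.
#' @param levels Which levels to draw (default: `present` and `complete`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ss_comparison
#' @export
autoplot.ss_comparison <- function(object,
                                   levels = c("present", "complete"), ...) {
  dat <- object$rates |> filter(.data$level %in% levels)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$distance, y = .data$rate,
                                    colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$significant), size = 2) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                name = "p < alpha") +
    ggplot2::facet_wrap(~level) +
    ggplot2::labs(x = "patristic distance from reference",
                  y = "conservation rate", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ss_comparison
#' @param cmp An `ss_comparison` object.
#' @export
plot_conservation_curves <- function(cmp,
                                     levels = c("present", "complete")) {
  ggplot2::autoplot(cmp, levels = levels)
}
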