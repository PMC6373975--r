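#' Configuration for the synthetic HTT survey generator
#'
#' Bundles every knob of the synthetic-data module in one validated record.
#' Defaults describe a survey of the size and composition this pipeline is
#' designed for: 460 host species across 19 arthropod orders, two specimens
#' per species, 163 species flagged as having full reference genomes, and
#' three TE superfamilies (Copia, Jockey, Mariner). Smaller configurations
#' are used throughout the test suite; the statistical structure, not the
#' scale, is what downstream stages rely on.
#'
#' @param n_species Number of host species (tree tips). Must be >= 2.
#' @param n_orders Number of taxonomic orders; orders are monophyletic tip
#'   partitions of the host tree. Must satisfy `n_species >= n_orders >= 1`.
#' @param specimens_per_species Sequenced specimens per species (default 2;
#'   two independent specimens are what allows contamination to be ruled out
#'   downstream, hence the occurrence filter in clustering).
#' @param n_ref_species Number of tips flagged as full-genome reference
#'   species (>= 2 so at least one tree node can carry a reference dS
#'   distribution).
#' @param tree_age Root age of the host chronogram, in million years (My).
#' @param ds_rate Synonymous substitution rate, substitutions per synonymous
#'   site per My per lineage. The genomic dS of a species pair with MRCA age
#'   `t` is `2 * ds_rate * t`.
#' @param ds_noise_cv Coefficient of variation of the per-node reference dS
#'   distributions (housekeeping-gene spread around the clock expectation).
#' @param n_families_per_superfamily Vertically inherited TE families
#'   generated per superfamily.
#' @param superfamily_labels Character vector of superfamily names.
#' @param p_vertical_presence Probability that a species inside a family's
#'   anchor clade carries the family.
#' @param n_planted_ht Number of horizontal transfer events planted per
#'   superfamily, each in its own TE family.
#' @param hotspot_order Order label receiving an elevated transfer rate, or
#'   `NULL` for none.
#' @param hotspot_multiplier Sampling-weight multiplier (>= 1) applied to
#'   species of `hotspot_order` when drawing planted transfer endpoints.
#' @param seed Master integer seed; all stage-level randomness is derived
#'   from it through fixed stream offsets.
#' @param n_codons Codons per generated TE sequence (default 150, i.e.
#'   450 nt, comparable to a Mariner/Jockey amplicon).
#' @param panel_size Number of dS draws per reference node (default 1000).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_species = 12, n_orders = 3, n_ref_species = 4,
#'                   tree_age = 100, seed = 42)
#' cfg$n_orders
#' @export
sim_config <- function(n_species = 460,
                       n_orders = 19,
                       specimens_per_species = 2,
                       n_ref_species = 163,
                       tree_age = 500,
                       ds_rate = 0.003,
                       ds_noise_cv = 0.3,
                       n_families_per_superfamily = 50,
                       superfamily_labels = c("Copia", "Jockey", "Mariner"),
                       p_vertical_presence = 0.3,
                       n_planted_ht = 20,
                       hotspot_order = NULL,
                       hotspot_multiplier = 1,
                       seed = 1,
                       n_codons = 150,
                       panel_size = 1000) {
  cfg <- list(
    n_species = as.integer(n_species),
    n_orders = as.integer(n_orders),
    specimens_per_species = as.integer(specimens_per_species),
    n_ref_species = as.integer(n_ref_species),
    tree_age = as.numeric(tree_age),
    ds_rate = as.numeric(ds_rate),
    ds_noise_cv = as.numeric(ds_noise_cv),
    n_families_per_superfamily = as.integer(n_families_per_superfamily),
    superfamily_labels = as.character(superfamily_labels),
    p_vertical_presence = as.numeric(p_vertical_presence),
    n_planted_ht = as.integer(n_planted_ht),
    hotspot_order = if (is.null(hotspot_order)) NULL else as.character(hotspot_order),
    hotspot_multiplier = as.numeric(hotspot_multiplier),
    seed = as.integer(seed),
    n_codons = as.integer(n_codons),
    panel_size = as.integer(panel_size)
  )
  counts <- c("n_species", "n_orders", "specimens_per_species",
              "n_families_per_superfamily", "n_codons", "panel_size")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      config_error("'", f, "' must be a count >= 1")
  }
  if (cfg$n_planted_ht < 0L) config_error("'n_planted_ht' must be >= 0")
  if (cfg$n_species < 2L) config_error("'n_species' must be >= 2")
  if (cfg$n_orders > cfg$n_species)
    config_error("'n_orders' cannot exceed 'n_species'")
  if (cfg$n_ref_species < 2L) config_error("'n_ref_species' must be >= 2")
  if (cfg$n_ref_species > cfg$n_species)
    config_error("'n_ref_species' cannot exceed 'n_species'")
  if (cfg$p_vertical_presence < 0 || cfg$p_vertical_presence > 1)
    config_error("'p_vertical_presence' must be a probability in [0, 1]")
  if (cfg$hotspot_multiplier < 1)
    config_error("'hotspot_multiplier' must be >= 1")
  if (cfg$tree_age <= 0) config_error("'tree_age' must be positive")
  if (cfg$ds_rate < 0 || cfg$ds_noise_cv < 0)
    config_error("'ds_rate' and 'ds_noise_cv' must be non-negative")
  if (!is.null(cfg$hotspot_order) && length(cfg$hotspot_order) != 1L)
    config_error("'hotspot_order' must be a single order label or NULL")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic HTT survey configuration\n")
  cat(sprintf("  %d species / %d orders, %d specimens each, %d reference genomes\n",
              x$n_species, x$n_orders, x$specimens_per_species, x$n_ref_species))
  cat(sprintf("  chronogram age %g My, dS rate %g /site/My, reference CV %g\n",
              x$tree_age, x$ds_rate, x$ds_noise_cv))
  cat(sprintf("  superfamilies: %s (%d vertical families each, %d planted HTs)\n",
              paste(x$superfamily_labels, collapse = ", "),
              x$n_families_per_superfamily, x$n_planted_ht))
  if (!is.null(x$hotspot_order))
    cat(sprintf("  hotspot: %s at %gx transfer rate\n",
                x$hotspot_order, x$hotspot_multiplier))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
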