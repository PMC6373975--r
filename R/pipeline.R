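# End-to-end orchestration: synthetic generation (optional), clustering,
# divergence, detection, event inference, null model, reporting. Every
# intermediate is persisted as plain text so any stage can be re-run from
# its inputs, and a JSON manifest records configuration, seeds and
# per-stage record counts.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] for synthetic mode, or `NULL` to read inputs
#'   from files.
#' @param fasta,tree_file,tips_file,panel_file Input paths (ignored in
#'   synthetic mode).
#' @param outdir Output directory (created if missing).
#' @param min_identity,min_overlap_frac Family clustering thresholds
#'   (percent identity >= 80; alignment span >= 0.80 of the shorter
#'   sequence).
#' @param quantile Reference-distribution quantile for the outlier test
#'   (default 0.05).
#' @param n_scenarios Random HTT scenarios for per-species means
#'   (default 1000).
#' @param n_sims Null-model simulations per superfamily (default 1000).
#' @param distance_window Divergence-time window width in My (default 25).
#' @param seed Master seed for scenario and null-model streams.
#' @param use_truth_families Skip the hit-table/clustering stage and take
#'   family memberships from the generator's truth labels (synthetic mode
#'   only); useful when the question under study is detection or the null
#'   model, not clustering.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, fasta = NULL, tree_file = NULL,
                            tips_file = NULL, panel_file = NULL,
                            outdir = tempfile("httscan_run_"),
                            min_identity = 80, min_overlap_frac = 0.80,
                            quantile = 0.05, n_scenarios = 1000,
                            n_sims = 1000, distance_window = 25,
                            seed = 1, use_truth_families = FALSE) {
  if (min_identity <= 0 || min_identity > 100)
    config_error("'min_identity' must be in (0, 100]")
  if (min_overlap_frac <= 0 || min_overlap_frac > 1)
    config_error("'min_overlap_frac' must be in (0, 1]")
  if (quantile <= 0 || quantile > 1)
    config_error("'quantile' must be in (0, 1]")
  if (is.null(sim)) {
    paths <- list(fasta = fasta, tree_file = tree_file,
                  tips_file = tips_file, panel_file = panel_file)
    for (nm in names(paths)) {
      if (is.null(paths[[nm]]))
        config_error("non-synthetic mode requires '", nm, "'")
      if (!file.exists(paths[[nm]]))
        config_error("input file missing or not found: ", paths[[nm]])
    }
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  structure(list(sim = sim, fasta = fasta, tree_file = tree_file,
                 tips_file = tips_file, panel_file = panel_file,
                 outdir = outdir, min_identity = min_identity,
                 min_overlap_frac = min_overlap_frac, quantile = quantile,
                 n_scenarios = as.integer(n_scenarios),
                 n_sims = as.integer(n_sims),
                 distance_window = distance_window,
                 seed = as.integer(seed),
                 use_truth_families = isTRUE(use_truth_families)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Top-level keys map to [pipeline_config()] arguments; an optional `sim`
#' mapping holds [sim_config()] arguments for synthetic mode.
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (e.g. from CLI flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  do.call(pipeline_config, y)
}

#' Run the full HTT inference pipeline
#'
#' Executes, in order: synthetic data generation (when `config$sim` is
#' set), pairwise hit computation and single-linkage clustering, the
#' specimen-occurrence filter, per-family minimum dS, the conservative
#' reference-matched outlier test, minimal-event counting with scenario
#' sampling, the constrained permutation null per superfamily, and the
#' summary table. Every stage writes its table under `config$outdir`; a
#' `manifest.json` records the configuration, seeds and per-stage record
#' counts. Identical configurations and seeds reproduce identical output
#' files.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `pipeline_result` with elements `tree`, `panel`,
#'   `dataset` (synthetic mode), `families`, `pairwise`, `detection`,
#'   `scenarios`, `null` (per superfamily), `summary`, `manifest`,
#'   `outdir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(seed = config$seed,
                   thresholds = config[c("min_identity", "min_overlap_frac",
                                         "quantile", "n_scenarios", "n_sims",
                                         "distance_window")],
                   stages = list())
  seed_comment <- sprintf("seed: %d", config$seed)
  stage <- function(name, n) {
    manifest$stages[[name]] <<- list(records = n)
    say("[%s] %d records", name, n)
  }

  dataset <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    tree <- generate_host_tree(sim)
    panel <- generate_reference_panel(tree, sim)
    dataset <- generate_te_dataset(tree, sim)
    write_host_tree(tree, file.path(config$outdir, "host_tree.nwk"),
                    file.path(config$outdir, "tips.tsv"),
                    comments = seed_comment)
    write_reference_panel(panel, file.path(config$outdir, "panel.tsv"),
                          comments = seed_comment)
    write_te_fasta(dataset$seqs, file.path(config$outdir, "sequences.fasta"))
    write_tsv(dataset$truth, file.path(config$outdir, "truth.tsv"),
              comments = seed_comment)
    seqs <- dataset$seqs
    meta <- dataset$meta
    stage("simulate", length(seqs))
  } else {
    tree <- read_host_tree(config$tree_file, config$tips_file)
    panel <- read_reference_panel(config$panel_file, tree)
    fa <- read_te_fasta(config$fasta)
    seqs <- fa$seqs
    meta <- fa$meta
    stage("load", length(seqs))
  }

  if (config$use_truth_families && !is.null(dataset)) {
    families <- meta[, c("family", "superfamily", "species", "specimen",
                         "seq_id")]
    class(families) <- c("te_families", "data.frame")
    stage("cluster(truth)", nrow(families))
  } else {
    sf_map <- stats::setNames(meta$superfamily, meta$seq_id)
    hits <- generate_hit_table(seqs, sf_map)
    write_hit_table(hits, file.path(config$outdir, "hits.tsv"),
                    comments = seed_comment)
    stage("hits", nrow(hits))
    families <- cluster_single_linkage(hits, meta,
                                       min_identity = config$min_identity,
                                       min_overlap_frac = config$min_overlap_frac)
    stage("cluster", nrow(families))
  }
  families <- filter_family_occurrences(families)
  write_families(families, file.path(config$outdir, "families.tsv"),
                 comments = seed_comment)
  stage("filter", nrow(families))

  pairwise <- family_pairwise_ds(families, seqs)
  write_tsv(pairwise, file.path(config$outdir, "pairwise_ds.tsv"),
            comments = seed_comment)
  stage("divergence", nrow(pairwise))

  detection <- detect_ht_links(pairwise, tree, panel)
  write_tsv(detection$links, file.path(config$outdir, "ht_links.tsv"),
            comments = seed_comment)
  stage("detect", nrow(detection$links))

  superfamilies <- sort(unique(families$superfamily))
  elig <- eligible_reference_nodes(tree)
  scenarios <- list()
  nulls <- list()
  n_events <- stats::setNames(integer(length(superfamilies)), superfamilies)
  for (sf in superfamilies) {
    fe <- family_ht_edges(detection$links, sf)
    scenarios[[sf]] <- sample_scenarios(fe, tree,
                                        n_scenarios = config$n_scenarios,
                                        seed = config$seed)
    n_events[sf] <- scenarios[[sf]]$n_events
    carriers <- sort(unique(families$species[families$superfamily == sf]))
    if (length(fe) > 0 && length(carriers) >= 2) {
      forb <- forbidden_pairs(tree, carriers, elig)
      nulls[[sf]] <- simulate_null(fe, tree, carriers, forb,
                                   n_sims = config$n_sims,
                                   seed = child_seed(config$seed, 7000L + match(sf, superfamilies)),
                                   return_sims = TRUE)
      write_tsv(cbind(superfamily = sf, nulls[[sf]]$table),
                file.path(config$outdir,
                          sprintf("null_comparison_%s.tsv", sf)),
                comments = seed_comment)
    }
    means <- data.frame(species = names(scenarios[[sf]]$species_means),
                        mean_htt = unname(scenarios[[sf]]$species_means))
    write_tsv(means,
              file.path(config$outdir, sprintf("species_means_%s.tsv", sf)),
              comments = seed_comment)
  }
  stage("events", sum(n_events))
  stage("null", length(nulls))

  fam_counts <- tapply(families$family, families$superfamily,
                       function(x) length(unique(x)))
  present <- tapply(families$species, families$superfamily,
                    function(x) length(unique(x)))
  summary_tab <- summarize_htt(
    n_families = as.integer(fam_counts[superfamilies]),
    n_events = n_events,
    species_present = as.integer(present[superfamilies]),
    n_species_total = length(tree$phy$tip.label),
    superfamilies = superfamilies)
  write_tsv(summary_tab, file.path(config$outdir, "summary.tsv"),
            comments = seed_comment)
  stage("report", nrow(summary_tab))

  manifest$files <- list.files(config$outdir)
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(tree = tree, panel = panel, dataset = dataset,
                 families = families, pairwise = pairwise,
                 detection = detection, scenarios = scenarios,
                 null = nulls, summary = summary_tab, manifest = manifest,
                 outdir = config$outdir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("HTT pipeline result in ", x$outdir, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Per-superfamily HTT summary table
#'
#' Computes, per superfamily: the number of families, the minimal number of
#' transfer events, the transfer rate (events per family), each
#' superfamily's percent share of all events and of all families, and —
#' when species presence counts are supplied — the percent of surveyed
#' species carrying the superfamily and the mean number of families per
#' carrier species. A totals row is appended. Values are stored at full
#' precision; rounding is applied for display only.
#'
#' @param n_families Integer vector of family counts per superfamily.
#' @param n_events Integer vector of minimal transfer events per
#'   superfamily.
#' @param species_present Optional integer vector: species carrying each
#'   superfamily.
#' @param n_species_total Optional total number of surveyed species.
#' @param superfamilies Superfamily names (default: names of `n_families`).
#' @return A data frame of class `htt_summary`.
#' @examples
#' summarize_htt(n_families = c(Copia = 696, Jockey = 3876, Mariner = 453),
#'               n_events = c(123, 34, 175))
#' @export
summarize_htt <- function(n_families, n_events, species_present = NULL,
                          n_species_total = NULL,
                          superfamilies = names(n_families)) {
  if (is.null(superfamilies))
    superfamilies <- paste0("superfamily", seq_along(n_families))
  stopifnot(length(n_events) == length(n_families))
  tot_fam <- sum(n_families)
  tot_ev <- sum(n_events)
  tab <- data.frame(
    superfamily = superfamilies,
    n_families = as.numeric(n_families),
    min_htt = as.numeric(n_events),
    htt_rate = as.numeric(n_events) / as.numeric(n_families),
    event_share_pct = if (tot_ev > 0) 100 * n_events / tot_ev else
      rep(NA_real_, length(n_events)),
    family_share_pct = 100 * n_families / tot_fam,
    stringsAsFactors = FALSE)
  if (!is.null(species_present)) {
    tab$species_present <- as.numeric(species_present)
    tab$families_per_carrier <- tab$n_families / tab$species_present
    if (!is.null(n_species_total))
      tab$prevalence_pct <- 100 * tab$species_present / n_species_total
  }
  total <- data.frame(superfamily = "total", n_families = tot_fam,
                      min_htt = tot_ev, htt_rate = tot_ev / tot_fam,
                      event_share_pct = if (tot_ev > 0) 100 else NA_real_,
                      family_share_pct = 100, stringsAsFactors = FALSE)
  for (extra in setdiff(names(tab), names(total))) total[[extra]] <- NA_real_
  out <- rbind(tab, total)
  rownames(out) <- NULL
  class(out) <- c("htt_summary", "data.frame")
  out
}

#' @export
print.htt_summary <- function(x, ...) {
  disp <- as.data.frame(x)
  disp$htt_rate <- sprintf("%.2f", disp$htt_rate)
  for (col in intersect(c("event_share_pct", "family_share_pct",
                          "prevalence_pct"), names(disp)))
    disp[[col]] <- ifelse(is.na(disp[[col]]), "",
                          sprintf("%d%%", round(disp[[col]])))
  if ("families_per_carrier" %in% names(disp))
    disp$families_per_carrier <- ifelse(is.na(disp$families_per_carrier), "",
                                        sprintf("%.1f", disp$families_per_carrier))
  print(disp, row.names = FALSE)
  invisible(x)
}
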