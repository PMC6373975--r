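# Synthetic-data generator: trees, panels, sequence sets, hit tables.

test_that("generated host trees are ultrametric with monophyletic orders", {
  for (seed in c(1, 17)) {
    cfg <- tiny_config(seed = seed, n_species = 25, n_orders = 5,
                       n_ref_species = 6)
    tr <- generate_host_tree(cfg)
    phy <- tr$phy
    depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
    expect_lt(diff(range(depths)) / max(depths), 1e-9)
    expect_equal(max(depths), cfg$tree_age)
    expect_length(unique(tr$order), cfg$n_orders)
    for (ord in unique(tr$order)) {
      members <- names(tr$order)[tr$order == ord]
      if (length(members) == 1) next
      mrca <- ape::getMRCA(phy, members)
      clade_tips <- phy$tip.label[phangorn::Descendants(phy, mrca, "tips")[[1]]]
      expect_setequal(clade_tips, members)
    }
    expect_equal(sum(tr$is_ref), cfg$n_ref_species)
    expect_gt(length(eligible_reference_nodes(tr)), 0)
  }
})

test_that("the smallest tree has two tips and a root at the requested age", {
  cfg <- tiny_config(n_species = 2, n_orders = 1, n_ref_species = 2,
                     tree_age = 100)
  tr <- generate_host_tree(cfg)
  expect_length(tr$phy$tip.label, 2)
  expect_equal(max(tr$age), 100)
})

test_that("19 orders come out monophyletic with named arthropod labels", {
  cfg <- tiny_config(n_species = 60, n_orders = 19, n_ref_species = 10,
                     seed = 3)
  tr <- generate_host_tree(cfg)
  expect_length(unique(tr$order), 19)
  expect_true("Lepidoptera" %in% tr$order)
  # largest order carries the first label (ties permit equal-size peers)
  sizes <- table(tr$order)
  expect_equal(unname(sizes[["Lepidoptera"]]), max(sizes))
})

test_that("impossible reference placement is a configuration error", {
  expect_error(tiny_config(n_species = 4, n_ref_species = 9),
               class = "httscan_config_error")
})

test_that("reference panel means scale linearly with node age", {
  cfg <- tiny_config(ds_noise_cv = 0, n_ref_species = 16, panel_size = 50)
  tr <- generate_host_tree(cfg)
  pan <- generate_reference_panel(tr, cfg)
  means <- vapply(pan$samples, mean, 1)
  ages <- pan$nodes$age
  # with zero CV every sample is the deterministic clock expectation
  expect_equal(unname(means), 2 * cfg$ds_rate * ages, tolerance = 1e-12)
  # ratio check between any two nodes follows the age ratio
  i <- which.max(ages); j <- which.min(ages)
  expect_equal(means[[i]] / means[[j]], ages[i] / ages[j], tolerance = 1e-9)
})

test_that("panel sampling matches its stated moments at cv > 0", {
  cfg <- tiny_config(ds_rate = 0.005, tree_age = 100, ds_noise_cv = 0.2,
                     n_ref_species = 16, panel_size = 1000, seed = 5)
  tr <- generate_host_tree(cfg)
  pan <- generate_reference_panel(tr, cfg)
  root_lab <- pan$nodes$label[which.max(pan$nodes$age)]
  x <- pan$samples[[root_lab]]
  m <- 2 * 0.005 * 100  # root at 100 My -> mean 1.0
  se <- (0.2 * m) / sqrt(length(x))
  expect_lt(abs(mean(x) - m), 3 * se)
  expect_equal(stats::sd(x) / mean(x), 0.2, tolerance = 0.1)
  expect_true(all(x >= 0))
})

test_that("TE dataset construction invariants hold", {
  cfg <- tiny_config(specimens_per_species = 2)
  tr <- generate_host_tree(cfg)
  ds <- generate_te_dataset(tr, cfg)
  occ <- table(ds$meta$family, ds$meta$species)
  expect_true(all(occ[occ > 0] == 2))
  # every planted pair appears exactly once in the truth table
  h <- ds$truth[ds$truth$mechanism == "horizontal", ]
  expect_equal(nrow(h), cfg$n_planted_ht * length(cfg$superfamily_labels))
  expect_false(anyDuplicated(h$family) > 0)
  # vertical records carry no event node; planted dS below 20% of genomic
  v <- ds$truth[ds$truth$mechanism == "vertical", ]
  expect_true(all(is.na(v$event_node)))
  expect_true(all(h$ds_target < 0.2 * h$ds_genomic))
  # sequence lengths in frame
  expect_true(all(nchar(ds$seqs) == 3 * cfg$n_codons))
})

test_that("a null configuration plants nothing", {
  cfg <- tiny_config(n_planted_ht = 0)
  ds <- generate_te_dataset(generate_host_tree(cfg), cfg)
  expect_true(all(ds$truth$mechanism == "vertical"))
})

test_that("hotspot weighting concentrates planted endpoints in the hotspot", {
  cfg <- tiny_config(n_species = 40, n_orders = 4, n_ref_species = 20,
                     n_planted_ht = 30, n_families_per_superfamily = 1,
                     superfamily_labels = "Copia",
                     hotspot_order = "Lepidoptera", hotspot_multiplier = 5,
                     seed = 9)
  tr <- generate_host_tree(cfg)
  ds <- generate_te_dataset(tr, cfg)
  h <- ds$truth[ds$truth$mechanism == "horizontal", ]
  ends <- c(h$species_a, h$species_b)
  by_order <- table(tr$order[ends])
  expect_equal(names(which.max(by_order)), "Lepidoptera")
  expect_gt(by_order[["Lepidoptera"]], length(ends) / 2 * 0.6)
})

test_that("regeneration with the same seed is byte-identical", {
  cfg <- tiny_config(seed = 123)
  d1 <- generate_te_dataset(generate_host_tree(cfg), cfg)
  d2 <- generate_te_dataset(generate_host_tree(cfg), cfg)
  expect_identical(d1$seqs, d2$seqs)
  expect_identical(d1$truth, d2$truth)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_te_fasta(d1$seqs, f1); write_te_fasta(d2$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("hit tables behave on identity, divergence and degenerate input", {
  s300 <- paste(rep("ACGTGA", 50), collapse = "")
  hits <- generate_hit_table(c(a = s300, b = s300))
  expect_equal(nrow(hits), 2)  # both orientations
  expect_equal(hits$pident, c(100, 100))
  expect_equal(hits$length, c(300L, 300L))

  # ~30% mismatches push identity below the clustering threshold
  v <- strsplit(s300, "")[[1]]
  idx <- seq(1, 300, length.out = 90)
  v[idx] <- chartr("ACGT", "CATG", v[idx])
  hits2 <- generate_hit_table(c(a = s300, b = paste(v, collapse = "")))
  expect_lt(max(hits2$pident), 80)

  expect_equal(nrow(generate_hit_table(c(a = s300))), 0)
  expect_equal(nrow(generate_hit_table(character(0))), 0)
})
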