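# NG86 synonymous divergence, redundancy collapse, minimum-dS reduction.

test_that("dS is zero for identical sequences and symmetric in its arguments", {
  set.seed(1)
  a <- paste(httscan:::random_codon_seq(60), collapse = "")
  b <- paste(httscan:::evolve_jc(strsplit(a, "")[[1]], 0.2), collapse = "")
  expect_equal(ds_ng86(a, a)$ds, 0)
  expect_equal(ds_ng86(a, b)$ds, ds_ng86(b, a)$ds)
  expect_gt(ds_ng86(a, b)$ds, 0)
})

test_that("dS matches the hand-computed fixture and the naive oracle", {
  # 60 alanine codons; two synonymous third-position changes.
  # S = 60 (each GCN third position is 4-fold), Sd = 2, pS = 1/30,
  # dS = -(3/4) log(1 - 4/90) = 0.03409678.
  a <- codon_run("GCT", 60)
  b <- paste0("GCC", "GCA", codon_run("GCT", 58))
  got <- ds_ng86(a, b)
  expect_equal(got$s_sites, 60)
  expect_equal(got$ds, 0.0340967805576, tolerance = 1e-6)
  orc <- oracle_ng86(a, b)
  expect_equal(got$ds, orc$ds, tolerance = 1e-12)
  expect_equal(got$s_sites, orc$s, tolerance = 1e-12)
})

test_that("dS agrees with the naive oracle on random mixed-codon pairs", {
  set.seed(11)
  for (rep in 1:12) {
    a <- paste(httscan:::random_codon_seq(25), collapse = "")
    vb <- httscan:::evolve_jc(strsplit(a, "")[[1]], stats::runif(1, 0, 0.6))
    # introduce a couple of first/second position changes too, avoiding stops
    for (k in sample(seq(1, 73, by = 3), 2)) {
      vb[k] <- sample(setdiff(c("A", "C", "G", "T"), vb[k]), 1)
      cod <- paste(vb[k - (k - 1) %% 3 + 0:2], collapse = "")
      if (Biostrings::GENETIC_CODE[[cod]] == "*") vb[k] <- strsplit(a, "")[[1]][k]
    }
    b <- paste(vb, collapse = "")
    got <- ds_ng86(a, b)
    orc <- oracle_ng86(a, b)
    expect_equal(got$defined, orc$defined)
    if (got$defined) expect_equal(got$ds, orc$ds, tolerance = 1e-9)
  }
})

test_that("saturation and short alignments flag undefined, not an error", {
  a <- codon_run("GCT", 60)
  # flip all third positions twice over -> pS near 1 (use maximal divergence)
  b <- codon_run("GCA", 30)  # 30 codons only: length mismatch must error
  expect_error(ds_ng86(a, b), class = "httscan_input_error")
  expect_error(ds_ng86("GCTA", "GCTA"), class = "httscan_input_error")

  sat <- ds_ng86(codon_run("GCT", 60), codon_run("GCA", 60))
  expect_false(sat$defined)  # pS = 1 >= 0.75
  expect_true(is.na(sat$ds))

  short <- ds_ng86("GCTGCT", "GCCGCT")  # S = 2 < 10 sites
  expect_false(short$defined)
})

test_that("dS grows monotonically as synonymous differences accumulate", {
  base <- strsplit(codon_run("GCT", 60), "")[[1]]
  prev <- -1
  for (k in c(0, 2, 5, 10, 20)) {
    v <- base
    if (k > 0) v[3 * seq_len(k)] <- "C"  # GCT -> GCC, synonymous
    d <- ds_ng86(paste(base, collapse = ""), paste(v, collapse = ""))$ds
    expect_gt(d, prev)
    prev <- d
  }
})

test_that("gap and ambiguity codons are skipped, not counted", {
  a <- paste0("GCT", "GCT", codon_run("GCT", 28))
  b <- paste0("---", "GCN", codon_run("GCT", 28))
  got <- ds_ng86(a, b)
  expect_equal(got$s_sites, 28)
  expect_equal(got$ds, 0)
})

test_that("specimen collapse merges only near-identical rows within a specimen", {
  s <- codon_run("GCT", 40)
  s_longer <- paste0(s, "GCT")
  # three identical rows of one specimen -> single (longest) survivor
  seqs <- c(r1 = paste0(s, "---"), r2 = s_longer, r3 = paste0(s, "---"))
  meta <- manual_meta(c("r1", "r2", "r3"), "S1", specimen = c("p1", "p1", "p1"))
  out <- collapse_specimen_redundancy(seqs, meta)
  expect_equal(names(out$seqs), "r2")

  # two specimens with one row each: untouched
  seqs2 <- c(r1 = s, r2 = s)
  meta2 <- manual_meta(c("r1", "r2"), "S1", specimen = c("p1", "p2"))
  expect_length(collapse_specimen_redundancy(seqs2, meta2)$seqs, 2)

  # 90% identity within one specimen stays below the 99% linkage threshold
  v <- strsplit(s, "")[[1]]
  v[seq(3, 36, by = 3)] <- "C"
  seqs3 <- c(r1 = s, r2 = paste(v, collapse = ""))
  meta3 <- manual_meta(c("r1", "r2"), "S1", specimen = c("p1", "p1"))
  expect_length(collapse_specimen_redundancy(seqs3, meta3)$seqs, 2)
})

test_that("minimum dS picks the smallest defined cross-species value", {
  a1 <- codon_run("GCT", 60)
  b1 <- strsplit(a1, "")[[1]]; b1[3 * 1:12] <- "C"     # farther
  b2 <- strsplit(a1, "")[[1]]; b2[3 * 1:3] <- "C"      # closer
  seqs <- c(a1 = a1, b1 = paste(b1, collapse = ""),
            b2 = paste(b2, collapse = ""))
  meta <- manual_meta(c("a1", "b1", "b2"), c("A", "B", "B"))
  res <- min_pairwise_ds(seqs, meta)
  expect_equal(nrow(res), 1)
  expect_equal(res$seq_b, "b2")
  expect_equal(res$ds, ds_ng86(a1, seqs[["b2"]])$ds)

  # single-species family yields nothing
  expect_equal(nrow(min_pairwise_ds(seqs[1], meta[1, ])), 0)
})

test_that("minimum dS equals the brute-force minimum over all cross pairs", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    species <- sample(c("A", "B", "C"), n, replace = TRUE)
    base <- httscan:::random_codon_seq(40)
    seqs <- stats::setNames(vapply(seq_len(n), function(i)
      paste(httscan:::evolve_jc(base, stats::runif(1, 0, 0.5)), collapse = ""),
      ""), sprintf("q%d", seq_len(n)))
    meta <- manual_meta(names(seqs), species)
    res <- min_pairwise_ds(seqs, meta)
    for (i in seq_len(nrow(res))) {
      ids_a <- meta$seq_id[meta$species == res$species_a[i]]
      ids_b <- meta$seq_id[meta$species == res$species_b[i]]
      vals <- c()
      for (x in ids_a) for (y in ids_b) {
        r <- ds_ng86(seqs[[x]], seqs[[y]])
        if (r$defined) vals <- c(vals, r$ds)
      }
      if (res$defined[i]) expect_equal(res$ds[i], min(vals))
      else expect_length(vals, 0)
    }
  }
})

test_that("on vertical-only data minimum dS tracks genomic dS per pair", {
  cfg <- tiny_config(n_species = 10, n_orders = 2, n_ref_species = 4,
                     n_planted_ht = 0, n_families_per_superfamily = 40,
                     superfamily_labels = "Copia",
                     p_vertical_presence = 0.8, seed = 13)
  tr <- generate_host_tree(cfg)
  ds <- generate_te_dataset(tr, cfg)
  fams <- ds$meta[, c("family", "superfamily", "species", "specimen", "seq_id")]
  class(fams) <- c("te_families", "data.frame")
  pw <- family_pairwise_ds(filter_family_occurrences(fams), ds$seqs)
  mr <- ape::mrca(tr$phy)
  pw$genomic <- 2 * cfg$ds_rate * tr$age[mr[cbind(pw$species_a, pw$species_b)]]
  med <- tapply(seq_len(nrow(pw)), paste(pw$species_a, pw$species_b),
                function(i) stats::median(pw$ds[i], na.rm = TRUE))
  gen <- tapply(pw$genomic, paste(pw$species_a, pw$species_b), unique)
  shared <- names(med)[!is.na(med) & gen > 0.05]  # enough signal to compare
  rel_err <- abs(med[shared] - gen[shared]) / gen[shared]
  expect_lt(stats::median(rel_err), 0.2)
})
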