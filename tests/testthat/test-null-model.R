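# Constrained permutation null: relabeling, repair, envelopes.

six_tree <- function() {
  phy <- ape::read.tree(text =
    "(((A:10,B:10):20,(C:15,D:15):15):30,(E:25,F:25):35);")
  host_tree(phy,
            order = stats::setNames(c("O1", "O1", "O1", "O1", "O2", "O2"),
                                    phy$tip.label),
            is_ref = stats::setNames(rep(TRUE, 6), phy$tip.label))
}

test_that("permutation preserves the degree multiset and avoids forbidden pairs", {
  tr <- six_tree()
  fe <- list(f1 = rbind(c("A", "C"), c("A", "D")), f2 = rbind(c("B", "E")))
  carriers <- tr$phy$tip.label
  forb <- rbind(c("E", "F"))
  deg <- sort(table(c("A", "A", "B", "C", "D", "E")))
  for (seed in 1:20) {
    p <- permute_network(fe, carriers, forb, seed = seed)
    expect_true(p$clean)
    rel <- do.call(rbind, p$family_edges)
    expect_identical(unname(sort(table(as.vector(rel)))), unname(deg))
    expect_false(any(httscan:::pair_key(rel[, 1], rel[, 2]) %in%
                       httscan:::pair_key("E", "F")))
    # bijectivity
    expect_false(anyDuplicated(p$map) > 0)
  }
  # empty network is trivially valid
  expect_true(permute_network(list(), carriers, forb, seed = 1)$clean)
})

test_that("with all but one pair forbidden the surviving draw is forced", {
  tr <- six_tree()
  carriers <- c("A", "B", "C", "D")
  all_pairs <- t(utils::combn(carriers, 2))
  forb <- all_pairs[!(all_pairs[, 1] == "A" & all_pairs[, 2] == "B"), ]
  fe <- list(f1 = rbind(c("C", "D")))
  for (seed in 1:10) {
    p <- permute_network(fe, carriers, forb, seed = seed, retry_cap = 500)
    expect_true(p$clean)
    e <- p$family_edges$f1
    expect_setequal(as.vector(e), c("A", "B"))
  }
})

test_that("repair replaces forbidden edges among authorized unconnected pairs", {
  # identity on a network that has a forbidden edge forces repair
  fe <- list(f1 = rbind(c("A", "B"), c("A", "C"), c("A", "D")))
  forb <- rbind(c("A", "B"))
  rep1 <- repair_forbidden(fe, forb, seed = 1)
  e <- rep1$f1
  expect_equal(nrow(e), 3)
  keys <- httscan:::pair_key(e[, 1], e[, 2])
  expect_false(httscan:::pair_key("A", "B") %in% keys)
  expect_false(anyDuplicated(keys) > 0)

  # with exactly one authorized unconnected pair the replacement is forced
  fe2 <- list(f1 = rbind(c("A", "B"), c("A", "C"), c("A", "D"), c("B", "C")))
  forb2 <- rbind(c("A", "B"), c("B", "D"))
  rep2 <- repair_forbidden(fe2, forb2, seed = 3)
  keys2 <- httscan:::pair_key(rep2$f1[, 1], rep2$f1[, 2])
  expect_true(httscan:::pair_key("C", "D") %in% keys2)
  expect_equal(nrow(rep2$f1), 4)

  # no forbidden edges: identity
  expect_identical(repair_forbidden(fe, rbind(c("X", "Y")), seed = 1), fe)

  # edge count preserved over many seeded repairs
  for (seed in 1:50) {
    r <- repair_forbidden(fe2, forb2, seed = seed)
    expect_equal(nrow(r$f1), 4)
    k <- httscan:::pair_key(r$f1[, 1], r$f1[, 2])
    expect_false(any(k %in% httscan:::pair_key(forb2[, 1], forb2[, 2])))
  }
})

test_that("the degenerate identity null brackets the observation exactly", {
  tr <- six_tree()
  fe <- list(f1 = rbind(c("A", "C"), c("A", "D")), f2 = rbind(c("E", "F")))
  nc <- simulate_null(fe, tr, tr$phy$tip.label, NULL, n_sims = 20, seed = 1,
                      identity = TRUE)
  expect_equal(nc$table$observed, nc$table$sim_mean)
  expect_false(any(nc$table$excess | nc$table$deficit))
  expect_equal(nc$bias, 1)
})

test_that("null simulations are valid: no forbidden edges, preserved degrees, normalized totals", {
  tr <- six_tree()
  fe <- list(f1 = rbind(c("A", "C"), c("A", "D")), f2 = rbind(c("B", "E")))
  forb <- forbidden_pairs(tr, tr$phy$tip.label)  # all-ref tree: none
  expect_equal(nrow(forb), 0)
  forb <- rbind(c("E", "F"), c("A", "F"))
  nc <- simulate_null(fe, tr, tr$phy$tip.label, forb, n_sims = 200, seed = 5,
                      return_sims = TRUE)
  d <- nc$diagnostics
  expect_true(all(d$n_forbidden == 0))
  expect_true(all(d$degree_preserved))
  expect_equal(d$scaled_total_events, rep(nc$observed_total, nrow(d)),
               tolerance = 1e-12)
  # per-simulation scaled per-order endpoint counts total 2 x observed events
  expect_equal(unname(colSums(nc$sims)),
               rep(2 * nc$observed_total, ncol(nc$sims)), tolerance = 1e-9)
  # determinism under the master-seed contract
  nc2 <- simulate_null(fe, tr, tr$phy$tip.label, forb, n_sims = 200, seed = 5,
                       return_sims = TRUE)
  expect_identical(nc$sims, nc2$sims)
})

test_that("the quantile envelope widens (weakly) with fewer simulations", {
  tr <- six_tree()
  fe <- list(f1 = rbind(c("A", "C"), c("A", "D")), f2 = rbind(c("B", "E")))
  nc_big <- simulate_null(fe, tr, tr$phy$tip.label, NULL, n_sims = 1000,
                          seed = 9, return_sims = TRUE)
  width_big <- nc_big$table$q975 - nc_big$table$q025
  # average width over disjoint 100-simulation subsamples: empirical tail
  # quantiles sit further out at small n, so widths do not shrink on average
  widths <- vapply(seq(0, 900, by = 100), function(off) {
    sub <- nc_big$sims[, off + 1:100, drop = FALSE]
    mean(apply(sub, 1, function(x)
      diff(stats::quantile(x, c(0.025, 0.975)))))
  }, 1)
  expect_gte(mean(widths), mean(width_big) - 1e-9)
})

test_that("phylogenetically clustered networks inflate simulated totals", {
  # observed edges all inside one cherry-rich clade: a single deep event
  # explains several of them, while random relabelings scatter the edges
  # and need more events.
  phy <- ape::read.tree(text = paste0(
    "(((A:5,B:5):5,(C:5,D:5):5):40,((E:20,F:20):10,(G:20,H:20):10):20);"))
  tr <- host_tree(phy,
                  order = stats::setNames(rep("O1", 8), phy$tip.label),
                  is_ref = stats::setNames(rep(TRUE, 8), phy$tip.label))
  fe <- list(f1 = rbind(c("A", "C"), c("A", "D"), c("B", "C"), c("B", "D")))
  nc <- simulate_null(fe, tr, phy$tip.label, NULL, n_sims = 300, seed = 11)
  expect_equal(nc$observed_total, 1)  # one node explains all four edges
  expect_gt(nc$bias, 1)
})

test_that("distance profiles bin by event age and normalize by expectation", {
  obs <- c(30, 40, 45)  # all in the 25-50 My window
  sims <- replicate(50, c(10, 35, 60, 85), simplify = FALSE)  # uniform-ish
  dp <- distance_profile(obs, sims, window = 25)
  expect_equal(dp$observed[dp$window_start == 25], 3)
  expect_gt(dp$ratio[dp$window_start == 25], 1)
  expect_true(all(dp$ratio[dp$window_start != 25] < 1, na.rm = TRUE))
  # observed == expected gives unit ratios
  dp2 <- distance_profile(c(10, 35), replicate(10, c(10, 35), simplify = FALSE),
                          window = 25)
  expect_equal(dp2$ratio[1:2], c(1, 1))
})

test_that("planted transfer ages restricted to young pairs fall off with distance", {
  set.seed(61)
  young <- stats::runif(40, 0, 45)
  sims <- replicate(100, stats::runif(40, 0, 150), simplify = FALSE)
  dp <- distance_profile(young, sims, window = 50)
  r <- dp$ratio[dp$expected > 0]
  expect_gt(r[1], r[2])
  expect_gte(r[2], r[3])
})
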