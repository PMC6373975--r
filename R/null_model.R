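# Constrained permutation null model for per-taxon HTT excess.
#
# A simulated dataset relabels the species of the observed HT network with
# a uniformly drawn same-size subset of the superfamily's carriers, which
# preserves the per-species transfer-degree distribution and the network
# structure. Draws are rejected while any relabeled edge lands on a
# forbidden (untestable-by-construction) pair; if rejection keeps failing
# (dense networks), forbidden edges are instead repaired by re-drawing them
# among authorized unconnected node pairs, preserving the edge count.

forbidden_keys <- function(forbidden) {
  if (is.null(forbidden) || NROW(forbidden) == 0L) return(character(0))
  forbidden <- as.matrix(forbidden)
  unique(pair_key(forbidden[, 1], forbidden[, 2]))
}

#' Compute the untestable (forbidden) species pairs of a host tree
#'
#' Species pairs whose MRCA subtree contains no eligible reference node can
#' never be flagged as horizontal in the real data, so the null model must
#' not connect them either.
#'
#' @param tree A [host_tree()].
#' @param species Character vector of species to consider (default: all
#'   tips).
#' @param eligible Node set from [eligible_reference_nodes()].
#' @return Two-column character matrix of unordered untestable pairs.
#' @export
forbidden_pairs <- function(tree, species = tree$phy$tip.label,
                            eligible = eligible_reference_nodes(tree)) {
  species <- sort(unique(species))
  out <- list()
  if (length(species) >= 2L) {
    pairs <- utils::combn(species, 2)
    for (i in seq_len(ncol(pairs))) {
      if (is.na(match_reference(tree, pairs[1, i], pairs[2, i], eligible)))
        out[[length(out) + 1L]] <- pairs[, i]
    }
  }
  if (length(out) == 0L) return(matrix(character(0), ncol = 2))
  do.call(rbind, out)
}

relabel_edges <- function(family_edges, map) {
  lapply(family_edges, function(m)
    cbind(unname(map[m[, 1]]), unname(map[m[, 2]])))
}

all_edge_keys <- function(family_edges) {
  m <- do.call(rbind, family_edges)
  if (is.null(m) || nrow(m) == 0L) return(character(0))
  pair_key(m[, 1], m[, 2])
}

#' Randomly relabel an HT network onto the carrier species
#'
#' Draws a bijection from the network's species to a uniformly chosen
#' same-size subset of `carriers` and applies it to every edge, resampling
#' until no edge lands on a forbidden pair (up to `retry_cap` attempts).
#' The relabeled network is isomorphic to the input and has the identical
#' degree multiset.
#'
#' @param family_edges Named list (by family) of two-column species-pair
#'   matrices: the observed network with its per-family edge attribution.
#' @param carriers Species carrying at least one family of the superfamily;
#'   must contain every network node.
#' @param forbidden Two-column matrix of untestable pairs (see
#'   [forbidden_pairs()]).
#' @param seed Integer seed.
#' @param retry_cap Rejection attempts before giving up (default 1000).
#' @param identity Use the identity relabeling (degenerate null, for
#'   validation).
#' @return A list: `family_edges` (relabeled), `map` (named character
#'   bijection), `attempts`, `clean` (logical: no forbidden edge; when
#'   `FALSE` the caller must repair).
#' @export
permute_network <- function(family_edges, carriers, forbidden = NULL,
                            seed = 1, retry_cap = 1000, identity = FALSE) {
  nodes <- sort(unique(as.vector(do.call(rbind, family_edges))))
  if (length(setdiff(nodes, carriers)))
    input_error("network node(s) outside the carrier set: ",
                paste(utils::head(setdiff(nodes, carriers), 3), collapse = ", "))
  fkeys <- forbidden_keys(forbidden)
  if (length(nodes) == 0L)
    return(list(family_edges = family_edges,
                map = stats::setNames(character(0), character(0)),
                attempts = 0L, clean = TRUE))
  if (identity) {
    map <- stats::setNames(nodes, nodes)
    rel <- relabel_edges(family_edges, map)
    return(list(family_edges = rel, map = map, attempts = 1L,
                clean = !any(all_edge_keys(rel) %in% fkeys)))
  }
  set.seed(child_seed(seed, 505L))
  for (attempt in seq_len(retry_cap)) {
    map <- stats::setNames(sample(carriers, length(nodes)), nodes)
    rel <- relabel_edges(family_edges, map)
    if (!any(all_edge_keys(rel) %in% fkeys))
      return(list(family_edges = rel, map = map, attempts = attempt,
                  clean = TRUE))
  }
  list(family_edges = rel, map = map, attempts = retry_cap, clean = FALSE)
}

#' Repair forbidden edges of a relabeled network
#'
#' Replaces each forbidden edge, sequentially, by an edge drawn uniformly
#' among unordered pairs of network nodes that are neither forbidden nor
#' already connected (connectivity updated after each replacement). The
#' total edge count is preserved; the network configuration may change
#' slightly.
#'
#' @param family_edges Relabeled per-family edge lists containing forbidden
#'   edges.
#' @param forbidden Two-column matrix of untestable pairs.
#' @param seed Integer seed.
#' @return Repaired per-family edge lists.
#' @export
repair_forbidden <- function(family_edges, forbidden, seed = 1) {
  fkeys <- forbidden_keys(forbidden)
  nodes <- sort(unique(as.vector(do.call(rbind, family_edges))))
  if (length(nodes) < 2L) return(family_edges)
  cand <- utils::combn(nodes, 2)
  cand_keys <- pair_key(cand[1, ], cand[2, ])
  connected <- unique(all_edge_keys(family_edges))
  set.seed(child_seed(seed, 606L))
  for (f in names(family_edges)) {
    m <- family_edges[[f]]
    for (i in seq_len(nrow(m))) {
      k <- pair_key(m[i, 1], m[i, 2])
      if (!(k %in% fkeys)) next
      ok <- which(!(cand_keys %in% fkeys) & !(cand_keys %in% connected))
      if (length(ok) == 0L)
        stop("network repair failed: no authorized unconnected pair left (",
             length(nodes), " nodes, ", length(connected), " edges)",
             call. = FALSE)
      pick <- ok[if (length(ok) == 1L) 1L else sample.int(length(ok), 1L)]
      m[i, ] <- cand[, pick]
      connected <- c(setdiff(connected, k), cand_keys[pick])
    }
    family_edges[[f]] <- m
  }
  family_edges
}

# Per-order endpoint expectations for a per-family edge list.
order_endpoint_counts <- function(family_edges, tree) {
  events <- collect_events(family_edges, tree)
  mu <- expected_endpoint_counts(events, tree$phy$tip.label)
  ords <- sort(unique(tree$order))
  per_order <- tapply(mu, factor(tree$order[names(mu)], levels = ords), sum)
  per_order[is.na(per_order)] <- 0
  list(per_order = per_order, total_events = length(events),
       ages = vapply(events, function(e) e$age, 1))
}

#' Simulate the constrained permutation null and compare per-order counts
#'
#' Produces `n_sims` relabeled datasets of one superfamily's observed HT
#' network ([permute_network()], with [repair_forbidden()] as fallback),
#' recounts minimal events and per-order expected endpoint counts on each,
#' rescales every simulation so its total event count matches the observed
#' total (the phylogenetic clustering of real networks otherwise inflates
#' simulated counts), and summarizes the per-order simulated distribution
#' as mean and 2.5% / 97.5% quantiles next to the observed count.
#'
#' @param family_edges Observed per-family HT edge lists (named list of
#'   two-column species matrices).
#' @param tree A [host_tree()].
#' @param carriers Species carrying the superfamily.
#' @param forbidden Two-column matrix of untestable pairs.
#' @param n_sims Number of simulated datasets (default 1000).
#' @param seed Integer master seed; simulation `i` depends only on child
#'   seed `i`.
#' @param retry_cap Rejection attempts before switching to repair mode.
#' @param identity Force the identity relabeling in every simulation
#'   (degenerate null, for validation).
#' @param return_sims Attach per-simulation per-order counts and event ages.
#' @return A list of class `null_comparison`: `table` (per order: observed,
#'   simulated mean, q025, q975, normalization mean, `excess` flag),
#'   `observed_total`, `sim_total_mean`, `bias` (mean simulated / observed
#'   total before normalization), `diagnostics` (per simulation: attempts,
#'   repaired, forbidden edges in final network, degree preservation
#'   pre-repair, raw totals, factors), and optionally `sims`.
#' @export
simulate_null <- function(family_edges, tree, carriers, forbidden = NULL,
                          n_sims = 1000, seed = 1, retry_cap = 1000,
                          identity = FALSE, return_sims = FALSE) {
  obs <- order_endpoint_counts(family_edges, tree)
  ords <- names(obs$per_order)
  fkeys <- forbidden_keys(forbidden)
  obs_degrees <- sort(table(as.vector(do.call(rbind, family_edges))))
  sim_mat <- matrix(NA_real_, nrow = length(ords), ncol = n_sims,
                    dimnames = list(ords, NULL))
  diag_rows <- vector("list", n_sims)
  sim_ages <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    si <- child_seed(seed, i)
    perm <- permute_network(family_edges, carriers, forbidden, seed = si,
                            retry_cap = retry_cap, identity = identity)
    deg_ok <- identical(
      unname(sort(table(as.vector(do.call(rbind, perm$family_edges))))),
      unname(obs_degrees))
    edges_i <- perm$family_edges
    repaired <- FALSE
    if (!perm$clean) {
      edges_i <- repair_forbidden(edges_i, forbidden, seed = si)
      repaired <- TRUE
    }
    n_forbidden <- sum(all_edge_keys(edges_i) %in% fkeys)
    cnt <- order_endpoint_counts(edges_i, tree)
    factor_i <- if (cnt$total_events > 0)
      obs$total_events / cnt$total_events else 0
    sim_mat[, i] <- as.numeric(cnt$per_order) * factor_i
    sim_ages[[i]] <- cnt$ages
    diag_rows[[i]] <- data.frame(
      sim = i, attempts = perm$attempts, repaired = repaired,
      n_forbidden = n_forbidden, degree_preserved = deg_ok,
      raw_total_events = cnt$total_events, factor = factor_i,
      scaled_total_events = cnt$total_events * factor_i)
  }
  diagnostics <- do.call(rbind, diag_rows)
  tab <- data.frame(
    order = ords,
    observed = as.numeric(obs$per_order),
    sim_mean = rowMeans(sim_mat),
    q025 = apply(sim_mat, 1, stats::quantile, probs = 0.025, names = FALSE),
    q975 = apply(sim_mat, 1, stats::quantile, probs = 0.975, names = FALSE),
    stringsAsFactors = FALSE)
  tab$excess <- tab$observed > tab$q975
  tab$deficit <- tab$observed < tab$q025
  res <- list(table = tab,
              observed_total = obs$total_events,
              sim_total_mean = mean(diagnostics$raw_total_events),
              bias = mean(diagnostics$raw_total_events) /
                max(obs$total_events, 1),
              observed_ages = obs$ages,
              diagnostics = diagnostics)
  if (return_sims) {
    res$sims <- sim_mat
    res$sim_ages <- sim_ages
  }
  structure(res, class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("Permutation null: %d simulations, %d observed events (sim mean %.1f before normalization)\n",
              nrow(x$diagnostics), x$observed_total, x$sim_total_mean))
  flagged <- x$table$order[x$table$excess]
  cat(if (length(flagged))
    paste0("  orders in excess of the 97.5% envelope: ",
           paste(flagged, collapse = ", "), "\n")
    else "  no order exceeds its 97.5% envelope\n")
  invisible(x)
}

#' Observed/expected transfer counts by divergence-time window
#'
#' Bins observed events by the MRCA age of their (assigned) species pair
#' into consecutive windows of `window` My, computes the per-window mean of
#' the simulated event counts, and reports the observed/expected ratio
#' (NA where the expectation is zero).
#'
#' @param observed_ages Numeric vector of observed event-node ages (My),
#'   e.g. `simulate_null(...)$observed_ages`.
#' @param sim_ages List of per-simulation event-age vectors (from
#'   `simulate_null(..., return_sims = TRUE)$sim_ages`).
#' @param window Window width in My (default 25).
#' @return Data frame: `window_start`, `window_end`, `observed`,
#'   `expected`, `ratio`.
#' @export
distance_profile <- function(observed_ages, sim_ages, window = 25) {
  top <- max(c(observed_ages, unlist(sim_ages), 0))
  breaks <- seq(0, ceiling(top / window) * window + window, by = window)
  bin <- function(x) tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                              nbins = length(breaks) - 1L)
  obs <- bin(observed_ages)
  exp_counts <- rowMeans(vapply(sim_ages, bin, numeric(length(breaks) - 1L)))
  data.frame(window_start = breaks[-length(breaks)],
             window_end = breaks[-1],
             observed = obs,
             expected = exp_counts,
             ratio = ifelse(exp_counts > 0, obs / exp_counts, NA_real_))
}

#' Plot a per-order observed-vs-null comparison
#'
#' Draws, for each order, the observed endpoint count as a point and the
#' simulated 2.5-97.5% envelope as a horizontal segment.
#'
#' @param x A `null_comparison`.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_null_comparison <- function(x, main = "Observed vs simulated HTT counts",
                                 ...) {
  tab <- x$table
  n <- nrow(tab)
  graphics::plot(c(0, max(tab$observed, tab$q975) * 1.05), c(0.5, n + 0.5),
                 type = "n", ylab = "", xlab = "HTT endpoint count",
                 yaxt = "n", main = main, ...)
  graphics::axis(2, at = seq_len(n), labels = tab$order, las = 2,
                 cex.axis = 0.7)
  graphics::segments(tab$q025, seq_len(n), tab$q975, seq_len(n), lwd = 2,
                     col = "grey50")
  graphics::points(tab$observed, seq_len(n), pch = 19,
                   col = ifelse(tab$excess, "firebrick", "black"))
  invisible(x)
}
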