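# Minimal-event counting on the host chronogram and random HTT scenarios.
#
# One transfer into the common ancestor of a recently diverged clade can
# explain many present-day shared pairs; the minimal count therefore
# attributes one event to every node of a family's host subtree whose two
# (or more) descending clades are connected by at least one
# horizontal-verdict species pair.

#' Host subtree spanned by a set of species
#'
#' The minimal induced subtree of the tips, with unbranched internal nodes
#' suppressed and node ages preserved (the result of pruning an ultrametric
#' chronogram is ultrametric).
#'
#' @param tree A [host_tree()].
#' @param species Character vector of tip labels (>= 1).
#' @return A `phylo` object (a single-tip tree degenerates to a one-edge
#'   stub).
#' @export
family_subtree <- function(tree, species) {
  phy <- tree$phy
  missing <- setdiff(species, phy$tip.label)
  if (length(missing))
    input_error("species absent from tree: ",
                paste(utils::head(missing, 3), collapse = ", "))
  ape::keep.tip(phy, unique(species))
}

#' Count the minimal number of transfer events explaining a family's links
#'
#' Scans every internal node of the family's host subtree and counts one
#' event if at least one horizontal-verdict species pair has its two
#' endpoints in two different child clades of that node. For each event
#' node the crossing edges (the candidate realizations of the event) are
#' retained for scenario sampling.
#'
#' @param subtree A `phylo` from [family_subtree()] (or any rooted tree
#'   whose tips include all edge endpoints).
#' @param ht_edges Two-column character matrix of species pairs with
#'   horizontal verdicts (may have zero rows).
#' @return A list of class `event_count`: `n_events`, `event_nodes`
#'   (subtree node numbers), `event_ages` (My), and `crossing` (list of
#'   edge-row indices per event node).
#' @export
minimal_events <- function(subtree, ht_edges) {
  ht_edges <- as.matrix(ht_edges)
  if (nrow(ht_edges) == 0L)
    return(structure(list(n_events = 0L, event_nodes = integer(0),
                          event_ages = numeric(0), crossing = list()),
                     class = "event_count"))
  bad <- setdiff(as.vector(ht_edges), subtree$tip.label)
  if (length(bad))
    input_error("HT edge endpoint(s) not in subtree: ",
                paste(utils::head(bad, 3), collapse = ", "))
  ntip <- length(subtree$tip.label)
  ages <- node_ages(subtree)
  a_idx <- match(ht_edges[, 1], subtree$tip.label)
  b_idx <- match(ht_edges[, 2], subtree$tip.label)
  event_nodes <- integer(0)
  crossing <- list()
  for (nd in seq(ntip + 1L, ntip + subtree$Nnode)) {
    kids <- node_children(subtree, nd)
    clade_of <- integer(ntip)
    for (k in seq_along(kids)) clade_of[tips_under(subtree, kids[k])] <- k
    cross <- which(clade_of[a_idx] != 0L & clade_of[b_idx] != 0L &
                     clade_of[a_idx] != clade_of[b_idx])
    if (length(cross)) {
      event_nodes <- c(event_nodes, nd)
      crossing[[as.character(nd)]] <- cross
    }
  }
  structure(list(n_events = length(event_nodes), event_nodes = event_nodes,
                 event_ages = ages[event_nodes], crossing = crossing),
            class = "event_count")
}

#' @export
print.event_count <- function(x, ...) {
  cat(sprintf("Minimal HTT events: %d\n", x$n_events))
  invisible(x)
}

# Flatten per-family event counts into one event list: each element holds
# the family, the event age and the crossing species-pair matrix.
collect_events <- function(family_edges, tree) {
  events <- list()
  for (f in names(family_edges)) {
    edges <- family_edges[[f]]
    if (is.null(edges) || nrow(edges) == 0L) next
    sub <- family_subtree(tree, unique(as.vector(edges)))
    ec <- minimal_events(sub, edges)
    for (i in seq_along(ec$event_nodes)) {
      events[[length(events) + 1L]] <- list(
        family = f,
        age = ec$event_ages[i],
        edges = edges[ec$crossing[[i]], , drop = FALSE])
    }
  }
  events
}

#' Sample random HTT scenarios over the inferred events
#'
#' Each inferred event is an ancestral transfer whose concrete endpoints
#' are unknown; a scenario realizes every event as one species pair drawn
#' uniformly among the pairs crossing its node. Repeating this
#' `n_scenarios` times yields, per species, a mean number of transfer
#' endpoints attributed to it, and per order the sum of its members'
#' counts.
#'
#' @param family_edges Named list (by family) of two-column species-pair
#'   matrices with horizontal verdicts.
#' @param tree A [host_tree()].
#' @param n_scenarios Number of scenarios (default 1000).
#' @param seed Integer seed for the scenario stream.
#' @return A list of class `scenario_set`: `counts` (species x scenario
#'   endpoint-count matrix), `species_means`, `order_means`,
#'   `species_involved_means` (mean number of distinct species touched per
#'   order), `n_events`.
#' @export
sample_scenarios <- function(family_edges, tree, n_scenarios = 1000,
                             seed = 1) {
  events <- collect_events(family_edges, tree)
  species <- tree$phy$tip.label
  counts <- matrix(0L, nrow = length(species), ncol = n_scenarios,
                   dimnames = list(species, NULL))
  set.seed(child_seed(seed, 404L))
  for (ev in events) {
    k <- nrow(ev$edges)
    idx <- if (k == 1L) rep(1L, n_scenarios)
           else sample.int(k, n_scenarios, replace = TRUE)
    ai <- match(ev$edges[idx, 1], species)
    bi <- match(ev$edges[idx, 2], species)
    sc <- seq_len(n_scenarios)
    counts[cbind(ai, sc)] <- counts[cbind(ai, sc)] + 1L
    counts[cbind(bi, sc)] <- counts[cbind(bi, sc)] + 1L
  }
  species_means <- rowMeans(counts)
  ords <- sort(unique(tree$order[species]))
  order_fac <- factor(tree$order[species], levels = ords)
  order_means <- tapply(species_means, order_fac, sum)
  inv <- vapply(seq_len(n_scenarios), function(s)
    as.numeric(tapply(counts[, s] > 0, order_fac, sum)),
    numeric(length(ords)))
  involved <- stats::setNames(rowMeans(matrix(inv, nrow = length(ords))), ords)
  structure(list(counts = counts,
                 species_means = species_means,
                 order_means = order_means,
                 species_involved_means = involved,
                 n_events = length(events)),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("Scenario set: %d events, %d scenarios\n",
              x$n_events, ncol(x$counts)))
  invisible(x)
}

# Exact per-species expected endpoint counts (the n_scenarios -> Inf limit
# of the scenario means): each crossing edge of an event is chosen with
# probability 1/k, so a species' expectation is its appearance count
# weighted by 1/k, summed over events.
expected_endpoint_counts <- function(events, species) {
  mu <- stats::setNames(numeric(length(species)), species)
  for (ev in events) {
    k <- nrow(ev$edges)
    tab <- table(c(ev$edges[, 1], ev$edges[, 2]))
    mu[names(tab)] <- mu[names(tab)] + as.numeric(tab) / k
  }
  mu
}
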