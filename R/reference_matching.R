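# Conservative reference matching and the dS outlier test.
#
# The null distribution for "these two species inherited this TE
# vertically" is the housekeeping-gene dS distribution at a tree node. To
# stay conservative, the node chosen for a species pair is the oldest
# reference node *inside* the subtree rooted at their MRCA: its expected dS
# is never larger than the pair's true genomic dS, so its 5% quantile can
# only under-call horizontal transfer, never over-call it.

#' Internal nodes carrying a reference dS distribution
#'
#' Exactly the internal nodes with full-genome reference species in at
#' least two distinct child subtrees: at such a node a reference genome
#' pair diverges, so an empirical dS distribution exists for it.
#'
#' @param tree A [host_tree()].
#' @return Integer vector of node numbers (possibly empty).
#' @export
eligible_reference_nodes <- function(tree) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  ref_tips <- which(tree$is_ref[phy$tip.label])
  if (length(ref_tips) < 2L) return(integer(0))
  internal <- seq(ntip + 1L, ntip + phy$Nnode)
  has_ref <- function(node) any(tips_under(phy, node) %in% ref_tips)
  elig <- vapply(internal, function(nd) {
    sum(vapply(node_children(phy, nd), has_ref, TRUE)) >= 2L
  }, TRUE)
  internal[elig]
}

#' Match a species pair to its conservative reference node
#'
#' Among eligible reference nodes lying within the subtree rooted at
#' `MRCA(species_a, species_b)` (including that node itself), returns the
#' one of maximal age. The matched node is therefore never older than the
#' pair's MRCA. At equal age, nodes on the path between the two species are
#' preferred, then the smallest node number (for determinism). Returns `NA`
#' when no eligible node lies in the subtree: the pair is untestable.
#'
#' @param tree A [host_tree()].
#' @param species_a,species_b Tip labels.
#' @param eligible Integer node set from [eligible_reference_nodes()]
#'   (computed if missing).
#' @return A node number, or `NA_integer_` if the pair is untestable.
#' @export
match_reference <- function(tree, species_a, species_b,
                            eligible = eligible_reference_nodes(tree)) {
  phy <- tree$phy
  a <- match(species_a, phy$tip.label)
  b <- match(species_b, phy$tip.label)
  if (is.na(a) || is.na(b))
    input_error("unknown species: ",
                paste(c(species_a, species_b)[is.na(c(a, b))], collapse = ", "))
  if (length(eligible) == 0L) return(NA_integer_)
  mrca <- ape::getMRCA(phy, c(a, b))
  inside <- eligible[eligible == mrca |
                       eligible %in% phangorn::Descendants(phy, mrca, "all")]
  if (length(inside) == 0L) return(NA_integer_)
  ages <- tree$age[inside]
  top <- inside[ages == max(ages)]
  if (length(top) == 1L) return(top)
  on_path <- unique(c(mrca,
                      phangorn::Ancestors(phy, a, "all"),
                      phangorn::Ancestors(phy, b, "all")))
  pref <- top[top %in% on_path]
  if (length(pref)) return(min(pref))
  min(top)
}

#' Flag species pairs whose TE dS rejects vertical inheritance
#'
#' Maps each per-(family, species pair) minimum dS to a verdict:
#' `horizontal` when the pair is testable and its TE dS is strictly lower
#' than the 5% quantile of the matched reference distribution, `vertical`
#' when testable and not lower (a dS exactly equal to the quantile is
#' vertical), and `untestable` when no reference node exists inside the
#' pair's MRCA subtree or the dS estimate is undefined (saturation argues
#' for, not against, vertical inheritance). Horizontal verdicts are then
#' assembled into one undirected network per superfamily whose edges carry
#' their contributing families.
#'
#' @param pairwise Data frame from [family_pairwise_ds()] (columns
#'   `family`, `superfamily`, `species_a`, `species_b`, `ds`, `defined`).
#' @param tree A [host_tree()].
#' @param panel A `reference_panel`.
#' @return A list of class `ht_detection`: `links` (one row per input pair
#'   with `node`, `node_age`, `q05`, `verdict`), `networks` (named list of
#'   `ht_network` objects by superfamily), and `summary` (counts of pairs
#'   tested / testable / rejected).
#' @export
detect_ht_links <- function(pairwise, tree, panel) {
  stopifnot(inherits(tree, "host_tree"), inherits(panel, "reference_panel"))
  elig <- panel$nodes$node
  q05_by_node <- stats::setNames(panel$nodes$q05, panel$nodes$node)
  memo <- new.env(parent = emptyenv())
  links <- pairwise
  links$node <- NA_character_
  links$node_age <- NA_real_
  links$q05 <- NA_real_
  links$verdict <- "untestable"
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$species_a[i]
    b <- pairwise$species_b[i]
    key <- pair_key(a, b)
    node <- memo[[key]]
    if (is.null(node)) {
      node <- match_reference(tree, a, b, elig)
      assign(key, node, envir = memo)
    }
    if (is.na(node)) next
    links$node[i] <- node_label(tree, node)
    links$node_age[i] <- tree$age[node]
    links$q05[i] <- q05_by_node[[as.character(node)]]
    if (!isTRUE(pairwise$defined[i]) || is.na(pairwise$ds[i])) next
    links$verdict[i] <- if (pairwise$ds[i] < links$q05[i]) "horizontal"
                        else "vertical"
  }
  networks <- lapply(split(links[links$verdict == "horizontal", , drop = FALSE],
                           links$superfamily[links$verdict == "horizontal"]),
                     build_ht_network)
  summary <- data.frame(
    n_pairs = nrow(links),
    n_testable = sum(links$verdict != "untestable"),
    n_horizontal = sum(links$verdict == "horizontal"))
  structure(list(links = links, networks = networks, summary = summary),
            class = "ht_detection")
}

build_ht_network <- function(h_links) {
  sf <- if (nrow(h_links)) h_links$superfamily[1] else NA_character_
  key <- pair_key(h_links$species_a, h_links$species_b)
  fams <- tapply(h_links$family, key, function(x)
    paste(sort(unique(x)), collapse = ";"))
  first <- !duplicated(key)
  edges <- data.frame(
    species_a = pmin(h_links$species_a, h_links$species_b)[first],
    species_b = pmax(h_links$species_a, h_links$species_b)[first],
    families = unname(fams[key[first]]),
    n_links = unname(tapply(key, key, length)[key[first]]),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$species_a, edges$species_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(superfamily = sf,
                 nodes = sort(unique(c(edges$species_a, edges$species_b))),
                 edges = edges),
            class = "ht_network")
}

#' @export
print.ht_network <- function(x, ...) {
  cat(sprintf("HT network (%s): %d species, %d edges\n",
              x$superfamily, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
print.ht_detection <- function(x, ...) {
  s <- x$summary
  cat(sprintf("HTT detection: %d species pairs, %d testable, %d horizontal\n",
              s$n_pairs, s$n_testable, s$n_horizontal))
  invisible(x)
}

# Per-family HT edge lists (2-column character matrices) for one
# superfamily, from the detection links.
family_ht_edges <- function(links, sf) {
  h <- links[links$verdict == "horizontal" & links$superfamily == sf, ,
             drop = FALSE]
  lapply(split(h, h$family), function(d)
    cbind(d$species_a, d$species_b))
}
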