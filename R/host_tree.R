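# Host chronogram container and synthetic tree generator.

.arthropod_orders <- c(
  "Lepidoptera", "Diptera", "Coleoptera", "Hymenoptera", "Hemiptera",
  "Araneae", "Psocoptera", "Thysanoptera", "Orthoptera", "Mantodea",
  "Blattodea", "Isoptera", "Amphipoda", "Scolopendromorpha",
  "Sarcoptiformes", "Ixodida", "Trombidiformes", "Archaeognatha", "Odonata"
)

order_label_set <- function(k) {
  if (k <= length(.arthropod_orders)) return(.arthropod_orders[seq_len(k)])
  c(.arthropod_orders,
    sprintf("Order%02d", seq(length(.arthropod_orders) + 1L, k)))
}

# Children of an internal node in a phylo object.
node_children <- function(phy, node) {
  phy$edge[phy$edge[, 1] == node, 2]
}

# Tip indices below a node (the node itself if it is a tip).
tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  phangorn::Descendants(phy, node, type = "tips")[[1]]
}

# Node ages (My before present) for an ultrametric phylo, indexed by node
# number (tips first, then internal nodes).
node_ages <- function(phy) {
  d <- ape::node.depth.edgelength(phy)
  a <- max(d) - d
  a[abs(a) < 1e-9] <- 0
  a
}

#' Construct a host chronogram object
#'
#' Wraps an ultrametric `phylo` tree together with the per-tip taxonomic
#' order map and full-genome reference flags used throughout the pipeline.
#'
#' @param phy An ultrametric rooted `phylo` object with branch lengths in
#'   million years.
#' @param order Named character vector: taxonomic order per tip label.
#' @param is_ref Named logical vector: whether each tip is a full-genome
#'   reference species.
#' @return An object of class `host_tree`: a list with elements `phy`,
#'   `order`, `is_ref` and `age` (node ages in My, indexed by node number).
#' @export
host_tree <- function(phy, order, is_ref) {
  if (!inherits(phy, "phylo")) input_error("'phy' must be a phylo object")
  tips <- phy$tip.label
  if (!setequal(names(order), tips))
    input_error("'order' must be named by the tree's tip labels")
  if (!setequal(names(is_ref), tips))
    input_error("'is_ref' must be named by the tree's tip labels")
  age <- node_ages(phy)
  tip_ages <- age[seq_along(tips)]
  if (max(abs(tip_ages)) > 1e-6 * max(age))
    input_error("tree is not ultrametric (tip ages differ)")
  if (is.null(phy$node.label) || anyDuplicated(phy$node.label)) {
    phy$node.label <- paste0("N", seq_len(phy$Nnode) + length(tips))
  }
  structure(
    list(phy = phy,
         order = order[tips],
         is_ref = is_ref[tips],
         age = age),
    class = "host_tree"
  )
}

#' @export
print.host_tree <- function(x, ...) {
  cat(sprintf("Host chronogram: %d species, %d orders, %d reference genomes, root age %.1f My\n",
              length(x$phy$tip.label), length(unique(x$order)),
              sum(x$is_ref), max(x$age)))
  invisible(x)
}

# Label <-> node-number helpers (internal nodes carry labels "N<number>"
# assigned at construction; arbitrary input labels are also honoured).
node_label <- function(tree, node) {
  ntip <- length(tree$phy$tip.label)
  ifelse(node <= ntip, tree$phy$tip.label[node],
         tree$phy$node.label[node - ntip])
}

node_from_label <- function(tree, label) {
  ntip <- length(tree$phy$tip.label)
  i <- match(label, tree$phy$node.label)
  ifelse(is.na(i), match(label, tree$phy$tip.label), i + ntip)
}

#' Generate a synthetic host chronogram
#'
#' Draws a pure-birth (Yule) tree conditioned on the number of species,
#' rescales it so the root sits at `config$tree_age` My, carves the tips
#' into `config$n_orders` monophyletic orders by repeatedly splitting the
#' largest clade, and flags `config$n_ref_species` tips as full-genome
#' reference species such that at least one internal node has reference
#' descendants on both sides (so a reference dS distribution exists
#' somewhere on the tree).
#'
#' Order labels are assigned to clades in decreasing size, so the first
#' label (Lepidoptera under the default label set) is always the largest
#' order, mirroring the composition of a typical field sample.
#'
#' @param config A [sim_config()].
#' @return A [host_tree()] object.
#' @examples
#' tr <- generate_host_tree(sim_config(n_species = 8, n_orders = 2,
#'                                     n_ref_species = 3, seed = 7))
#' table(tr$order)
#' @export
generate_host_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_ref_species > config$n_species)
    config_error("cannot place ", config$n_ref_species,
                 " reference species on ", config$n_species, " tips")
  set.seed(child_seed(config$seed, 101L))
  n <- config$n_species
  phy <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (config$tree_age / depth)
  phy$tip.label <- sprintf("OTU%03d", seq_len(n))
  phy$node.label <- paste0("N", seq_len(phy$Nnode) + n)

  # Partition tips into monophyletic orders: start from the root clade and
  # repeatedly split the largest splittable clade until n_orders remain.
  clades <- n + 1L  # root node
  while (length(clades) < config$n_orders) {
    sizes <- vapply(clades, function(nd) length(tips_under(phy, nd)), 1L)
    splittable <- clades > n
    cand <- which(splittable & sizes == max(sizes[splittable]))
    pick <- clades[cand[which.min(clades[cand])]]
    clades <- c(setdiff(clades, pick), node_children(phy, pick))
  }
  sizes <- vapply(clades, function(nd) length(tips_under(phy, nd)), 1L)
  ord <- order(-sizes, clades)
  labels <- order_label_set(config$n_orders)
  order_map <- character(n)
  for (i in seq_along(ord)) {
    order_map[tips_under(phy, clades[ord[i]])] <- labels[i]
  }
  names(order_map) <- phy$tip.label

  # Reference flags: random tips, forced to straddle the root when >= 2.
  refs <- sort(sample.int(n, config$n_ref_species))
  root_kids <- node_children(phy, n + 1L)
  left <- tips_under(phy, root_kids[1])
  if (all(refs %in% left)) {
    right <- setdiff(seq_len(n), left)
    refs[1] <- right[sample.int(length(right), 1)]
  } else if (!any(refs %in% left)) {
    refs[1] <- left[sample.int(length(left), 1)]
  }
  is_ref <- stats::setNames(seq_len(n) %in% refs, phy$tip.label)

  host_tree(phy, order_map, is_ref)
}

#' Write a host chronogram to Newick plus a tip-attribute table
#'
#' @param tree A [host_tree()].
#' @param tree_path Output Newick path (node labels retained, branch lengths
#'   in My).
#' @param tips_path Output TSV path with columns `tip`, `order`, `is_ref`.
#' @param comments Comment lines for the TSV header.
#' @return Invisibly, `tree_path`.
#' @export
write_host_tree <- function(tree, tree_path, tips_path, comments = NULL) {
  ape::write.tree(tree$phy, file = tree_path)
  write_tsv(data.frame(tip = tree$phy$tip.label,
                       order = unname(tree$order),
                       is_ref = unname(tree$is_ref)),
            tips_path, comments = comments)
  invisible(tree_path)
}

#' Read a host chronogram from Newick plus a tip-attribute table
#'
#' @param tree_path Newick file with branch lengths in My.
#' @param tips_path TSV with columns `tip`, `order`, `is_ref`.
#' @return A [host_tree()].
#' @export
read_host_tree <- function(tree_path, tips_path) {
  if (!file.exists(tree_path)) input_error("tree file not found: ", tree_path)
  phy <- ape::read.tree(tree_path)
  tips <- read_tsv(tips_path)
  host_tree(phy,
            stats::setNames(as.character(tips$order), tips$tip),
            stats::setNames(as.logical(tips$is_ref), tips$tip))
}
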