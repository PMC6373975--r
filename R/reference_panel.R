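# Per-node reference dS distributions (housekeeping-gene null).

#' Lower empirical 5% quantile (order statistic, no interpolation)
#'
#' Returns the smallest sample value `v` such that at least a fraction `q`
#' of the sample is `<= v`. This order-statistic convention is conservative:
#' it never falls below any interpolated quantile convention evaluated on
#' the same sample, so it can only make the downstream horizontal-transfer
#' test stricter.
#'
#' @param sample Non-empty numeric vector.
#' @param q Quantile level (default 0.05).
#' @return A single number from `sample`.
#' @examples
#' quantile05(1:100)  # 5
#' @export
quantile05 <- function(sample, q = 0.05) {
  if (length(sample) == 0L) input_error("empty reference sample")
  s <- sort(sample)
  s[max(1L, ceiling(q * length(s)))]
}

#' Generate a synthetic reference dS panel
#'
#' For every tree node that separates full-genome reference species into at
#' least two child subtrees (see [eligible_reference_nodes()]), draws a
#' sample of dS values emulating pairwise housekeeping-gene divergence
#' between the reference genomes diverging at that node. Samples are gamma
#' distributed with mean `2 * ds_rate * node_age` and coefficient of
#' variation `ds_noise_cv` (a degenerate point mass when the CV is 0),
#' truncated at zero by construction.
#'
#' @param tree A [host_tree()].
#' @param config A [sim_config()]; uses `ds_rate`, `ds_noise_cv`,
#'   `panel_size` and `seed`.
#' @return An object of class `reference_panel`: list with `nodes` (data
#'   frame: `node`, `label`, `age`, `q05`, `n`) and `samples` (named list of
#'   numeric vectors keyed by node label).
#' @export
generate_reference_panel <- function(tree, config) {
  stopifnot(inherits(tree, "host_tree"), inherits(config, "sim_config"))
  elig <- eligible_reference_nodes(tree)
  if (length(elig) == 0L)
    config_error("no tree node separates two reference lineages; ",
                 "cannot build a reference panel")
  set.seed(child_seed(config$seed, 202L))
  cv <- config$ds_noise_cv
  samples <- list()
  rows <- vector("list", length(elig))
  for (i in seq_along(elig)) {
    node <- elig[i]
    lab <- node_label(tree, node)
    m <- 2 * config$ds_rate * tree$age[node]
    x <- if (cv == 0 || m == 0) {
      rep(m, config$panel_size)
    } else {
      stats::rgamma(config$panel_size, shape = 1 / cv^2, scale = m * cv^2)
    }
    samples[[lab]] <- x
    rows[[i]] <- data.frame(node = node, label = lab, age = tree$age[node],
                            q05 = quantile05(x), n = length(x))
  }
  structure(list(nodes = do.call(rbind, rows), samples = samples),
            class = "reference_panel")
}

#' Assemble a reference panel from raw per-node samples
#'
#' @param samples Named list of non-empty numeric dS vectors keyed by node
#'   label of the host tree.
#' @param tree A [host_tree()] supplying node ages.
#' @return A `reference_panel`.
#' @export
reference_panel <- function(samples, tree) {
  if (length(samples) == 0L) input_error("empty reference panel")
  nodes <- vapply(names(samples), function(lab) node_from_label(tree, lab), 1L)
  if (anyNA(nodes))
    input_error("panel node label(s) not found in tree: ",
                paste(names(samples)[is.na(nodes)], collapse = ", "))
  rows <- data.frame(node = unname(nodes), label = names(samples),
                     age = tree$age[unname(nodes)],
                     q05 = vapply(samples, quantile05, 1),
                     n = lengths(samples))
  rownames(rows) <- NULL
  structure(list(nodes = rows, samples = samples), class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("Reference dS panel: %d nodes, %d samples each, node ages %.1f-%.1f My\n",
              nrow(x$nodes), max(x$nodes$n), min(x$nodes$age), max(x$nodes$age)))
  invisible(x)
}

#' Write a reference panel as long-format TSV (one row per sample value)
#'
#' @param panel A `reference_panel`.
#' @param path Output path.
#' @param comments Comment header lines.
#' @return Invisibly, `path`.
#' @export
write_reference_panel <- function(panel, path, comments = NULL) {
  df <- data.frame(
    node = rep(names(panel$samples), lengths(panel$samples)),
    ds = unlist(panel$samples, use.names = FALSE)
  )
  write_tsv(df, path, comments = comments)
}

#' Read a reference panel from long-format TSV
#'
#' @param path TSV with columns `node` (node label) and `ds`.
#' @param tree The [host_tree()] the node labels refer to.
#' @return A `reference_panel`.
#' @export
read_reference_panel <- function(path, tree) {
  df <- read_tsv(path)
  reference_panel(split(df$ds, factor(df$node, levels = unique(df$node))),
                  tree)
}
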