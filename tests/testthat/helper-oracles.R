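# Independent brute-force oracles used to cross-check the implementation.

# --- Naive NG86 oracle -------------------------------------------------
# Recomputed from first principles off Biostrings::GENETIC_CODE, without
# reusing any package internals: per-codon synonymous site fractions,
# path-enumerated difference counts, Jukes-Cantor correction.

oracle_codon_split <- function(x) {
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

oracle_syn_fraction <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (gc[[mut]] != "*" && gc[[mut]] == gc[[codon]]) s <- s + 1
    }
  }
  s / 3
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_pair_sd <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(0)
  paths <- oracle_permutations(pos)
  tally <- function(ord) {
    cur <- c1; sd <- 0; hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") hit_stop <- TRUE
      else if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1
      cur <- nxt
    }
    c(sd, hit_stop)
  }
  res <- t(vapply(paths, tally, numeric(2)))
  use <- if (any(res[, 2] == 0)) res[res[, 2] == 0, 1, drop = TRUE] else res[, 1]
  mean(use)
}

oracle_ng86 <- function(a, b) {
  ca <- oracle_codon_split(toupper(a))
  cb <- oracle_codon_split(toupper(b))
  gc <- Biostrings::GENETIC_CODE
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ok <- ok & vapply(ca, function(x) !ok_stop(x), TRUE) &
    vapply(cb, function(x) !ok_stop(x), TRUE)
  ca <- ca[ok]; cb <- cb[ok]
  s <- (sum(vapply(ca, oracle_syn_fraction, 1)) +
          sum(vapply(cb, oracle_syn_fraction, 1))) / 2
  sd_tot <- sum(mapply(oracle_pair_sd, ca, cb))
  ps <- sd_tot / s
  if (s < 10 || ps >= 0.75) return(list(ds = NA_real_, s = s, defined = FALSE))
  list(ds = -0.75 * log(1 - 4 * ps / 3), s = s, defined = TRUE)
}

ok_stop <- function(codon) Biostrings::GENETIC_CODE[[codon]] == "*"

# --- Union-find single-linkage oracle ----------------------------------

oracle_components <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (NROW(edges)) {
    for (i in seq_len(NROW(edges))) {
      ra <- find(edges[i, 1]); rb <- find(edges[i, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, "")
  split(ids, roots)
}

# --- MRCA-assignment event-count oracle --------------------------------
# Assign each HT edge to the MRCA node of its endpoints on the tree and
# count distinct assigned nodes.

oracle_event_count <- function(phy, edges) {
  if (NROW(edges) == 0) return(0L)
  nodes <- apply(edges, 1, function(e) {
    a <- match(e[1], phy$tip.label); b <- match(e[2], phy$tip.label)
    ape::getMRCA(phy, c(a, b))
  })
  length(unique(nodes))
}

# --- Random trees and edge sets for property tests ---------------------

random_ultrametric_tree <- function(n, age = 100) {
  phy <- ape::rcoal(n)
  phy$edge.length <- phy$edge.length * age / max(ape::node.depth.edgelength(phy))
  phy$tip.label <- sprintf("OTU%03d", seq_len(n))
  phy
}

random_edge_set <- function(tips, n_edges) {
  if (n_edges == 0) return(matrix(character(0), ncol = 2))
  m <- t(replicate(n_edges, sample(tips, 2)))
  matrix(m, ncol = 2)
}
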