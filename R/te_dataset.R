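# Synthetic TE sequence sets with planted horizontal transfer events.
#
# Sequences are in-frame codon strings built exclusively from codons whose
# third position is 4-fold degenerate, so every third-position change is
# synonymous and no nonsynonymous model is needed. Divergence is introduced
# only at third positions under Jukes-Cantor, which makes realized NG86 dS
# track the per-branch targets.

.fourfold_prefixes <- c("GC", "GT", "TC", "CC", "AC", "GG", "CG", "CT")
.bases <- c("A", "C", "G", "T")

# Random in-frame ancestral sequence (character vector of nucleotides).
random_codon_seq <- function(n_codons) {
  pre <- sample(.fourfold_prefixes, n_codons, replace = TRUE)
  third <- sample(.bases, n_codons, replace = TRUE)
  unlist(strsplit(paste0(pre, third), ""), use.names = FALSE)
}

# Evolve third positions under Jukes-Cantor to an expected dS of `d`
# substitutions per synonymous site.
evolve_jc <- function(seq_vec, d) {
  if (d <= 0) return(seq_vec)
  third <- seq(3, length(seq_vec), by = 3)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- third[stats::runif(length(third)) < p]
  if (length(hit)) {
    cur <- seq_vec[hit]
    shift <- sample.int(3, length(hit), replace = TRUE)
    seq_vec[hit] <- .bases[(match(cur, .bases) - 1L + shift) %% 4L + 1L]
  }
  seq_vec
}

# Evolve an ancestral sequence down the host tree to a set of present tips,
# with per-branch dS = rate * branch length. Returns a named list of
# nucleotide vectors keyed by tip label.
evolve_on_tree <- function(phy, present_tips, root_seq, rate) {
  if (length(present_tips) == 1L) {
    return(stats::setNames(list(root_seq), phy$tip.label[present_tips]))
  }
  start <- ape::getMRCA(phy, present_tips)
  edge_len <- stats::setNames(phy$edge.length, paste(phy$edge[, 1], phy$edge[, 2]))
  keep <- rep(FALSE, max(phy$edge))
  keep[present_tips] <- TRUE
  # mark internal nodes whose subtree holds a present tip (postorder sweep)
  eord <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(eord))) {
    if (keep[eord[i, 2]]) keep[eord[i, 1]] <- TRUE
  }
  out <- list()
  recurse <- function(node, s) {
    if (node <= length(phy$tip.label)) {
      out[[phy$tip.label[node]]] <<- s
      return(invisible())
    }
    for (child in node_children(phy, node)) {
      if (!keep[child]) next
      t <- edge_len[[paste(node, child)]]
      recurse(child, evolve_jc(s, rate * t))
    }
  }
  recurse(start, root_seq)
  out
}

seq_id_for <- function(species, spec_idx, superfamily, family) {
  sp_code <- sub("^OTU", "", species)
  sprintf("SPEC%s.%d|%s|%s|F%s", sp_code, spec_idx, species, superfamily, family)
}

#' Parse pipeline sequence identifiers
#'
#' Sequence IDs (FASTA headers) follow the dialect
#' `SPEC<specimen>|OTU<species>|<superfamily>|F<family>`.
#'
#' @param ids Character vector of sequence IDs.
#' @return Data frame with columns `seq_id`, `specimen`, `species`,
#'   `superfamily`, `family`.
#' @export
parse_seq_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    input_error("malformed sequence ID(s): ",
                paste(utils::head(ids[bad], 3), collapse = ", "))
  m <- do.call(rbind, parts)
  data.frame(seq_id = ids,
             specimen = sub("^SPEC", "", m[, 1]),
             species = m[, 2],
             superfamily = m[, 3],
             family = sub("^F", "", m[, 4]),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic TE sequence survey with planted horizontal transfers
#'
#' For each superfamily, generates `n_families_per_superfamily` vertically
#' inherited families plus `n_planted_ht` families each carrying one planted
#' horizontal transfer. A vertical family occupies a random anchor clade of
#' the host tree; each species under the anchor carries the family with
#' probability `p_vertical_presence`, and its sequences are evolved along
#' the tree so that realized pairwise dS approximates the genomic dS of the
#' species pair (`2 * ds_rate * MRCA age`). A planted transfer links two
#' species drawn with weights elevated by `hotspot_multiplier` inside
#' `hotspot_order`; the recipient's sequence is regenerated from the donor's
#' at a dS drawn uniformly from `[0, 0.2 x genomic dS]`, far below any
#' plausible vertical divergence. Every present species contributes
#' `specimens_per_species` identical specimen copies.
#'
#' The truth table records one `vertical` row per within-family species pair
#' and exactly one `horizontal` row per planted event, with the true event
#' node, the target and genomic dS, and a `testable` flag that is `FALSE`
#' ("untestable by design") when no reference node exists inside the pair's
#' MRCA subtree.
#'
#' @param tree A [host_tree()].
#' @param config A [sim_config()].
#' @return A list of class `te_dataset`: `seqs` (named character vector of
#'   nucleotide strings), `meta` (per-sequence data frame as in
#'   [parse_seq_ids()]), `truth` (truth-table data frame).
#' @export
generate_te_dataset <- function(tree, config) {
  stopifnot(inherits(tree, "host_tree"), inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 303L))
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  internal <- seq(ntip + 1L, ntip + phy$Nnode)
  mrca_mat <- ape::mrca(phy)
  elig <- eligible_reference_nodes(tree)

  w <- rep(1, ntip)
  if (!is.null(config$hotspot_order))
    w[tree$order == config$hotspot_order] <- config$hotspot_multiplier

  seqs <- list()
  meta <- list()
  truth <- list()
  add_specimens <- function(sf, fam, species, seq_vec) {
    s <- paste(seq_vec, collapse = "")
    for (k in seq_len(config$specimens_per_species)) {
      id <- seq_id_for(species, k, sf, fam)
      seqs[[id]] <<- s
      meta[[id]] <<- data.frame(seq_id = id,
                                specimen = paste0(sub("^OTU", "", species), ".", k),
                                species = species, superfamily = sf,
                                family = fam, stringsAsFactors = FALSE)
    }
  }

  for (sf in config$superfamily_labels) {
    for (f in seq_len(config$n_families_per_superfamily)) {
      fam <- sprintf("%s_T%03d", sf, f)
      anchor <- if (length(internal) == 1L) internal else sample(internal, 1L)
      cand <- tips_under(phy, anchor)
      present <- cand[stats::runif(length(cand)) < config$p_vertical_presence]
      if (length(present) == 0L) present <- cand[sample.int(length(cand), 1L)]
      tipseqs <- evolve_on_tree(phy, present, random_codon_seq(config$n_codons),
                                config$ds_rate)
      for (sp in names(tipseqs)) add_specimens(sf, fam, sp, tipseqs[[sp]])
      sp <- sort(names(tipseqs))
      if (length(sp) > 1L) {
        pairs <- utils::combn(sp, 2)
        truth[[length(truth) + 1L]] <- data.frame(
          family = fam, superfamily = sf,
          species_a = pairs[1, ], species_b = pairs[2, ],
          mechanism = "vertical", event_node = NA_character_,
          ds_target = NA_real_,
          ds_genomic = 2 * config$ds_rate *
            tree$age[mrca_mat[cbind(pairs[1, ], pairs[2, ])]],
          testable = NA, stringsAsFactors = FALSE)
      }
    }
    if (config$n_planted_ht > 0L) {
      for (e in seq_len(config$n_planted_ht)) {
        fam <- sprintf("%s_H%03d", sf, e)
        a <- sample.int(ntip, 1L, prob = w)
        b <- sample(setdiff(seq_len(ntip), a), 1L,
                    prob = w[setdiff(seq_len(ntip), a)])
        sp_a <- phy$tip.label[a]
        sp_b <- phy$tip.label[b]
        node <- mrca_mat[a, b]
        genomic <- 2 * config$ds_rate * tree$age[node]
        target <- stats::runif(1, 0, 0.2 * genomic)
        donor <- random_codon_seq(config$n_codons)
        recip <- evolve_jc(donor, target)
        add_specimens(sf, fam, sp_a, donor)
        add_specimens(sf, fam, sp_b, recip)
        testable <- !is.na(match_reference(tree, sp_a, sp_b, elig))
        truth[[length(truth) + 1L]] <- data.frame(
          family = fam, superfamily = sf,
          species_a = min(sp_a, sp_b), species_b = max(sp_a, sp_b),
          mechanism = "horizontal", event_node = node_label(tree, node),
          ds_target = target, ds_genomic = genomic,
          testable = testable, stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(seqs = unlist(seqs),
         meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
         truth = if (length(truth))
           do.call(rbind, c(truth, list(make.row.names = FALSE)))
         else
           data.frame(family = character(), superfamily = character(),
                      species_a = character(), species_b = character(),
                      mechanism = character(), event_node = character(),
                      ds_target = numeric(), ds_genomic = numeric(),
                      testable = logical())),
    class = "te_dataset")
}

#' @export
print.te_dataset <- function(x, ...) {
  cat(sprintf("Synthetic TE dataset: %d sequences, %d families, %d planted transfers\n",
              length(x$seqs), length(unique(x$meta$family)),
              sum(x$truth$mechanism == "horizontal")))
  invisible(x)
}

#' Write TE sequences as FASTA
#'
#' @param seqs Named character vector of nucleotide strings (names become
#'   headers).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_te_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read TE sequences from FASTA
#'
#' Headers must follow the `SPEC<specimen>|OTU<species>|<superfamily>|F<fam>`
#' dialect; sequences shorter than `min_length` nucleotides are dropped, as
#' they carry too few synonymous sites to test.
#'
#' @param path FASTA path.
#' @param min_length Minimum sequence length in nucleotides (default 100).
#' @return A list with `seqs` (named character vector) and `meta`
#'   (data frame from [parse_seq_ids()]).
#' @export
read_te_fasta <- function(path, min_length = 100) {
  set <- Biostrings::readDNAStringSet(path)
  keep <- Biostrings::width(set) >= min_length
  set <- set[keep]
  seqs <- stats::setNames(as.character(set), names(set))
  list(seqs = seqs, meta = parse_seq_ids(names(seqs)))
}
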