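# TE family clustering: single linkage on thresholded pairwise hits,
# followed by the specimen-occurrence filter.

#' Cluster TE sequences into families by single linkage
#'
#' Families are the connected components of the graph whose vertices are
#' sequences (within one superfamily) and whose edges are hit pairs passing
#' both thresholds: identity at least `min_identity` percent (inclusive)
#' and alignment length at least `min_overlap_frac` of the shorter
#' sequence. An asymmetric hit pair contributes an edge if either
#' orientation passes, since single linkage is symmetric. Sequences with no
#' passing hit form singleton families.
#'
#' Family IDs are assigned deterministically as `<superfamily>_F<k>`, with
#' components numbered by their lexicographically smallest member sequence
#' ID, so output is invariant to hit-table row order.
#'
#' @param hits Hit-table data frame (see [generate_hit_table()]).
#' @param meta Per-sequence data frame with columns `seq_id`, `specimen`,
#'   `species`, `superfamily` (e.g. from [parse_seq_ids()]).
#' @param min_identity Minimum percent identity (default 80, inclusive).
#' @param min_overlap_frac Minimum alignment length as a fraction of the
#'   shorter sequence (default 0.80).
#' @return A `te_families` data frame: one row per member sequence, columns
#'   `family`, `superfamily`, `species`, `specimen`, `seq_id`.
#' @export
cluster_single_linkage <- function(hits, meta, min_identity = 80,
                                   min_overlap_frac = 0.80) {
  unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), meta$seq_id)
  if (length(unknown))
    input_error("hit table references unknown sequence ID(s): ",
                paste(utils::head(unknown, 3), collapse = ", "))
  sf <- stats::setNames(meta$superfamily, meta$seq_id)
  pass <- hits$pident >= min_identity &
    hits$length >= min_overlap_frac * pmin(hits$qlen, hits$slen) &
    sf[hits$qseqid] == sf[hits$sseqid] &
    hits$qseqid != hits$sseqid
  edges <- hits[pass, c("qseqid", "sseqid"), drop = FALSE]
  out <- list()
  for (s in sort(unique(meta$superfamily))) {
    ids <- sort(meta$seq_id[meta$superfamily == s])
    e <- edges[edges$qseqid %in% ids, , drop = FALSE]
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                       vertices = data.frame(name = ids))
    memb <- igraph::components(g)$membership[ids]
    # renumber components by smallest member sequence ID
    first <- tapply(ids, memb, min)
    rank <- match(memb, names(sort(first)))
    out[[s]] <- data.frame(
      family = sprintf("%s_F%03d", s, rank),
      superfamily = s,
      species = meta$species[match(ids, meta$seq_id)],
      specimen = meta$specimen[match(ids, meta$seq_id)],
      seq_id = ids,
      stringsAsFactors = FALSE)
  }
  fams <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(fams) <- NULL
  class(fams) <- c("te_families", "data.frame")
  fams
}

#' Apply the specimen-occurrence filter to TE families
#'
#' Within each family, species represented by fewer than two distinct
#' specimens are removed (their member sequences dropped): a single
#' specimen cannot rule out cross-contamination. Families left with no
#' species are removed entirely.
#'
#' @param families A `te_families` data frame.
#' @return The filtered `te_families` data frame.
#' @export
filter_family_occurrences <- function(families) {
  key <- paste(families$family, families$species)
  n_spec <- tapply(families$specimen, key, function(x) length(unique(x)))
  keep <- n_spec[key] >= 2
  res <- families[keep, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("te_families", "data.frame")
  res
}

#' Enumerate species pairs co-occurring in a TE family
#'
#' Every unordered species pair sharing a family is an HTT candidate; each
#' pair is emitted once per family. Single-species families emit nothing.
#'
#' @param families A `te_families` data frame (normally filtered).
#' @return Data frame with columns `family`, `superfamily`, `species_a`,
#'   `species_b` (with `species_a < species_b`).
#' @export
shared_family_pairs <- function(families) {
  out <- list()
  for (f in unique(families$family)) {
    rows <- families[families$family == f, , drop = FALSE]
    sp <- sort(unique(rows$species))
    if (length(sp) < 2L) next
    pairs <- utils::combn(sp, 2)
    out[[f]] <- data.frame(family = f, superfamily = rows$superfamily[1],
                           species_a = pairs[1, ], species_b = pairs[2, ],
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(family = character(), superfamily = character(),
                      species_a = character(), species_b = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Write TE family membership as TSV
#'
#' @param families A `te_families` data frame.
#' @param path Output path.
#' @param comments Comment header lines.
#' @return Invisibly, `path`.
#' @export
write_families <- function(families, path, comments = NULL) {
  write_tsv(as.data.frame(families), path, comments = comments)
}

#' Read TE family membership from TSV
#'
#' @param path TSV written by [write_families()].
#' @return A `te_families` data frame.
#' @export
read_families <- function(path) {
  df <- read_tsv(path)
  class(df) <- c("te_families", "data.frame")
  df
}
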