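# Per-family synonymous divergence: specimen-redundancy collapse followed
# by the minimum pairwise dS across species.

# Percent-style identity between two aligned rows over columns where both
# are ungapped A/C/G/T; 0 when no column is shared.
shared_column_identity <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  ok <- va %in% .bases & vb %in% .bases
  if (!any(ok)) return(0)
  mean(va[ok] == vb[ok])
}

#' Collapse near-identical sequences of the same specimen
#'
#' Within each specimen, rows are grouped by single linkage at >= 99%
#' identity on shared (mutually ungapped) columns, and each group is
#' replaced by its longest member (ungapped length; ties broken by sequence
#' ID order). Rows from different specimens are never merged, since two
#' independent specimens are what validates an occurrence. This removes
#' within-genome copy redundancy before the minimum-dS reduction.
#'
#' @param seqs Named character vector of aligned rows (equal length).
#' @param meta Per-sequence data frame with `seq_id` and `specimen`.
#' @return A list with the retained `seqs` and `meta`.
#' @export
collapse_specimen_redundancy <- function(seqs, meta) {
  stopifnot(length(seqs) >= 1L, all(names(seqs) %in% meta$seq_id))
  meta <- meta[match(names(seqs), meta$seq_id), , drop = FALSE]
  keep <- character(0)
  for (spec in unique(meta$specimen)) {
    ids <- sort(meta$seq_id[meta$specimen == spec])
    if (length(ids) == 1L) { keep <- c(keep, ids); next }
    edges <- list()
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        if (shared_column_identity(seqs[[ids[i]]], seqs[[ids[j]]]) >= 0.99)
          edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
      }
    }
    g <- igraph::graph_from_data_frame(
      if (length(edges)) do.call(rbind, edges) else matrix(character(), 0, 2),
      directed = FALSE, vertices = data.frame(name = ids))
    memb <- igraph::components(g)$membership[ids]
    for (grp in split(ids, memb)) {
      lens <- vapply(seqs[grp], function(s) sum(strsplit(s, "")[[1]] != "-"), 1)
      keep <- c(keep, grp[order(-lens, grp)][1])
    }
  }
  keep <- names(seqs)[names(seqs) %in% keep]
  list(seqs = seqs[keep], meta = meta[match(keep, meta$seq_id), , drop = FALSE])
}

#' Minimum pairwise dS between every two species of a family
#'
#' For each unordered species pair present in the (collapsed) alignment,
#' computes [ds_ng86()] over all cross-species row pairs and reports the
#' smallest defined value with its contributing sequence pair. Undefined
#' estimates (saturated or too few synonymous sites) are excluded from the
#' minimum; a pair with only undefined values is reported with
#' `defined = FALSE`, i.e. untested rather than transferred.
#'
#' @param seqs Named character vector of aligned rows.
#' @param meta Per-sequence data frame with `seq_id` and `species`.
#' @return Data frame with one row per species pair: `species_a`,
#'   `species_b`, `ds`, `s_sites`, `seq_a`, `seq_b`, `defined`.
#' @export
min_pairwise_ds <- function(seqs, meta) {
  meta <- meta[match(names(seqs), meta$seq_id), , drop = FALSE]
  sp <- sort(unique(meta$species))
  if (length(sp) < 2L)
    return(data.frame(species_a = character(), species_b = character(),
                      ds = numeric(), s_sites = numeric(),
                      seq_a = character(), seq_b = character(),
                      defined = logical(), stringsAsFactors = FALSE))
  rows <- list()
  for (i in seq_len(length(sp) - 1L)) {
    for (j in seq(i + 1L, length(sp))) {
      ids_a <- sort(meta$seq_id[meta$species == sp[i]])
      ids_b <- sort(meta$seq_id[meta$species == sp[j]])
      best <- list(ds = NA_real_, s_sites = NA_real_,
                   seq_a = NA_character_, seq_b = NA_character_)
      for (a in ids_a) {
        for (b in ids_b) {
          r <- ds_ng86(seqs[[a]], seqs[[b]])
          if (r$defined && (is.na(best$ds) || r$ds < best$ds))
            best <- list(ds = r$ds, s_sites = r$s_sites, seq_a = a, seq_b = b)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species_a = sp[i], species_b = sp[j],
        ds = best$ds, s_sites = best$s_sites,
        seq_a = best$seq_a, seq_b = best$seq_b,
        defined = !is.na(best$ds), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-family minimum pairwise dS for a whole family set
#'
#' Convenience wrapper running [collapse_specimen_redundancy()] then
#' [min_pairwise_ds()] on every multi-species family. Sequences are assumed
#' pre-aligned within each family (the synthetic generator emits gapless,
#' frame-consistent families; external alignments are accepted as-is).
#'
#' @param families A `te_families` data frame.
#' @param seqs Named character vector covering all member `seq_id`s.
#' @return Data frame of per-(family, species pair) minimum dS, with
#'   `family` and `superfamily` columns prepended.
#' @export
family_pairwise_ds <- function(families, seqs) {
  out <- list()
  for (f in unique(families$family)) {
    rows <- families[families$family == f, , drop = FALSE]
    if (length(unique(rows$species)) < 2L) next
    missing <- setdiff(rows$seq_id, names(seqs))
    if (length(missing))
      input_error("family ", f, " references unknown sequence ID(s): ",
                  paste(utils::head(missing, 3), collapse = ", "))
    coll <- collapse_specimen_redundancy(seqs[rows$seq_id], rows)
    ds <- min_pairwise_ds(coll$seqs, coll$meta)
    if (nrow(ds) == 0L) next
    out[[f]] <- cbind(data.frame(family = f, superfamily = rows$superfamily[1],
                                 stringsAsFactors = FALSE), ds)
  }
  if (length(out) == 0L)
    return(data.frame(family = character(), superfamily = character(),
                      species_a = character(), species_b = character(),
                      ds = numeric(), s_sites = numeric(),
                      seq_a = character(), seq_b = character(),
                      defined = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}
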