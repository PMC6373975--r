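# All-vs-all pairwise hit table for the synthetic sequences, in BLAST
# outfmt-6 field order (qseqid, sseqid, pident, length) with qlen and slen
# appended. The generator controls divergence, so an exact global alignment
# (match +1, mismatch -1, gap -2) stands in for a local search.

empty_hit_table <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), qlen = integer(), slen = integer(),
             stringsAsFactors = FALSE)
}

#' Compute an all-vs-all pairwise hit table
#'
#' Globally aligns every pair of sequences within each superfamily (match
#' +1, mismatch -1, gap -2) and reports percent identity over the aligned
#' span (gap columns included) and the alignment length. Both orientations
#' of each pair are emitted, as a symmetric search would produce;
#' self-hits are excluded.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param superfamily Optional named character vector (same names as
#'   `seqs`) restricting alignment to within-superfamily pairs; when `NULL`
#'   all sequences form one group.
#' @return Data frame with columns `qseqid`, `sseqid`, `pident`, `length`,
#'   `qlen`, `slen`.
#' @export
generate_hit_table <- function(seqs, superfamily = NULL) {
  if (length(seqs) < 2L) return(empty_hit_table())
  groups <- if (is.null(superfamily)) {
    list(names(seqs))
  } else {
    split(names(seqs), superfamily[names(seqs)])
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  out <- list()
  for (ids in groups) {
    m <- length(ids)
    if (m < 2L) next
    set <- Biostrings::DNAStringSet(seqs[ids])
    widths <- stats::setNames(Biostrings::width(set), ids)
    for (j in 2:m) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = set[seq_len(j - 1L)], subject = set[[j]],
        substitutionMatrix = submat, gapOpening = 0, gapExtension = 2,
        type = "global")
      alen <- Biostrings::nchar(aln)
      pid <- 100 * Biostrings::nmatch(aln) / alen
      qs <- ids[seq_len(j - 1L)]
      out[[length(out) + 1L]] <- data.frame(
        qseqid = c(qs, rep(ids[j], j - 1L)),
        sseqid = c(rep(ids[j], j - 1L), qs),
        pident = c(pid, pid),
        length = as.integer(c(alen, alen)),
        qlen = c(widths[qs], rep(widths[ids[j]], j - 1L)),
        slen = c(rep(widths[ids[j]], j - 1L), widths[qs]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_hit_table())
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Write a hit table as tab-separated values
#'
#' @param hits Hit-table data frame.
#' @param path Output path.
#' @param comments Comment header lines.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path, comments = NULL) {
  write_tsv(hits, path, comments = comments)
}

#' Read a hit table in BLAST outfmt-6 dialect with qlen/slen columns
#'
#' @param path TSV with columns `qseqid`, `sseqid`, `pident`, `length`,
#'   `qlen`, `slen` (header row required).
#' @return Hit-table data frame.
#' @export
read_hit_table <- function(path) {
  df <- read_tsv(path)
  need <- c("qseqid", "sseqid", "pident", "length", "qlen", "slen")
  if (!all(need %in% names(df)))
    input_error("hit table misses column(s): ",
                paste(setdiff(need, names(df)), collapse = ", "))
  df
}
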