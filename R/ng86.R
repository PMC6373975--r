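# Nei-Gojobori (1986) synonymous divergence between aligned coding sequences.
#
# The estimator is deliberately the classical minimal-assumption one: no
# transition/transversion weighting, no codon frequencies, Jukes-Cantor
# multiple-hit correction on the synonymous proportion. Mutations that would
# create a stop codon are treated as nonsynonymous when counting sites, and
# mutational paths passing through a stop codon are excluded when counting
# differences (falling back to all paths if none avoids a stop).

.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tab)) return(.ng86_cache$tab)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(gc)
  syn_sites <- stats::setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    if (gc[[cod]] == "*") { syn_sites[cod] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- b
        if (gc[[mut]] != "*" && gc[[mut]] == gc[[cod]]) s <- s + 1 / 3
      }
    }
    syn_sites[cod] <- s
  }
  .ng86_cache$tab <- list(gc = gc, syn_sites = syn_sites)
  .ng86_cache$tab
}

# Average synonymous / nonsynonymous difference counts between two codons,
# over all orderings of the single-base steps separating them. Returns
# c(sd, nd). Cached per codon pair.
codon_diff_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- ng86_tables()
  gc <- tab$gc
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) {
    res <- c(0, 0)
  } else {
    perms <- switch(k,
                    list(pos),
                    list(pos, pos[2:1]),
                    {
                      p <- pos
                      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                    })
    count_path <- function(ord) {
      cur <- c1
      sd <- nd <- 0
      ok <- TRUE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (gc[[nxt]] == "*") ok <- FALSE
        if (gc[[nxt]] == "*" || gc[[nxt]] != gc[[cur]]) nd <- nd + 1
        else sd <- sd + 1
        cur <- nxt
      }
      c(sd, nd, as.numeric(ok))
    }
    counts <- vapply(perms, count_path, numeric(3))
    valid <- counts[3, ] == 1
    if (any(valid)) counts <- counts[, valid, drop = FALSE]
    res <- rowMeans(counts[1:2, , drop = FALSE])
  }
  assign(key, res, envir = .ng86_cache)
  res
}

split_codons <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  substring(x, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Nei-Gojobori (1986) synonymous divergence between two aligned sequences
#'
#' Computes dS between two frame-consistent, equal-length coding sequences.
#' Codon columns containing a gap, an ambiguity code, or a stop codon in
#' either sequence are skipped. Per-codon synonymous site fractions are
#' averaged over both sequences; synonymous and nonsynonymous differences
#' are counted along all orderings of the single-base steps between codon
#' pairs (stop-crossing orderings excluded), and the synonymous proportion
#' `pS = Sd / S` is corrected for multiple hits with
#' `dS = -(3/4) * log(1 - (4/3) * pS)`.
#'
#' The estimate is flagged undefined (rather than raising an error) when the
#' correction leaves its domain (`pS >= 3/4`, i.e. saturation) or when fewer
#' than `min_sites` synonymous sites are comparable — short amplicons give
#' the log correction a dangerously small denominator otherwise.
#'
#' @param a,b Nucleotide strings of equal length, divisible by 3, aligned
#'   in a common reading frame (`-` for gaps).
#' @param min_sites Minimum number of synonymous sites for a defined
#'   estimate (default 10).
#' @return A list: `ds` (numeric, `NA` when undefined), `s_sites` (average
#'   synonymous sites compared), `ps` (synonymous proportion), `defined`
#'   (logical).
#' @examples
#' ds_ng86("GCTGCT", "GCCGCT")  # one synonymous change at a 4-fold site
#' @export
ds_ng86 <- function(a, b, min_sites = 10) {
  if (nchar(a) != nchar(b))
    input_error("aligned sequences differ in length (",
                nchar(a), " vs ", nchar(b), ")")
  if (nchar(a) %% 3 != 0)
    input_error("alignment length ", nchar(a), " is not a multiple of 3")
  tab <- ng86_tables()
  ca <- split_codons(a)
  cb <- split_codons(b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  clean <- clean & !is.na(tab$syn_sites[ca]) & !is.na(tab$syn_sites[cb])
  ca <- ca[clean]
  cb <- cb[clean]
  if (length(ca) == 0L)
    return(list(ds = NA_real_, s_sites = 0, ps = NA_real_, defined = FALSE))
  s <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  sd_tot <- 0
  differ <- which(ca != cb)
  for (i in differ) sd_tot <- sd_tot + codon_diff_counts(ca[i], cb[i])[1]
  ps <- if (s > 0) sd_tot / s else NA_real_
  if (is.na(ps) || s < min_sites || ps >= 0.75) {
    return(list(ds = NA_real_, s_sites = s, ps = ps, defined = FALSE))
  }
  list(ds = -0.75 * log(1 - 4 * ps / 3), s_sites = s, ps = ps, defined = TRUE)
}
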