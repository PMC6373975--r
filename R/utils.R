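# Shared internal helpers.

# Derive a reproducible child seed (< 2^31) from a master seed and a stream
# index, so that independent pipeline stages draw from independent streams.
child_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k)
  as.integer(s %% 2147483629 + 1)
}

# Canonical key for an unordered species pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Write a data frame as tab-separated values with comment header lines
#'
#' All tabular outputs of the pipeline use this dialect: optional `#`-prefixed
#' comment lines (run seed, provenance) followed by a header row and
#' tab-separated records.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @param comments Character vector of comment lines (written as `# <line>`).
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated file written by [write_tsv()]
#'
#' @param path Input file path.
#' @return A data frame; `#` comment lines are skipped.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Stop with a consistent error class so callers/tests can distinguish
# configuration errors from runtime failures.
config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("httscan_config_error", "error")))
}

input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("httscan_input_error", "error")))
}
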