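# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Reverse complement of a DNA string
#'
#' Case-preserving reverse complement; characters outside ACGTN are left
#' unchanged (but reversed).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("acgtnACGTN", "tgcanTGCAN", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# split a string into a character vector of single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Read a tab-separated table
#'
#' All tabular inputs share one dialect: header row, tab-delimited, UTF-8,
#' lines starting with '#' are comments.
#'
#' @param path file path.
#' @return a data.frame with character/numeric columns as parsed.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_table <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# deterministic sort order helper: NA values last
order_na_last <- function(...) {
  args <- list(...)
  keys <- list()
  for (a in args) {
    keys[[length(keys) + 1L]] <- is.na(a)
    keys[[length(keys) + 1L]] <- a
  }
  do.call(order, c(keys, list(method = "radix")))
}

log_stage <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}
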