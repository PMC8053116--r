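# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

#' Write a data frame as plain TSV
#'
#' Tab-separated, no quoting, no row names: the output convention used by
#' every stage of the pipeline so results stay diffable.
#'
#' @param x data frame.
#' @param path output file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain TSV written by [write_tsv()]
#' @param path file path.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed is fanned out deterministically so that stages draw from
#' independent streams but the whole run is reproducible. The result is kept
#' below 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed global integer seed.
#' @param stage stage name (character).
#' @return integer seed.
#' @export
fan_seed <- function(seed, stage) {
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "seed must be a single finite number")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1L) + 1)
}
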