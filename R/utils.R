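#' @keywords internal
"_PACKAGE"

#' @importFrom stats median setNames
#' @importFrom utils read.delim write.table head
NULL

# Standard 20-letter amino-acid alphabet, alphabetical by one-letter code.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Stable 31-bit hash of a string
#'
#' Horner-scheme polynomial hash over UTF-8 bytes, reduced modulo 2^31 - 1.
#' Used to derive independent per-id random streams from one master seed, so
#' that generated objects do not depend on the order in which they are drawn.
#'
#' @param x character scalar.
#' @return integer in [0, 2^31 - 2].
#' @keywords internal
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 0
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double-int range
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Derive a substream seed from a master seed and an id
#' @keywords internal
stream_seed <- function(master_seed, id) {
  as.integer((as.numeric(master_seed) + stable_hash(id)) %% 2147483647)
}

# Evaluate code under a temporary seed, restoring the caller's RNG state.
with_stream <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Union of 1-based inclusive integer intervals
#'
#' Merges overlapping or bookended-identical intervals and returns the union
#' as a matrix of disjoint intervals sorted by start. Touching intervals
#' (end + 1 == next start) are NOT merged: only genuine overlap is.
#'
#' @param starts,ends integer vectors, starts <= ends elementwise.
#' @return two-column matrix (start, end) of disjoint sorted intervals.
#' @keywords internal
interval_union <- function(starts, ends) {
  stopifnot(length(starts) == length(ends), all(starts <= ends))
  if (length(starts) == 0L) return(matrix(integer(0), ncol = 2))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    k <- length(out_s)
    if (starts[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], ends[i])
    } else {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    }
  }
  cbind(start = out_s, end = out_e)
}

# Abort helpers keep error classes greppable in tests.
stop_input <- function(...) stop(..., call. = FALSE)
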