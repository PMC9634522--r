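# Internal helpers shared across modules.

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a matrix.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape; each row is non-negative and sums to 1.
#' @keywords internal
#' @noRd
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

#' @noRd
softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Round half away from zero
#'
#' Base `round()` uses banker's rounding; report tables use conventional
#' half-up rounding to match printed two-decimal scores.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a over a character string; used for config hashes in run manifests.
#' @noRd
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b)  # xor only touches the low byte
    # 2^53-safe modular multiply by the FNV prime 16777619
    hi <- h %/% 65536
    lo16 <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo16 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
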