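# Binary structural fingerprints are plain integer vectors of 0/1 bits;
# libraries and panels keep them as 0/1 matrices (one row per molecule) so
# similarity against a whole panel is a single matrix product.

#' Tanimoto similarity of two binary fingerprints
#'
#' Computes the Tanimoto (Jaccard) coefficient `c / (a + b - c)` where `a`
#' and `b` are the popcounts of the two fingerprints and `c` the popcount of
#' their bitwise intersection. Two all-zero fingerprints score 0 by
#' convention, so an empty fingerprint can never pass a positive similarity
#' threshold.
#'
#' @param a,b Integer or logical vectors of equal length holding 0/1 bits.
#' @return A similarity score in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 0)) # 0.5
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(as.logical(a))
  b <- as.integer(as.logical(b))
  if (length(a) == 0L || length(a) != length(b)) {
    stop("fingerprints must be non-empty and of equal length", call. = FALSE)
  }
  inter <- sum(a & b)
  denom <- sum(a) + sum(b) - inter
  if (denom == 0L) return(0)
  inter / denom
}

#' Tanimoto similarity matrix between two fingerprint matrices
#'
#' @param x,y 0/1 matrices with one fingerprint per row and identical column
#'   counts.
#' @return A `nrow(x)` by `nrow(y)` matrix of Tanimoto scores; pairs where
#'   both fingerprints are all-zero score 0.
#' @export
tanimoto_matrix <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) == 0L || ncol(x) != ncol(y)) {
    stop("fingerprint matrices must share a positive bit length", call. = FALSE)
  }
  storage.mode(x) <- "double"; storage.mode(y) <- "double"
  inter <- x %*% t(y)
  denom <- outer(rowSums(x), rowSums(y), "+") - inter
  s <- inter / denom
  s[denom == 0] <- 0
  s
}

#' Encode a bit vector as a hexadecimal string
#'
#' Bits are packed four per hex digit, most significant bit first; the vector
#' is zero-padded on the right to a multiple of four. Used for the
#' `fingerprint_hex` column of compound-library and panel TSV files.
#'
#' @param bits Integer or logical 0/1 vector.
#' @return A single lowercase hex string.
#' @export
fp_to_hex <- function(bits) {
  bits <- as.integer(as.logical(bits))
  pad <- (4L - length(bits) %% 4L) %% 4L
  bits <- c(bits, integer(pad))
  nib <- matrix(bits, nrow = 4L)
  vals <- as.integer(c(8, 4, 2, 1) %*% nib)
  paste(format.hexmode(vals), collapse = "")
}

#' Decode a hexadecimal fingerprint string back to a bit vector
#'
#' @param hex Hex string produced by [fp_to_hex()].
#' @param length Number of bits to return (trailing padding is dropped).
#' @return Integer 0/1 vector of the requested length.
#' @export
fp_from_hex <- function(hex, length) {
  digits <- strtoi(strsplit(hex, "", fixed = TRUE)[[1L]], 16L)
  if (anyNA(digits)) stop("invalid hex fingerprint string", call. = FALSE)
  if (4L * base::length(digits) < length) {
    stop("hex string too short for requested fingerprint length", call. = FALSE)
  }
  bits <- as.integer(outer(c(8L, 4L, 2L, 1L), digits, function(m, d) bitwAnd(d, m) > 0L))
  bits[seq_len(length)]
}
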