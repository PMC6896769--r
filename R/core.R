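#' Hex codec for fingerprints
#'
#' Convert between the FPS hex representation and raw fingerprint bytes.
#' Bit `k` of the fingerprint is bit `k %% 8` of byte `k %/% 8` — the bytes
#' are in little-endian bit order, while the two hex characters of each
#' byte are in conventional big-endian nibble order.  Decoding "0100" gives
#' a 16-bit fingerprint with only bit 0 set; "2000" sets only bit 5; "c218"
#' sets bits 1, 6, 7, 11 and 12.
#'
#' @param hex An even-length hex string (case-insensitive).
#' @param fp A raw vector of fingerprint bytes.
#' @return `hex_to_fp()` returns a raw vector; `fp_to_hex()` returns a
#'   lowercase hex string.  The two functions round-trip exactly.
#' @examples
#' fp_bits(hex_to_fp("c218"))   # 1 6 7 11 12
#' fp_to_hex(hex_to_fp("C218")) # "c218"
#' @export
hex_to_fp <- function(hex) {
  stopifnot(is.character(hex), length(hex) == 1L)
  cpp_hex_decode(hex)
}

#' @rdname hex_to_fp
#' @export
fp_to_hex <- function(fp) {
  stopifnot(is.raw(fp))
  cpp_hex_encode(fp)
}

#' Indices of the set bits of a fingerprint
#'
#' @param fp Raw fingerprint.
#' @param num_bits Bit length; defaults to `8 * length(fp)`.
#' @return Integer vector of 0-based bit indices, ascending.
#' @export
fp_bits <- function(fp, num_bits = 8L * length(fp)) {
  stopifnot(is.raw(fp))
  bits <- as.logical(rawToBits(fp))
  idx <- which(bits) - 1L
  idx[idx < num_bits]
}

#' Population count
#'
#' Number of set bits in a fingerprint (`fp_popcount`) or in the
#' intersection of two equal-length fingerprints (`fp_intersect_popcount`).
#' All registered kernels return identical values; the kernel choice is a
#' performance detail only.  `"word64"` counts 8 bytes per step with the
#' hardware popcount, `"lookup8"` uses a 256-entry byte table, and
#' `"bitwise"` shifts out single bits (the testing oracle).
#'
#' @param fp,fp1,fp2 Raw fingerprint vectors.
#' @param kernel One of [popcount_kernels()].
#' @return A non-negative integer count.
#' @export
fp_popcount <- function(fp, kernel = "word64") {
  stopifnot(is.raw(fp))
  cpp_popcount(fp, kernel)
}

#' @rdname fp_popcount
#' @export
fp_intersect_popcount <- function(fp1, fp2, kernel = "word64") {
  stopifnot(is.raw(fp1), is.raw(fp2))
  cpp_intersect_popcount(fp1, fp2, kernel)
}

#' @rdname fp_popcount
#' @export
popcount_kernels <- function() c("word64", "lookup8", "bitwise")

#' Tanimoto similarity of two fingerprints
#'
#' Computes `c / (A + B - c)` where `A` and `B` are the popcounts of the
#' two fingerprints and `c` is their intersection popcount, so only one
#' popcount evaluation is needed per comparison when `A` and `B` are known.
#' Two fingerprints with no bits set have a Tanimoto of 0.
#'
#' @param fp1,fp2 Raw fingerprints of equal length.
#' @return A similarity score in `[0, 1]`.
#' @examples
#' tanimoto(hex_to_fp("0300"), hex_to_fp("0500"))  # bits {0,1} vs {0,2}: 1/3
#' @export
tanimoto <- function(fp1, fp2) {
  A <- fp_popcount(fp1)
  B <- fp_popcount(fp2)
  cc <- fp_intersect_popcount(fp1, fp2)
  d <- A + B - cc
  if (d == 0) 0 else cc / d
}

#' Tversky similarity with integer weights
#'
#' The asymmetric Tversky similarity
#' `c / (alpha * (A - c) + beta * (B - c) + c)`, where `alpha` weighs the
#' bits unique to `fp1` and `beta` those unique to `fp2`.  IEEE doubles are
#' not distributive, and naive floating-point implementations can return a
#' self-similarity slightly below 1.  Here `alpha` and `beta` (at most 10)
#' are scaled by 10,000 and rounded to integers before the search, the
#' whole expression is evaluated in integer arithmetic, and only the final
#' division uses floating point — so `tversky(x, x, a, b)` is exactly 1 for
#' any nonzero `x`.  With `alpha = beta = 1` the score equals the Tanimoto.
#' Two all-zero fingerprints (or a zero denominator generally) score 0,
#' mirroring the Tanimoto convention.
#'
#' @param fp1,fp2 Raw fingerprints of equal length.
#' @param alpha,beta Weights in `[0, 10]`.  Values with more than four
#'   decimal digits are rounded, with a warning.
#' @return A similarity score in `[0, 1]`.
#' @export
tversky <- function(fp1, fp2, alpha = 1, beta = 1) {
  w <- tversky_weights(alpha, beta)
  cpp_tversky(fp1, fp2, w[1L], w[2L])
}

# scale alpha/beta by 10,000 and round; warn when precision is lost
tversky_weights <- function(alpha, beta) {
  for (nm in c("alpha", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 10)
      stop(nm, " must be a single value in [0, 10]")
  }
  a <- round(alpha * 10000)
  b <- round(beta * 10000)
  if (abs(a - alpha * 10000) > 1e-6 || abs(b - beta * 10000) > 1e-6)
    warning("alpha/beta rounded to 4 decimal digits")
  c(as.integer(a), as.integer(b))
}

#' Exact rational representation of a similarity threshold
#'
#' Every finite double in `[0, 1]` is exactly an integer fraction
#' `m / 2^s`; the threshold is decomposed that way and reduced, so `p / q`
#' equals the double exactly.  A candidate with intersection popcount `c`
#' against popcounts `A` and `B` then satisfies `Tanimoto >= T` if and only
#' if `c * q >= p * (A + B - c)` — the integer rejection test is also the
#' final test, and no floating-point comparison is ever needed for an
#' accept/reject decision.
#'
#' @param t A threshold in `[0, 1]`: a number, a decimal string (see
#'   [parse_threshold()]), or an existing `rational_threshold`.
#' @return An object of class `rational_threshold` with fields `p`, `q`
#'   (exact integers stored as doubles; `q <= 2^53`) and `original`.
#' @examples
#' rational_threshold(0.75)  # 3/4: the test becomes c*4 >= 3*(A+B-c)
#' @export
rational_threshold <- function(t) {
  if (inherits(t, "rational_threshold")) return(t)
  if (is.character(t)) return(parse_threshold(t))
  if (!is.numeric(t) || length(t) != 1L || is.na(t))
    stop("threshold must be a single number in [0, 1]")
  if (t < 0 || t > 1) stop("threshold must be in [0, 1], got ", t)
  pq <- cpp_rational_from_double(t)
  structure(list(p = pq[1L], q = pq[2L], original = as.numeric(t)),
            class = "rational_threshold")
}

#' @export
print.rational_threshold <- function(x, ...) {
  cat("<rational_threshold> ", format(x$original, digits = 17),
      " = ", format(x$p, big.mark = ""), "/", format(x$q, big.mark = ""),
      "\n", sep = "")
  invisible(x)
}

#' Minimum required intersection popcount
#'
#' For a threshold `T > 0` and popcounts `A`, `B`, returns
#' `ceiling(T * (A + B) / (1 + T))`, evaluated as
#' `ceiling(p * (A + B) / (p + q))` in exact integer arithmetic so the
#' ceiling is never corrupted by floating-point error.  Any pair whose
#' intersection popcount reaches this value satisfies `Tanimoto >= T`, and
#' no smaller intersection does.  Computed once per popcount bin, it
#' reduces the threshold test to a single integer comparison.
#'
#' @param threshold A positive threshold (number, string, or
#'   `rational_threshold`).  A threshold of 0 is an error: threshold-0
#'   searches match everything and bypass this bound.
#' @param A,B Integer popcounts (vectorized, recycled).
#' @return Integer vector of minimum required intersection popcounts.
#' @examples
#' min_required_popcount(0.75, 8, 8)  # 7
#' @export
min_required_popcount <- function(threshold, A, B) {
  rt <- rational_threshold(threshold)
  if (rt$p == 0) stop("threshold must be > 0")
  n <- max(length(A), length(B))
  A <- rep_len(as.integer(A), n)
  B <- rep_len(as.integer(B), n)
  if (any(A < 0) || any(B < 0)) stop("popcounts must be non-negative")
  cpp_min_required_popcount(rt$p, rt$q, A, B)
}
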