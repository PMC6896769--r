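#' Fingerprint metadata
#'
#' Describes a set of fingerprints: the bit length, how the fingerprints
#' were generated (the canonical type string), and provenance (software,
#' sources, date).  This mirrors the metadata lines of an FPS header.
#'
#' When `num_bits` is not a multiple of 8 the fingerprint is stored in
#' `ceiling(num_bits / 8)` bytes and the bits at index `num_bits` and above
#' must be zero.
#'
#' @param num_bits Positive integer; number of bits in each fingerprint.
#' @param type Optional canonical fingerprint type string, e.g.
#'   `"OpenBabel-FP2/1"`.
#' @param software Optional text describing the generating software.
#' @param sources Character vector of input sources (zero or more).
#' @param date Optional ISO-8601 datetime text.
#' @param extra List of additional header entries.  Each element is a
#'   character vector `c(key, value)`; unparseable comment lines are kept
#'   with `key = NA`.
#' @return An object of class `fp_metadata` with fields `num_bits`,
#'   `num_bytes`, `type`, `software`, `sources`, `date`, `extra`.
#' @examples
#' fp_metadata(166, type = "OpenEye-MACCS166/3")
#' @export
fp_metadata <- function(num_bits, type = NULL, software = NULL,
                        sources = character(), date = NULL, extra = list()) {
  num_bits <- as.integer(num_bits)
  if (length(num_bits) != 1L || is.na(num_bits) || num_bits < 1L)
    stop("num_bits must be a single positive integer")
  structure(
    list(
      num_bits  = num_bits,
      num_bytes = as.integer(ceiling(num_bits / 8)),
      type      = if (is.null(type)) NULL else as.character(type),
      software  = if (is.null(software)) NULL else as.character(software),
      sources   = as.character(sources),
      date      = if (is.null(date)) NULL else as.character(date),
      extra     = extra
    ),
    class = "fp_metadata"
  )
}

#' @export
print.fp_metadata <- function(x, ...) {
  cat("<fp_metadata> ", x$num_bits, " bits (", x$num_bytes, " bytes)\n", sep = "")
  if (!is.null(x$type)) cat("  type:     ", x$type, "\n", sep = "")
  if (!is.null(x$software)) cat("  software: ", x$software, "\n", sep = "")
  for (s in x$sources) cat("  source:   ", s, "\n", sep = "")
  if (!is.null(x$date)) cat("  date:     ", x$date, "\n", sep = "")
  if (length(x$extra)) cat("  +", length(x$extra), "extra header line(s)\n")
  invisible(x)
}

# number of zero pad bits in the last byte
pad_bits <- function(metadata) 8L * metadata$num_bytes - metadata$num_bits
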