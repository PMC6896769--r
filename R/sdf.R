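# ---------------------------------------------------------------------------
# Minimal SD-file scanning for pre-computed fingerprints.
#
# Records are parsed only to the depth needed here: the title line and the
# data items ("> <TAG>" header, value lines up to the next blank line).
# Connection tables are never interpreted, so V2000 and V3000 records are
# handled alike.

#' Read titles and data tags from an SD file
#'
#' @param path Path to an SD file (records separated by `$$$$`).
#' @return A list with one element per record: `list(title =, tags =)`
#'   where `tags` is a named character vector (multi-line values are
#'   joined with newlines).
#' @export
read_sdf_tags <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  ends <- which(lines == "$$$$")
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (r in seq_along(ends)) {
    rec <- lines[seq.int(starts[r], ends[r] - 1L)]
    if (length(rec) == 0L) next
    tags <- character()
    i <- 1L
    while (i <= length(rec)) {
      m <- regmatches(rec[i], regexec("^>.*<([^<>]+)>", rec[i]))[[1L]]
      if (length(m) == 2L) {
        j <- i + 1L
        vals <- character()
        while (j <= length(rec) && nzchar(rec[j])) {
          vals <- c(vals, rec[j])
          j <- j + 1L
        }
        tags[m[2L]] <- paste(vals, collapse = "\n")
        i <- j
      } else {
        i <- i + 1L
      }
    }
    out[[r]] <- list(title = rec[1L], tags = tags)
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Decode a fingerprint stored in an SD data tag
#'
#' Supported encodings: `"hex"`; `"base64"`; `"binary01-lsb"` — a string
#' of '0'/'1' characters where character `i` is bit `i - 1`; and
#' `"binary01-msb"` — the same string with the highest bit index first.
#' The `"pubchem"` decoder handles the PUBCHEM_CACTVS_SUBSKEYS convention:
#' base64 with a 4-byte big-endian bit-count prefix, which is stripped
#' (experimental; the exact CACTVS bit order is not normative here).
#'
#' @param value Tag text (surrounding whitespace is ignored).
#' @param decoder One of `"hex"`, `"base64"`, `"binary01-lsb"`,
#'   `"binary01-msb"`, `"pubchem"`.
#' @return A list with `fp` (raw vector) and `num_bits` (integer or `NA`
#'   when only the byte length is known).
#' @export
decode_fp_tag <- function(value,
                          decoder = c("hex", "base64", "binary01-lsb",
                                      "binary01-msb", "pubchem")) {
  decoder <- match.arg(decoder)
  value <- gsub("[ \t\r\n]", "", value)
  if (!nzchar(value)) stop("empty fingerprint tag value")
  switch(decoder,
    hex = list(fp = cpp_hex_decode(value), num_bits = NA_integer_),
    base64 = list(fp = jsonlite::base64_dec(value), num_bits = NA_integer_),
    `binary01-lsb` = decode_binary01(value, msb = FALSE),
    `binary01-msb` = decode_binary01(value, msb = TRUE),
    pubchem = {
      b <- jsonlite::base64_dec(value)
      if (length(b) < 5) stop("PubChem fingerprint value too short")
      nbits <- sum(as.numeric(b[1:4]) * 256^(3:0))
      list(fp = b[-(1:4)], num_bits = as.integer(nbits))
    })
}

decode_binary01 <- function(value, msb) {
  if (grepl("[^01]", value)) stop("binary01 value contains characters other than 0/1")
  bits <- strtoi(strsplit(value, "", fixed = TRUE)[[1L]], base = 10L)
  num_bits <- length(bits)
  if (msb) bits <- rev(bits)
  pad <- (-num_bits) %% 8
  fp <- packBits(c(bits, integer(pad)) != 0L, type = "raw")
  list(fp = fp, num_bits = num_bits)
}
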