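#' A set of fingerprint records
#'
#' A lightweight container for `n` equal-length fingerprints: the ids, the
#' fingerprint bytes (stored contiguously), and the shared metadata.
#' Records keep their input order; duplicate ids are allowed.
#'
#' @param ids Character vector of non-empty record ids.  Ids may not
#'   contain tab or newline characters.
#' @param fingerprints Either a list of raw vectors (one per record, all
#'   the same length) or a single raw vector of `n * num_bytes` packed
#'   bytes.
#' @param metadata An [fp_metadata()] object, or `NULL` to infer
#'   `num_bits = 8 * num_bytes`.
#' @param extra Optional character vector of per-record extra-field text
#'   (the tab-separated fields after the id, verbatim), preserved on
#'   pass-through but otherwise ignored.
#' @return An object of class `fps_records` with fields `metadata`, `ids`,
#'   `block`, `n`, `num_bytes`, `extra`.
#' @export
fps_records <- function(ids, fingerprints, metadata = NULL, extra = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n > 0 && (anyNA(ids) || any(!nzchar(ids))))
    stop("record ids must be non-empty")
  bad <- grepl("[\t\n\r]", ids)
  if (any(bad)) stop("record id contains tab/newline: ", ids[which(bad)[1L]])

  if (is.list(fingerprints)) {
    if (length(fingerprints) != n)
      stop("ids and fingerprints have different lengths")
    lens <- lengths(fingerprints)
    if (n > 0) {
      if (any(lens == 0)) stop("0-length fingerprints are not allowed")
      if (length(unique(lens)) != 1L) {
        i <- which(lens != lens[1L])[1L]
        stop("fingerprint length mismatch for record '", ids[i], "'")
      }
    }
    num_bytes <- if (n > 0) lens[1L] else 0L
    block <- do.call(c, c(fingerprints, list(raw(0))))
  } else if (is.raw(fingerprints)) {
    if (n == 0) {
      num_bytes <- 0L
      block <- raw(0)
    } else {
      if (length(fingerprints) %% n != 0)
        stop("packed fingerprint block length is not a multiple of the record count")
      num_bytes <- length(fingerprints) %/% n
      if (num_bytes == 0) stop("0-length fingerprints are not allowed")
      block <- fingerprints
    }
  } else {
    stop("fingerprints must be a list of raw vectors or a packed raw vector")
  }

  if (is.null(metadata)) {
    metadata <- if (num_bytes > 0) fp_metadata(8L * num_bytes) else NULL
  } else {
    stopifnot(inherits(metadata, "fp_metadata"))
    if (n > 0 && metadata$num_bytes != num_bytes)
      stop("fingerprints have ", num_bytes, " bytes but metadata num_bits=",
           metadata$num_bits, " implies ", metadata$num_bytes)
  }
  if (!is.null(extra)) {
    extra <- as.character(extra)
    stopifnot(length(extra) == n)
    if (all(!nzchar(extra))) extra <- NULL
  }
  structure(
    list(metadata = metadata, ids = ids, block = block,
         n = n, num_bytes = as.integer(num_bytes), extra = extra),
    class = "fps_records"
  )
}

#' @export
length.fps_records <- function(x) x$n

#' @export
print.fps_records <- function(x, ...) {
  cat("<fps_records> ", x$n, " records, ",
      if (is.null(x$metadata)) "unknown bit length" else
        paste0(x$metadata$num_bits, " bits"), "\n", sep = "")
  invisible(x)
}

#' Extract one fingerprint from a record set
#'
#' @param x An `fps_records` object.
#' @param i Record index (1-based).
#' @return A raw vector of `num_bytes` bytes.
#' @export
fps_fingerprint <- function(x, i) {
  stopifnot(inherits(x, "fps_records"), i >= 1, i <= x$n)
  cpp_block_slot(x$block, as.integer(i), x$num_bytes, x$num_bytes, 0L)
}

#' Subset a record set
#'
#' @param x An `fps_records` object.
#' @param i Integer indices (may repeat; order is kept).
#' @param ... Ignored.
#' @return A new `fps_records` with the selected records.
#' @export
`[.fps_records` <- function(x, i, ...) {
  i <- as.integer(i)
  stopifnot(all(i >= 1L & i <= x$n))
  byte_idx <- rep((i - 1L) * x$num_bytes, each = x$num_bytes) +
    seq_len(x$num_bytes)
  fps_records(x$ids[i], x$block[byte_idx], metadata = x$metadata,
              extra = if (is.null(x$extra)) NULL else x$extra[i])
}

# ---------------------------------------------------------------------------
# FPS header handling

fps_metadata_keys <- c("num_bits", "type", "software", "source", "date")

# Parse the '#' header lines of an FPS stream into (metadata fields, version).
# Returns list(version, num_bits, type, software, sources, date, extra).
parse_fps_header <- function(lines) {
  out <- list(version = NULL, num_bits = NULL, type = NULL, software = NULL,
              sources = character(), date = NULL, extra = list())
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (k == 1L && grepl("^#FPS[0-9]", ln)) {
      out$version <- sub("^#", "", ln)
      next
    }
    m <- regmatches(ln, regexec("^#([A-Za-z0-9_.-]+)=(.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      key <- m[2L]; value <- m[3L]
      switch(key,
        num_bits = {
          nb <- suppressWarnings(as.integer(value))
          if (is.na(nb) || nb < 1L)
            stop("header line ", k, ": invalid num_bits value '", value, "'")
          out$num_bits <- nb
        },
        type = out$type <- value,
        software = out$software <- value,
        source = out$sources <- c(out$sources, value),
        date = out$date <- value,
        out$extra <- c(out$extra, list(c(key, value)))
      )
    } else {
      # unparseable '#' line: carried as an opaque comment
      out$extra <- c(out$extra, list(c(NA_character_, sub("^#", "", ln))))
    }
  }
  out
}

header_to_metadata <- function(h, num_bytes) {
  num_bits <- h$num_bits
  if (is.null(num_bits)) {
    if (num_bytes == 0) return(NULL)  # empty file, nothing to infer from
    num_bits <- 8L * num_bytes
  }
  fp_metadata(num_bits, type = h$type, software = h$software,
              sources = h$sources, date = h$date, extra = h$extra)
}

# Canonical FPS header lines for a metadata object (version line included).
fps_header_lines <- function(metadata, version = "FPS1") {
  lines <- paste0("#", version)
  if (!is.null(metadata)) {
    lines <- c(lines, paste0("#num_bits=", metadata$num_bits))
    if (!is.null(metadata$type)) lines <- c(lines, paste0("#type=", metadata$type))
    if (!is.null(metadata$software))
      lines <- c(lines, paste0("#software=", metadata$software))
    for (s in metadata$sources) lines <- c(lines, paste0("#source=", s))
    if (!is.null(metadata$date)) lines <- c(lines, paste0("#date=", metadata$date))
    for (e in metadata$extra) {
      lines <- c(lines,
                 if (is.na(e[1L])) paste0("#", e[2L])
                 else paste0("#", e[1L], "=", e[2L]))
    }
  }
  lines
}

# ---------------------------------------------------------------------------
# reading and writing

# open a text connection; gzip is detected from the magic bytes
open_fps_source <- function(source) {
  if (inherits(source, "connection")) return(source)
  stopifnot(is.character(source), length(source) == 1L)
  if (!file.exists(source)) stop("no such file: ", source)
  magic <- readBin(source, "raw", n = 2L)
  if (length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b))
    gzfile(source, "rt")
  else
    file(source, "rt")
}

#' Read an FPS file
#'
#' Reads the line-oriented FPS text format: an optional header of
#' '#'-prefixed lines (version line plus metadata), then one record per
#' line with two or more tab-separated fields — the hex-encoded fingerprint
#' first, then the record id.  Remaining fields are preserved in `extra`
#' but otherwise ignored.  Gzip compression is detected automatically from
#' the file's magic bytes.  Validation is total: every line is checked, and
#' format errors report the offending line number.  When the header has no
#' `num_bits` line the bit length is inferred as `8 * num_bytes` from the
#' first record.
#'
#' @param source Path to a `.fps` or `.fps.gz` file, or a text connection.
#' @return An [fps_records()] object (possibly empty).
#' @seealso [write_fps()]
#' @export
read_fps <- function(source) {
  con <- open_fps_source(source)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("\r$", "", lines)  # accept CRLF, normalise to LF semantics
  nheader <- 0L
  while (nheader < length(lines) && startsWith(lines[nheader + 1L], "#"))
    nheader <- nheader + 1L
  h <- parse_fps_header(lines[seq_len(nheader)])
  body <- lines[seq.int(nheader + 1L, length.out = length(lines) - nheader)]
  body <- body[!(seq_along(body) == length(body) & body == "")]
  parsed <- cpp_parse_fps_lines(body, nheader + 1L,
                                if (is.null(h$num_bits)) -1L else h$num_bits)
  metadata <- header_to_metadata(h, parsed$num_bytes)
  fps_records(parsed$ids, parsed$block, metadata = metadata,
              extra = parsed$extra)
}

#' Write an FPS file
#'
#' Emits the version line (`#FPS1`), the metadata lines in canonical order
#' (`num_bits`, `type`, `software`, one `source` per entry, `date`, then
#' any extra lines), and one `"<hexfp>\t<id>"` line per record with
#' lowercase hex.  Per-record extra fields, when present, are appended
#' verbatim.
#'
#' @param x An `fps_records` object (or an `fp_arena`, written in arena
#'   order).
#' @param path Output path.  A `.gz` suffix (or `gzip = TRUE`) writes
#'   gzip-compressed output.
#' @param gzip `"auto"` (by suffix), `TRUE`, or `FALSE`.
#' @return The number of records written, invisibly.
#' @export
write_fps <- function(x, path, gzip = "auto") {
  if (inherits(x, "fp_arena")) x <- as_fps_records(x)
  stopifnot(inherits(x, "fps_records"))
  use_gz <- if (identical(gzip, "auto")) endsWith(path, ".gz") else isTRUE(gzip)
  con <- if (use_gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  lines <- fps_header_lines(x$metadata)
  if (x$n > 0) {
    hex <- cpp_hex_encode_block(x$block, x$n, x$num_bytes, x$num_bytes, 0L)
    rec <- paste(hex, x$ids, sep = "\t")
    if (!is.null(x$extra)) {
      has <- nzchar(x$extra)
      rec[has] <- paste(rec[has], x$extra[has], sep = "\t")
    }
    lines <- c(lines, rec)
  }
  writeLines(lines, con, sep = "\n")
  invisible(x$n)
}

# ---------------------------------------------------------------------------
# type strings and thresholds

#' Parse a canonical fingerprint type string
#'
#' A type string has one or more terms separated by single spaces.  The
#' first term is the family name with an optional `/version`; every
#' remaining term is a `key=value` pair describing the generation
#' parameters.  Type strings are canonical: two strings describe the same
#' fingerprint type if and only if they are equal, so
#' `format_type_string(parse_type_string(s)) == s` for canonical input.
#'
#' @param type_string Text such as
#'   `"RDKit-Morgan/1 radius=2 fpSize=2048"`.
#' @return A list with `family`, `version` (or `NULL`), and `parameters`
#'   (named character vector, possibly empty, in input order).
#' @export
parse_type_string <- function(type_string) {
  stopifnot(is.character(type_string), length(type_string) == 1L)
  terms <- strsplit(type_string, " ", fixed = TRUE)[[1L]]
  if (length(terms) == 0L || !nzchar(terms[1L]))
    stop("empty fingerprint type string")
  if (any(!nzchar(terms)))
    stop("type string terms must be separated by single spaces")
  first <- strsplit(terms[1L], "/", fixed = TRUE)[[1L]]
  family <- first[1L]
  version <- if (length(first) > 1L) paste(first[-1L], collapse = "/") else NULL
  params <- character()
  for (term in terms[-1L]) {
    eq <- regexpr("=", term, fixed = TRUE)
    if (eq < 0)
      stop("type string term '", term, "' is not a key=value pair")
    params[substr(term, 1L, eq - 1L)] <- substr(term, eq + 1L, nchar(term))
  }
  list(family = family, version = version, parameters = params)
}

#' @rdname parse_type_string
#' @param parsed A list as returned by `parse_type_string()`.
#' @export
format_type_string <- function(parsed) {
  first <- if (is.null(parsed$version)) parsed$family
           else paste0(parsed$family, "/", parsed$version)
  if (length(parsed$parameters) == 0L) return(first)
  paste(c(first, paste0(names(parsed$parameters), "=", parsed$parameters)),
        collapse = " ")
}

#' Parse a decimal threshold string
#'
#' Converts plain decimal text to the nearest double and then to an exact
#' [rational_threshold()].  Expressions are not parsed — only plain
#' decimals (optionally with an exponent).  A documented consequence of
#' going through the double is that any decimal whose nearest double equals
#' that of `"0.7"` behaves identically to `0.7`: the written-out expansion
#' of 0.7 + 1e-17 has the same double representation, hence the same
#' rational threshold and the same hit sets.
#'
#' @param text Decimal text in `[0, 1]`, e.g. `"0.75"`.
#' @return A `rational_threshold`.
#' @export
parse_threshold <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!grepl("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$", text))
    stop("not a plain decimal threshold: '", text, "'")
  t <- as.numeric(text)
  if (is.na(t) || t < 0 || t > 1)
    stop("threshold must be in [0, 1], got '", text, "'")
  rational_threshold(t)
}
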