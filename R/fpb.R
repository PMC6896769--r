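# ---------------------------------------------------------------------------
# FPB: a chunked binary fingerprint container in the FourCC tradition.
#
# Layout of this dialect (not claimed wire-compatible with other tools'
# FPB files; all integers little-endian):
#   8-byte signature "FPB1\r\n\0\0"
#   chunks: u64 payload length, 4 ASCII tag bytes, u32 reserved (0),
#           then the payload — a 16-byte header per chunk
#   processing ends at the FEND chunk; unknown tags are skipped.
#
# Chunk payloads:
#   META  FPS header lines verbatim, '#' and newlines included
#   AREN  u32 num_bytes, u32 storage_size, u8 spacer length, spacer zeros,
#         then the fingerprints as one contiguous block.  The spacer
#         aligns the first fingerprint in the file: to 64 bytes when the
#         storage size is a multiple of 64, else to 8 bytes.
#   POPC  u32 popcount bin start indices (num_bits + 2 entries); present
#         iff the arena is popcount-sorted
#   FPID  u32 record count, u32 cumulative byte end-offsets, then the
#         UTF-8 id bytes concatenated
#   HASH  a cdb-style two-level hash table mapping id -> record indices
#         (multi-valued; duplicate ids are allowed)
#   FEND  empty

FPB_SIGNATURE <- as.raw(c(0x46, 0x50, 0x42, 0x31, 0x0d, 0x0a, 0x00, 0x00))

# --- u32 helpers (R integers are signed; counts/offsets here stay < 2^31,
# but cdb hash values use the full 32-bit range) ---

u32_to_int <- function(x) {
  x <- as.numeric(x)
  as.integer(ifelse(x >= 2^31, x - 2^32, x))
}

u32_raw <- function(x) writeBin(u32_to_int(x), raw(), size = 4L, endian = "little")

read_u32 <- function(r, offset, n) {
  v <- readBin(r[seq.int(offset, length.out = 4L * n)], "integer",
               n = n, size = 4L, endian = "little")
  v <- as.numeric(v)
  v[v < 0] <- v[v < 0] + 2^32
  v
}

# --- cdb hash table (classic two-level constant-database layout, with
# 32-bit offsets; entries are multi-valued via repeated keys) ---

cdb_pack <- function(ids) {
  ids8 <- enc2utf8(ids)
  if (!all(validUTF8(ids8))) stop("record id is not UTF-8 encodable")
  n <- length(ids8)
  klen <- nchar(ids8, type = "bytes")
  h <- cpp_cdb_hash(ids8)
  reclen <- 8 + klen + 4
  recpos <- 2048 + c(0, cumsum(reclen))[seq_len(n)]

  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(n)) {
    writeBin(u32_to_int(c(klen[i], 4)), con, size = 4L, endian = "little")
    writeBin(charToRaw(ids8[i]), con)
    writeBin(u32_to_int(i - 1), con, size = 4L, endian = "little")
  }
  records <- rawConnectionValue(con)

  bucket <- h %% 256
  tbl_pos <- numeric(256)
  tbl_slots <- numeric(256)
  tables <- vector("list", 256)
  pos <- 2048 + length(records)
  for (b in 0:255) {
    e <- which(bucket == b)
    nslots <- 2 * length(e)
    tbl_pos[b + 1] <- pos
    tbl_slots[b + 1] <- nslots
    if (nslots == 0) next
    sh <- numeric(nslots)
    sp <- numeric(nslots)
    for (i in e) {
      s <- (h[i] %/% 256) %% nslots
      while (sp[s + 1] != 0) s <- (s + 1) %% nslots
      sh[s + 1] <- h[i]
      sp[s + 1] <- recpos[i]
    }
    inter <- numeric(2 * nslots)
    inter[c(TRUE, FALSE)] <- sh
    inter[c(FALSE, TRUE)] <- sp
    tables[[b + 1]] <- u32_raw(inter)
    pos <- pos + 8 * nslots
  }
  header <- numeric(512)
  header[c(TRUE, FALSE)] <- tbl_pos
  header[c(FALSE, TRUE)] <- tbl_slots
  c(u32_raw(header), records, do.call(c, c(tables[!vapply(tables, is.null, TRUE)],
                                           list(raw(0)))))
}

cdb_lookup <- function(payload, id) {
  id8 <- enc2utf8(id)
  h <- cpp_cdb_hash(id8)
  b <- h %% 256
  hdr <- read_u32(payload, 8 * b + 1, 2)
  pos <- hdr[1]
  nslots <- hdr[2]
  if (nslots == 0) return(integer(0))
  key_raw <- charToRaw(id8)
  out <- numeric(0)
  s <- (h %/% 256) %% nslots
  for (step in seq_len(nslots)) {
    slot <- read_u32(payload, pos + 8 * s + 1, 2)
    if (slot[2] == 0) break  # empty slot terminates the probe
    if (slot[1] == h) {
      rp <- slot[2]
      kl <- read_u32(payload, rp + 1, 1)
      if (kl == length(key_raw)) {
        key <- payload[seq.int(rp + 9, length.out = kl)]
        if (identical(key, key_raw))
          out <- c(out, read_u32(payload, rp + 9 + kl, 1))
      }
    }
    s <- (s + 1) %% nslots
  }
  sort(as.integer(out + 1))
}

# ---------------------------------------------------------------------------
# writing

fpb_chunk <- function(tag, payload) {
  stopifnot(nchar(tag) == 4L)
  len <- length(payload)
  c(u32_raw(c(len %% 2^32, len %/% 2^32)), charToRaw(tag), u32_raw(0),
    payload)
}

#' Write an arena to an FPB file
#'
#' Serialises an arena to the chunked FPB binary format: META (the FPS
#' header lines verbatim), AREN (the contiguous fingerprint block with its
#' alignment spacer), POPC (popcount bin boundaries, sorted arenas only),
#' FPID (the ids with an offset table), HASH (a cdb-style id hash), and
#' FEND.  [read_fpb()] on the output reconstructs an equal arena.  The
#' 32-bit hash table design caps the record count (the practical ceiling
#' is a few hundred million records).
#'
#' @param arena An [fp_arena()] (sorted or unsorted, at least one record).
#' @param path Output path.
#' @return Total bytes written, invisibly.
#' @export
write_fpb <- function(arena, path) {
  stopifnot(inherits(arena, "fp_arena"))
  if (arena$n < 1) stop("cannot write an empty fingerprint set")
  if (arena$n >= 2^31)
    stop("record count exceeds the 32-bit hash table design limit")
  meta_txt <- paste0(paste(fps_header_lines(arena$metadata), collapse = "\n"),
                     "\n")
  META <- charToRaw(meta_txt)

  # the spacer aligns the first fingerprint byte within the file
  pos0 <- 8 + (16 + length(META)) + 16 + 9
  target <- arena$alignment
  spacer <- (target - (pos0 %% target)) %% target
  fp_block <- arena$block[seq.int(arena$start_padding + 1,
                                  length.out = arena$n * arena$storage_size)]
  AREN <- c(u32_raw(c(arena$num_bytes, arena$storage_size)), as.raw(spacer),
            raw(spacer), fp_block)

  chunks <- list(fpb_chunk("META", META), fpb_chunk("AREN", AREN))
  if (arena$sorted)
    chunks <- c(chunks, list(fpb_chunk("POPC", u32_raw(arena$popcount_index))))
  ids8 <- enc2utf8(arena$ids)
  if (!all(validUTF8(ids8))) stop("record id is not UTF-8 encodable")
  idbytes <- charToRaw(paste(ids8, collapse = ""))
  offsets <- cumsum(nchar(ids8, type = "bytes"))
  FPID <- c(u32_raw(arena$n), u32_raw(offsets), idbytes)
  chunks <- c(chunks, list(fpb_chunk("FPID", FPID),
                           fpb_chunk("HASH", cdb_pack(arena$ids)),
                           fpb_chunk("FEND", raw(0))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FPB_SIGNATURE, con)
  total <- 8
  for (ch in chunks) {
    writeBin(ch, con)
    total <- total + length(ch)
  }
  invisible(total)
}

# ---------------------------------------------------------------------------
# reading

read_file_slice <- function(path, offset, len) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, offset)
  out <- readBin(con, "raw", n = len)
  if (length(out) != len) stop("truncated read from ", path)
  out
}

#' Read an FPB file
#'
#' Walks the chunk directory and loads the metadata; with `lazy = TRUE`
#' (the default) the fingerprint block, the id table, and the id hash stay
#' on disk and are read on demand — [fpb_arena()] and [lookup_id()] resolve
#' against the file and cache what they load.  With `lazy = FALSE` all
#' payloads are materialised immediately.  Unknown chunk tags are skipped
#' without error, so extended files remain readable.
#'
#' @param path Path to an FPB file.
#' @param lazy Defer payload loading?
#' @return An object of class `fpb_file` with fields `path`, `chunks`
#'   (a data frame of tag/offset/length), and `metadata`.
#' @export
read_fpb <- function(path, lazy = TRUE) {
  size <- file.size(path)
  if (is.na(size) || size < 8) stop("not an FPB file (too short): ", path)
  sig <- read_file_slice(path, 0, 8)
  if (!identical(sig, FPB_SIGNATURE))
    stop("bad FPB signature in ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 8)
  pos <- 8
  tags <- character()
  offs <- numeric()
  lens <- numeric()
  saw_fend <- FALSE
  while (pos < size) {
    hdr <- readBin(con, "raw", n = 16L)
    if (length(hdr) < 16L) stop("truncated chunk header at byte ", pos)
    len <- read_u32(hdr, 1, 1) + 2^32 * read_u32(hdr, 5, 1)
    tag <- rawToChar(hdr[9:12])
    pos <- pos + 16
    if (pos + len > size) stop("truncated ", tag, " chunk")
    tags <- c(tags, tag)
    offs <- c(offs, pos)
    lens <- c(lens, len)
    if (tag == "FEND") { saw_fend <- TRUE; break }
    seek(con, len, origin = "current")
    pos <- pos + len
  }
  if (!saw_fend) stop("missing FEND chunk")
  chunks <- data.frame(tag = tags, offset = offs, length = lens,
                       stringsAsFactors = FALSE)
  for (req in c("META", "AREN", "FPID"))
    if (!req %in% chunks$tag) stop("missing required chunk ", req)

  meta_lines <- strsplit(rawToChar(fpb_chunk_payload(path, chunks, "META")),
                         "\n", fixed = TRUE)[[1L]]
  h <- parse_fps_header(meta_lines[startsWith(meta_lines, "#")])

  # basic geometry comes from the first 9 AREN bytes (a tiny read)
  aren <- chunks[chunks$tag == "AREN", ][1L, ]
  head9 <- read_file_slice(path, aren$offset, 9)
  num_bytes <- as.integer(read_u32(head9, 1, 1))
  storage <- as.integer(read_u32(head9, 5, 1))
  spacer <- as.integer(head9[9])
  n <- (aren$length - 9 - spacer) / storage
  if (n != round(n)) stop("corrupt AREN chunk geometry")
  metadata <- header_to_metadata(h, num_bytes)

  x <- structure(
    list(path = path, size = size, chunks = chunks, metadata = metadata,
         n = as.integer(n), num_bytes = num_bytes, storage_size = storage,
         spacer = spacer, lazy = isTRUE(lazy),
         cache = new.env(parent = emptyenv())),
    class = "fpb_file"
  )
  if (!lazy) {
    x$cache$arena <- fpb_arena(x)
    if ("HASH" %in% chunks$tag)
      x$cache$hash <- fpb_chunk_payload(path, chunks, "HASH")
  }
  x
}

fpb_chunk_payload <- function(path, chunks, tag) {
  row <- chunks[chunks$tag == tag, ]
  if (nrow(row) == 0) return(NULL)
  read_file_slice(path, row$offset[1L], row$length[1L])
}

#' @export
print.fpb_file <- function(x, ...) {
  cat("<fpb_file> ", x$path, ": ", x$n, " fingerprints x ",
      x$metadata$num_bits, " bits; chunks ",
      paste(x$chunks$tag, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Materialise the arena stored in an FPB file
#'
#' Loads (and caches) the AREN/POPC/FPID payloads and reconstructs the
#' [fp_arena()].  Searching the result is identical to searching the arena
#' the file was written from.
#'
#' @param x An `fpb_file`.
#' @return An `fp_arena`.
#' @export
fpb_arena <- function(x) {
  stopifnot(inherits(x, "fpb_file"))
  if (!is.null(x$cache$arena)) return(x$cache$arena)
  aren <- fpb_chunk_payload(x$path, x$chunks, "AREN")
  block <- aren[seq.int(10 + x$spacer, length.out = x$n * x$storage_size)]
  ids <- fpb_ids(x)
  popc_raw <- fpb_chunk_payload(x$path, x$chunks, "POPC")
  num_bits <- x$metadata$num_bits
  if (!is.null(popc_raw)) {
    popcount_index <- as.integer(read_u32(popc_raw, 1, num_bits + 2L))
    popcounts <- rep.int(0:num_bits, diff(popcount_index))
    sorted <- TRUE
  } else {
    popcount_index <- NULL
    popcounts <- cpp_block_popcounts(block, x$n, x$num_bytes,
                                     x$storage_size, 0L)
    sorted <- FALSE
  }
  arena <- structure(
    list(metadata = x$metadata, ids = ids, block = block, n = x$n,
         num_bytes = x$num_bytes, storage_size = x$storage_size,
         start_padding = 0L,
         alignment = if (x$storage_size %% 64L == 0L) 64L else 8L,
         popcount_index = popcount_index, popcounts = popcounts,
         id_hash = build_id_hash(ids), sorted = sorted),
    class = "fp_arena"
  )
  x$cache$arena <- arena
  arena
}

fpb_ids <- function(x) {
  fpid <- fpb_chunk_payload(x$path, x$chunks, "FPID")
  n <- read_u32(fpid, 1, 1)
  if (n != x$n) stop("FPID record count disagrees with AREN")
  ends <- read_u32(fpid, 5, n)
  starts <- c(0, ends[-length(ends)])
  bytes <- fpid[seq.int(5 + 4 * n, length.out = ends[length(ends)])]
  if (!any(bytes > as.raw(127))) {  # all-ASCII: byte offsets == char offsets
    return(substring(rawToChar(bytes), starts + 1, ends))
  }
  vapply(seq_len(n), function(i) {
    s <- rawToChar(bytes[seq.int(starts[i] + 1, length.out = ends[i] - starts[i])])
    Encoding(s) <- "UTF-8"
    s
  }, character(1))
}

#' Look up the indices of an id
#'
#' Ids are not unique; every index whose id equals the query is returned,
#' ascending.  An absent id gives an empty result, not an error.
#'
#' @param x An `fp_arena` or `fpb_file`.
#' @param id Record id text.
#' @return Integer vector of record indices.
#' @export
lookup_id <- function(x, id) UseMethod("lookup_id")

#' @export
lookup_id.fp_arena <- function(x, id) arena_lookup_id(x, id)

#' @export
lookup_id.fpb_file <- function(x, id) {
  if (is.null(x$cache$hash)) {
    payload <- fpb_chunk_payload(x$path, x$chunks, "HASH")
    if (is.null(payload)) stop("FPB file has no HASH chunk")
    x$cache$hash <- payload
  }
  cdb_lookup(x$cache$hash, id)
}

# ---------------------------------------------------------------------------
# collated (memory-budgeted) writing

#' Write an FPB file from a stream, spilling to disk
#'
#' Builds an FPB file from a record stream that may not fit the given
#' memory budget: records are accumulated until their fingerprint bytes
#' reach `memory_budget`, each batch is popcount-sorted and spilled to a
#' temporary FPB file, and the spills are collated popcount bin by
#' popcount bin into the final file.  Because each spill preserves
#' first-seen order within a bin and spills are merged in stream order,
#' the output is identical to [write_fpb()] of an arena built from the
#' whole stream at once.
#'
#' @param source An [fps_records()] object, or a function that returns the
#'   next `fps_records` chunk on each call and `NULL` at end of stream.
#' @param path Output path.
#' @param memory_budget Fingerprint-byte budget per in-memory batch.  Must
#'   hold at least one record.
#' @return Total bytes written, invisibly.
#' @export
write_fpb_collated <- function(source, path, memory_budget = 64 * 1024^2) {
  pull <- if (is.function(source)) {
    source
  } else {
    stopifnot(inherits(source, "fps_records"))
    done <- FALSE
    function() {
      if (done) return(NULL)
      done <<- TRUE
      source
    }
  }
  spills <- character()
  on.exit(unlink(spills), add = TRUE)
  acc <- list()
  acc_bytes <- 0
  metadata <- NULL
  flush <- function() {
    if (length(acc) == 0) return()
    recs <- if (length(acc) == 1L) acc[[1L]] else do.call(concat_fps_records, acc)
    tmp <- tempfile(fileext = ".fpb")
    write_fpb(fp_arena(recs), tmp)
    spills <<- c(spills, tmp)
    acc <<- list()
    acc_bytes <<- 0
  }
  repeat {
    chunk <- pull()
    if (is.null(chunk)) break
    stopifnot(inherits(chunk, "fps_records"))
    if (chunk$n == 0) next
    if (is.null(metadata)) metadata <- chunk$metadata
    if (memory_budget < chunk$num_bytes)
      stop("memory budget (", memory_budget,
           " bytes) cannot hold a single fingerprint record")
    # split the chunk so each batch respects the budget
    per <- max(1L, as.integer(memory_budget %/% chunk$num_bytes))
    start <- 1L
    while (start <= chunk$n) {
      take <- min(per - as.integer(acc_bytes %/% chunk$num_bytes),
                  chunk$n - start + 1L)
      if (take <= 0L) { flush(); next }
      part <- chunk[seq.int(start, length.out = take)]
      acc[[length(acc) + 1L]] <- part
      acc_bytes <- acc_bytes + take * chunk$num_bytes
      start <- start + take
      if (acc_bytes >= memory_budget) flush()
    }
  }
  flush()
  if (length(spills) == 0) stop("cannot write an empty fingerprint set")
  if (length(spills) == 1L) {
    nbytes <- file.size(spills[1L])
    file.copy(spills[1L], path, overwrite = TRUE)
    return(invisible(nbytes))
  }
  # collate spills bin by bin
  parts <- lapply(spills, read_fpb, lazy = TRUE)
  num_bits <- parts[[1L]]$metadata$num_bits
  storage <- parts[[1L]]$storage_size
  num_bytes <- parts[[1L]]$num_bytes
  for (p in parts)
    if (p$metadata$num_bits != num_bits)
      stop("spill files disagree on num_bits")
  popidx_list <- lapply(parts, function(p) {
    raw <- fpb_chunk_payload(p$path, p$chunks, "POPC")
    as.integer(read_u32(raw, 1, num_bits + 2L))
  })
  counts <- Reduce(`+`, lapply(popidx_list, diff))
  n <- sum(counts)
  popcount_index <- c(0L, cumsum(counts))
  block <- raw(n * storage)
  ids <- character(n)
  at <- 0L
  for (b in 0:num_bits) {
    for (s in seq_along(parts)) {
      p <- parts[[s]]
      pidx <- popidx_list[[s]]
      nb <- pidx[b + 2L] - pidx[b + 1L]
      if (nb == 0L) next
      aren <- p$chunks[p$chunks$tag == "AREN", ][1L, ]
      off <- aren$offset + 9 + p$spacer + pidx[b + 1L] * storage
      block[seq.int(at * storage + 1L, length.out = nb * storage)] <-
        read_file_slice(p$path, off, nb * storage)
      ids[seq.int(at + 1L, length.out = nb)] <-
        fpb_ids(p)[seq.int(pidx[b + 1L] + 1L, length.out = nb)]
      at <- at + nb
    }
  }
  arena <- structure(
    list(metadata = metadata, ids = ids, block = block, n = n,
         num_bytes = num_bytes, storage_size = storage, start_padding = 0L,
         alignment = if (storage %% 64L == 0L) 64L else 8L,
         popcount_index = popcount_index,
         popcounts = rep.int(0:num_bits, counts),
         id_hash = NULL, sorted = TRUE),
    class = "fp_arena"
  )
  arena$id_hash <- build_id_hash(ids)
  invisible(write_fpb(arena, path))
}

# concatenate record sets sharing a fingerprint length
concat_fps_records <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) p$n > 0, TRUE)]
  if (length(parts) == 0) stop("nothing to concatenate")
  nb <- unique(vapply(parts, function(p) p$num_bytes, integer(1)))
  if (length(nb) != 1L) stop("record sets have different fingerprint lengths")
  extra <- unlist(lapply(parts, function(p)
    if (is.null(p$extra)) character(p$n) else p$extra))
  fps_records(
    unlist(lapply(parts, function(p) p$ids)),
    do.call(c, lapply(parts, function(p) p$block)),
    metadata = parts[[1L]]$metadata,
    extra = extra
  )
}
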