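#' Build a fingerprint arena
#'
#' An arena stores equal-length fingerprints in one contiguous byte block,
#' each record zero-padded to a storage size that is a multiple of 8 bytes
#' (so popcounts can be taken 64 bits at a time).  By default the records
#' are sorted by population count and a popcount index is built: fingerprints
#' with popcount `b` occupy 0-based indices
#' `popcount_index[b] <= i < popcount_index[b + 1]`, with equal adjacent
#' boundaries for empty bins.  The index stores every target popcount
#' implicitly — a search needs only the intersection popcount per
#' comparison — and drives the BitBound pruning.  Ids are kept parallel to
#' the (sorted) fingerprints, and a hash maps each id to all of its
#' indices; duplicate ids and duplicate fingerprints are both allowed (no
#' dedup is performed).
#'
#' Unsorted arenas (`sort = FALSE`) preserve input order and have no
#' popcount index; searching them falls back to a linear scan computing
#' both popcounts.
#'
#' @param x An [fps_records()] object, or anything [read_fps()] returns.
#' @param sort Sort by popcount and build the popcount index?
#' @param alignment Byte alignment for the first fingerprint slot;
#'   default 64 when the storage size is a multiple of 64 bytes, else 8.
#'   (In-memory blocks are allocated at the required alignment, so the
#'   start padding is 0; the value matters for the FPB file layout.)
#' @return An object of class `fp_arena`.
#' @examples
#' recs <- synthetic_fingerprints(100, num_bits = 166, density = 0.25, seed = 1)
#' ar <- fp_arena(recs)
#' ar
#' @export
fp_arena <- function(x, sort = TRUE, alignment = NULL) {
  stopifnot(inherits(x, "fps_records"))
  if (x$n == 0) stop("cannot build an arena from an empty record set")
  metadata <- x$metadata
  num_bytes <- x$num_bytes
  num_bits <- metadata$num_bits
  storage <- 8L * as.integer(ceiling(num_bytes / 8))
  if (is.null(alignment)) alignment <- if (storage %% 64L == 0L) 64L else 8L

  pc <- cpp_block_popcounts(x$block, x$n, num_bytes, num_bytes, 0L)
  if (sort) {
    ord <- order(pc, method = "radix")  # stable: ties keep input order
    counts <- tabulate(pc + 1L, nbins = num_bits + 1L)
    popcount_index <- c(0L, cumsum(counts))  # length num_bits + 2
  } else {
    ord <- seq_len(x$n)
    popcount_index <- NULL
  }
  block <- cpp_pack_block(x$block, x$n, num_bytes, ord, storage, 0L)
  ids <- x$ids[ord]
  arena <- structure(
    list(metadata = metadata, ids = ids, block = block, n = x$n,
         num_bytes = num_bytes, storage_size = storage, start_padding = 0L,
         alignment = as.integer(alignment),
         popcount_index = popcount_index,
         popcounts = pc[ord],
         id_hash = NULL,
         sorted = isTRUE(sort)),
    class = "fp_arena"
  )
  arena$id_hash <- build_id_hash(ids)
  arena
}

build_id_hash <- function(ids) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  groups <- split(seq_along(ids), ids)
  list2env(groups, envir = e)
  e
}

#' @export
print.fp_arena <- function(x, ...) {
  cat("<fp_arena> ", x$n, " fingerprints x ", x$metadata$num_bits, " bits (",
      x$storage_size, " bytes/slot, ",
      if (x$sorted) "popcount-sorted" else "unsorted", ")\n", sep = "")
  invisible(x)
}

#' @export
length.fp_arena <- function(x) x$n

#' Extract one fingerprint from an arena
#'
#' @param arena An `fp_arena`.
#' @param i Index into the arena order (1-based).
#' @param padded Return the zero-padded storage slot instead of the tight
#'   `num_bytes` fingerprint?
#' @return A raw vector.
#' @export
arena_fingerprint <- function(arena, i, padded = FALSE) {
  stopifnot(inherits(arena, "fp_arena"), i >= 1, i <= arena$n)
  nb <- if (padded) arena$storage_size else arena$num_bytes
  cpp_block_slot(arena$block, as.integer(i), nb,
                 arena$storage_size, arena$start_padding)
}

#' Look up all indices of an id
#'
#' Ids are not unique; every matching index is returned, ascending.
#'
#' @param arena An `fp_arena` (or `fpb_file`).
#' @param id Record id text.
#' @return Integer vector of indices (empty when absent).
#' @export
arena_lookup_id <- function(arena, id) {
  stopifnot(inherits(arena, "fp_arena"))
  idx <- arena$id_hash[[id]]
  if (is.null(idx)) integer(0) else sort(idx)
}

#' Convert an arena back to plain records
#'
#' @param arena An `fp_arena`.
#' @return An [fps_records()] object in arena order.
#' @export
as_fps_records <- function(arena) {
  stopifnot(inherits(arena, "fp_arena"))
  slots <- arena$block[seq.int(arena$start_padding + 1L,
                               length.out = arena$n * arena$storage_size)]
  # drop the per-slot padding
  keep <- rep((seq_len(arena$n) - 1L) * arena$storage_size,
              each = arena$num_bytes) + seq_len(arena$num_bytes)
  fps_records(arena$ids, slots[keep], metadata = arena$metadata)
}

# pad a tight query fingerprint to the arena storage size
pad_query <- function(arena, query) {
  stopifnot(is.raw(query))
  if (length(query) != arena$num_bytes)
    stop("query has ", length(query), " bytes but the arena stores ",
         arena$num_bytes, "-byte fingerprints")
  c(query, raw(arena$storage_size - arena$num_bytes))
}
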