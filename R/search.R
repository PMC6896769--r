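# ---------------------------------------------------------------------------
# result plumbing

# Hits are returned as a data frame with columns index, id, score, plus
# attributes carrying the instrumentation counters:
#   candidates — intersection popcounts evaluated (survived BitBound)
#   divisions  — candidates that passed the integer rejection test
make_hits <- function(res, arena, query_id = NULL, ids = NULL) {
  idx <- res$index
  df <- data.frame(
    index = idx,
    id = if (!is.null(ids)) ids else arena$ids[idx],
    score = res$score,
    stringsAsFactors = FALSE
  )
  attr(df, "stats") <- list(candidates = res$candidates,
                            divisions = res$divisions)
  attr(df, "query_id") <- query_id
  class(df) <- c("fp_hits", "data.frame")
  df
}

hit_stats <- function(hits) attr(hits, "stats")

as_query_raw <- function(query) {
  if (is.raw(query)) return(query)
  if (is.character(query) && length(query) == 1L) return(hex_to_fp(query))
  stop("query must be a raw fingerprint or a hex string")
}

# ---------------------------------------------------------------------------
# single-query searches

#' Threshold similarity search of an arena
#'
#' Finds every target with similarity at least `threshold` to the query.
#' On a popcount-sorted arena the BitBound limits apply: for a query
#' popcount `A` only bins `B` with `ceiling(A*T) <= B <= floor(A/T)` are
#' examined, and within each bin a candidate is rejected by comparing its
#' intersection popcount against the per-bin minimum required popcount
#' before any division.  Because the threshold is held as an exact
#' rational, the pruned search returns exactly the hits a brute-force
#' linear scan would.  A threshold of 0 matches every target (zero-popcount
#' pairs score 0); an all-zero query matches nothing at a positive
#' threshold.  Hits are returned in ascending target-index order.
#'
#' @param arena An [fp_arena()].
#' @param query A raw fingerprint of `num_bytes` bytes, or a hex string.
#' @param threshold Similarity threshold in `[0, 1]` (number, decimal
#'   string, or [rational_threshold()]).
#' @param similarity `"tanimoto"` (default) or `"tversky"`.  Tversky search
#'   uses a linear scan with the integer rejection test: no popcount bound
#'   is applied for asymmetric weights (correctness over speed).
#' @param alpha,beta Tversky weights, see [tversky()].
#' @return A data frame of class `fp_hits` with columns `index`, `id`,
#'   `score`, carrying instrumentation counters in `attr(, "stats")`.
#' @export
search_threshold <- function(arena, query, threshold,
                             similarity = c("tanimoto", "tversky"),
                             alpha = 1, beta = 1) {
  stopifnot(inherits(arena, "fp_arena"))
  similarity <- match.arg(similarity)
  q <- pad_query(arena, as_query_raw(query))
  rt <- rational_threshold(threshold)
  if (similarity == "tversky") {
    w <- tversky_weights(alpha, beta)
    res <- cpp_tversky_search(arena$block, arena$n, arena$storage_size,
                              arena$start_padding, q, w[1L], w[2L],
                              rt$p, rt$q, 0L, 0L, -1L)
  } else if (arena$sorted) {
    res <- cpp_threshold_search(arena$block, arena$n, arena$storage_size,
                                arena$start_padding, arena$metadata$num_bits,
                                arena$popcount_index, q, rt$p, rt$q)
  } else {
    res <- cpp_linear_threshold(arena$block, arena$n, arena$storage_size,
                                arena$start_padding, q, rt$p, rt$q)
  }
  make_hits(res, arena)
}

#' k-nearest similarity search of an arena
#'
#' Returns the `k` targets most similar to the query, sorted by descending
#' score; ties at equal score are broken by ascending target index.  On a
#' sorted arena the popcount bins are visited in decreasing order of their
#' best possible score `min(A, B) / max(A, B)` — a constant-memory merge of
#' the two monotonically decreasing sides below and above the query
#' popcount — and the search stops as soon as no unvisited bin can beat
#' the current k-th best score.  `method = "heap"` keeps the best `k` in a
#' bounded priority queue (`O(n log k)`); `method = "counting"` buckets
#' hits by their exact rational score instead — Tanimoto scores are ratios
#' of small integers with few distinct values, so for large `k` the
#' counting sort removes the `log k` factor.  Both methods return
#' identical results.
#'
#' @inheritParams search_threshold
#' @param k Number of neighbors (at least 1).
#' @param threshold Optional minimum similarity; applied as a hard filter,
#'   so fewer than `k` hits may be returned.  Default 0.
#' @param method `"heap"` or `"counting"`.
#' @export
search_knearest <- function(arena, query, k, threshold = 0,
                            method = c("heap", "counting"),
                            similarity = c("tanimoto", "tversky"),
                            alpha = 1, beta = 1) {
  stopifnot(inherits(arena, "fp_arena"))
  method <- match.arg(method)
  similarity <- match.arg(similarity)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be a positive integer")
  q <- pad_query(arena, as_query_raw(query))
  rt <- rational_threshold(threshold)
  if (similarity == "tversky") {
    w <- tversky_weights(alpha, beta)
    res <- cpp_tversky_search(arena$block, arena$n, arena$storage_size,
                              arena$start_padding, q, w[1L], w[2L],
                              rt$p, rt$q, 1L, k, -1L)
  } else if (arena$sorted) {
    fun <- if (method == "heap") cpp_knearest else cpp_knearest_counting
    res <- fun(arena$block, arena$n, arena$storage_size, arena$start_padding,
               arena$metadata$num_bits, arena$popcount_index, q, k,
               rt$p, rt$q, -1L)
  } else {
    res <- knearest_unsorted(arena, q, k, rt)
  }
  make_hits(res, arena)
}

# linear-scan k-nearest for unsorted arenas
knearest_unsorted <- function(arena, q, k, rt) {
  res <- cpp_linear_threshold(arena$block, arena$n, arena$storage_size,
                              arena$start_padding, q, rt$p, rt$q)
  ord <- order(-res$score, res$index)
  take <- head(ord, k)
  list(index = res$index[take], score = res$score[take],
       candidates = res$candidates, divisions = res$divisions)
}

# ---------------------------------------------------------------------------
# multiquery and symmetric searches

# normalise a query collection to list(fps = list of raw, ids = character)
query_list <- function(queries, num_bytes) {
  if (inherits(queries, "fp_arena")) queries <- as_fps_records(queries)
  if (inherits(queries, "fps_records")) {
    fps <- lapply(seq_len(queries$n), function(i) fps_fingerprint(queries, i))
    return(list(fps = fps, ids = queries$ids))
  }
  if (is.raw(queries)) queries <- list(queries)
  if (is.list(queries)) {
    fps <- lapply(queries, as_query_raw)
    return(list(fps = fps, ids = names(queries)))
  }
  if (is.character(queries)) {
    fps <- lapply(queries, hex_to_fp)
    return(list(fps = fps, ids = names(queries)))
  }
  stop("unsupported query collection")
}

#' Multiquery search
#'
#' Runs a threshold or k-nearest search for each query and returns one hit
#' set per query, in input order.  Results are identical to the
#' corresponding single-query calls regardless of `workers` or
#' `sort_queries` (a determinism contract): `workers` only partitions the
#' per-query work across forked processes, and `sort_queries` only groups
#' the execution order by query popcount — which improves memory locality
#' on large target sets — before restoring input order in the output.
#'
#' @inheritParams search_threshold
#' @param queries An `fps_records`, `fp_arena`, list of raw fingerprints,
#'   or character vector of hex strings.
#' @param mode `"threshold"` or `"knearest"`.
#' @param k Neighbors per query (k-nearest mode).
#' @param workers Positive integer worker count.  Values above 1 use
#'   forked parallelism where available and fall back to serial elsewhere.
#' @param sort_queries Group execution order by query popcount?
#' @return A list of `fp_hits` data frames, one per query, input order.
#' @export
search_multiquery <- function(arena, queries, mode = c("threshold", "knearest"),
                              threshold = NULL, k = 1, workers = 1L,
                              sort_queries = FALSE,
                              similarity = c("tanimoto", "tversky"),
                              alpha = 1, beta = 1) {
  stopifnot(inherits(arena, "fp_arena"))
  mode <- match.arg(mode)
  similarity <- match.arg(similarity)
  workers <- as.integer(workers)
  if (length(workers) != 1L || is.na(workers) || workers < 1L)
    stop("workers must be a positive integer")
  if (is.null(threshold)) {
    if (mode == "threshold") stop("a threshold is required in threshold mode")
    threshold <- 0
  }
  ql <- query_list(queries, arena$num_bytes)
  nq <- length(ql$fps)
  if (nq == 0L) return(list())

  exec_order <- seq_len(nq)
  if (isTRUE(sort_queries)) {
    qpc <- vapply(ql$fps, fp_popcount, integer(1))
    exec_order <- order(qpc, method = "radix")
  }
  run_one <- function(j) {
    hits <- if (mode == "threshold")
      search_threshold(arena, ql$fps[[j]], threshold,
                       similarity = similarity, alpha = alpha, beta = beta)
    else
      search_knearest(arena, ql$fps[[j]], k, threshold,
                      similarity = similarity, alpha = alpha, beta = beta)
    if (!is.null(ql$ids)) attr(hits, "query_id") <- ql$ids[j]
    hits
  }
  use_fork <- workers > 1L && .Platform$OS.type == "unix"
  results <- if (use_fork)
    parallel::mclapply(exec_order, run_one, mc.cores = workers)
  else
    lapply(exec_order, run_one)
  out <- vector("list", nq)
  out[exec_order] <- results
  names(out) <- ql$ids
  out
}

#' Symmetric N x N similarity search
#'
#' All-pairs search of a sorted arena against itself; the diagonal is never
#' computed.  In threshold mode the upper triangle is searched once —
#' sorting means a row's partners at `j > i` all live in popcount bins at
#' or above its own, clipped by the BitBound upper limit — and the lower
#' triangle is filled in by mirroring, so the result is symmetric and its
#' entry count is even.  In k-nearest mode each row gets its top `k`
#' excluding itself (duplicate fingerprints at other indices still count).
#'
#' @inheritParams search_multiquery
#' @return Threshold mode: a data frame with columns `i`, `j`, `score`
#'   containing both `(i, j)` and `(j, i)` for every matching pair, ordered
#'   by `i` then `j`, with instrumentation in `attr(, "stats")`.  K-nearest
#'   mode: a list of `fp_hits`, one per row.
#' @export
search_symmetric <- function(arena, mode = c("threshold", "knearest"),
                             threshold = NULL, k = 1, workers = 1L) {
  stopifnot(inherits(arena, "fp_arena"))
  if (!arena$sorted)
    stop("symmetric search requires a popcount-sorted arena")
  mode <- match.arg(mode)
  if (is.null(threshold)) {
    if (mode == "threshold") stop("a threshold is required in threshold mode")
    threshold <- 0
  }
  rt <- rational_threshold(threshold)
  if (mode == "threshold") {
    res <- cpp_symmetric_threshold(arena$block, arena$n, arena$storage_size,
                                   arena$start_padding,
                                   arena$metadata$num_bits,
                                   arena$popcount_index, rt$p, rt$q)
    df <- data.frame(i = c(res$i, res$j), j = c(res$j, res$i),
                     score = c(res$score, res$score))
    df <- df[order(df$i, df$j), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "stats") <- list(candidates = res$candidates,
                              divisions = res$divisions)
    return(df)
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  run_one <- function(i) {
    q <- arena_fingerprint(arena, i, padded = TRUE)
    res <- cpp_knearest(arena$block, arena$n, arena$storage_size,
                        arena$start_padding, arena$metadata$num_bits,
                        arena$popcount_index, q, k, rt$p, rt$q, i - 1L)
    make_hits(res, arena, query_id = arena$ids[i])
  }
  use_fork <- workers > 1L && .Platform$OS.type == "unix"
  if (use_fork) parallel::mclapply(seq_len(arena$n), run_one, mc.cores = workers)
  else lapply(seq_len(arena$n), run_one)
}

# ---------------------------------------------------------------------------
# FPS file-scan search

#' Streaming search of an FPS file
#'
#' Scans an FPS file without building an arena: for each record line the
#' score is computed directly from the hex text, and no fingerprint object
#' is materialised for sub-threshold lines.  Threshold-mode scans validate
#' the whole file (format errors carry line numbers) and return hits in
#' file order; k-nearest scans may stop reading — and stop validating —
#' once `k` exact (score 1.0) matches have been found.  The hit sets are
#' identical to loading the file into an arena and searching it.
#'
#' @param source Path to an FPS or gzip-compressed FPS file.
#' @param query A raw fingerprint or hex string, or a list/record set of
#'   queries (each query triggers its own scan).
#' @param mode `"threshold"` or `"knearest"`.
#' @param threshold Similarity threshold; in k-nearest mode an optional
#'   minimum score, default 0.
#' @param k Neighbors in k-nearest mode.
#' @return For one query, a data frame with columns `recno` (record number
#'   in file order), `id`, `score`; for several, a list of such frames.
#' @export
search_fps_file <- function(source, query, mode = c("threshold", "knearest"),
                            threshold = NULL, k = 1) {
  mode <- match.arg(mode)
  if (is.null(threshold)) {
    if (mode == "threshold") stop("a threshold is required in threshold mode")
    threshold <- 0
  }
  rt <- rational_threshold(threshold)
  k <- as.integer(k)
  if (mode == "knearest" && k < 1L) stop("k must be a positive integer")

  con <- open_fps_source(source)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nheader <- 0L
  while (nheader < length(lines) && startsWith(lines[nheader + 1L], "#"))
    nheader <- nheader + 1L
  h <- parse_fps_header(lines[seq_len(nheader)])
  body <- lines[seq.int(nheader + 1L, length.out = length(lines) - nheader)]

  multi <- (is.list(query) && !is.raw(query)) ||
    inherits(query, "fps_records") || (is.character(query) && length(query) > 1L)
  ql <- query_list(query, NA_integer_)
  scan_one <- function(q) {
    num_bits <- if (!is.null(h$num_bits)) h$num_bits else 8L * length(q)
    if (ceiling(num_bits / 8) != length(q))
      stop("query has ", length(q), " bytes but the target file has num_bits=",
           num_bits)
    res <- cpp_fps_scan(body, nheader + 1L, q, num_bits, rt$p, rt$q,
                        if (mode == "threshold") 0L else 1L, k)
    df <- data.frame(recno = res$recno, id = res$id, score = res$score,
                     stringsAsFactors = FALSE)
    attr(df, "stats") <- list(candidates = res$candidates,
                              scanned = res$scanned)
    class(df) <- c("fp_hits", "data.frame")
    df
  }
  results <- lapply(ql$fps, scan_one)
  if (!multi) results[[1L]] else {
    names(results) <- ql$ids
    results
  }
}
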