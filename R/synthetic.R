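# ---------------------------------------------------------------------------
# synthetic fingerprint generation and the benchmark harness

# Default per-bit densities by fingerprint length, chosen to emulate the
# common fingerprint families at each size: MACCS-like keys at 166 bits
# are fairly dense, PubChem/CACTVS keys at 881 bits and FP2-like path
# fingerprints at 1021 bits are sparser, and 2048-bit Morgan fingerprints
# on drug-like collections have a bit density of about 0.024.
default_density <- function(num_bits) {
  switch(as.character(num_bits),
         "166" = 0.25, "881" = 0.10, "1021" = 0.05, "2048" = 0.024,
         0.10)
}

#' Generate synthetic fingerprint records
#'
#' Two density models are supported.  The uniform-per-bit model sets every
#' bit independently with probability `density`.  The popcount-histogram
#' model takes a vector of requested counts per popcount (index 1 holds
#' popcount 0) and realises that histogram exactly, choosing the set bit
#' positions uniformly at random.  Ids are sequential
#' (`prefix1`, `prefix2`, ...), duplicate fingerprints occur naturally,
#' and no dedup is performed.  Output is deterministic for a fixed seed.
#'
#' @param count Number of records (at least 1).
#' @param num_bits Fingerprint length in bits (166, 881, 1021, and 2048
#'   are the common sizes, but any length works).
#' @param density Per-bit density in (0, 1); defaults by `num_bits` (e.g.
#'   0.024 at 2048 bits, emulating Morgan fingerprints of drug-like
#'   molecules).  Ignored when `popcount_hist` is given.
#' @param popcount_hist Integer vector of length `num_bits + 1` of
#'   requested record counts per popcount; must sum to `count`.
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @param prefix Id prefix.
#' @return An [fps_records()] object.
#' @examples
#' recs <- synthetic_fingerprints(500, num_bits = 2048, seed = 42)
#' pc <- vapply(1:500, function(i) fp_popcount(fps_fingerprint(recs, i)), 1L)
#' mean(pc) / 2048  # ~0.024
#' @export
synthetic_fingerprints <- function(count, num_bits = 2048, density = NULL,
                                   popcount_hist = NULL, seed = NULL,
                                   prefix = "SYN") {
  count <- as.integer(count)
  if (count < 1L) stop("count must be at least 1")
  num_bits <- as.integer(num_bits)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(popcount_hist)) {
    if (is.null(density)) density <- default_density(num_bits)
    if (!is.numeric(density) || density <= 0 || density >= 1)
      stop("density must be in (0, 1)")
    block <- cpp_generate_block(count, num_bits, density)
  } else {
    popcount_hist <- as.integer(popcount_hist)
    if (length(popcount_hist) != num_bits + 1L)
      stop("popcount_hist must have num_bits + 1 entries")
    if (sum(popcount_hist) != count)
      stop("popcount_hist must sum to count")
    popcounts <- sample(rep.int(0:num_bits, popcount_hist))
    block <- cpp_generate_from_popcounts(popcounts, num_bits)
  }
  fps_records(paste0(prefix, seq_len(count)), block,
              metadata = fp_metadata(num_bits,
                                     type = synthetic_type(num_bits, density,
                                                           popcount_hist)))
}

synthetic_type <- function(num_bits, density, popcount_hist) {
  if (is.null(popcount_hist))
    paste0("Synthetic/1 numbits=", num_bits, " density=", format(density))
  else
    paste0("Synthetic/1 numbits=", num_bits, " model=popcount-histogram")
}

#' The standard benchmark task set
#'
#' One threshold task and two k-nearest tasks: find all matches at or
#' above a threshold (0.4 for sparse Morgan-like 2048-bit sets, where it
#' selects everything above background similarity, and 0.7 — a typical
#' "good similarity" search — for the others), and find the k nearest
#' neighbors for k = 1 and k = 1000.
#'
#' @param num_bits Fingerprint length, used to pick the default threshold.
#' @return A data frame with columns `task`, `threshold`, `k`.
#' @export
benchmark_tasks <- function(num_bits = 2048) {
  thr <- if (num_bits >= 2048) 0.4 else 0.7
  data.frame(
    task = c(paste0("threshold-", thr), "knearest-1", "knearest-1000"),
    mode = c("threshold", "knearest", "knearest"),
    threshold = c(thr, 0, 0),
    k = c(NA_integer_, 1L, 1000L),
    stringsAsFactors = FALSE
  )
}

#' Run the instrumented benchmark suite
#'
#' Executes each task over the query set against the target arena and
#' reports, per task: wall time, the number of Tanimoto evaluations
#' (candidates surviving the BitBound popcount pruning), the number of
#' score divisions (candidates passing the integer rejection test), and
#' the effective fingerprint bytes examined
#' (`evaluations * storage_size`).  The counts are deterministic for fixed
#' inputs; the times are not, and are reported for orientation only.
#'
#' @param targets An [fp_arena()], `fps_records`, or path to an FPS/FPB
#'   file.
#' @param queries An `fps_records`, `fp_arena`, or path; by default only
#'   the first `max_queries` queries are used.
#' @param tasks A task data frame as from [benchmark_tasks()].
#' @param max_queries Cap on the number of queries (default 1000).
#' @param repetitions Timing repetitions (counts are identical across
#'   repetitions; the minimum wall time is reported).
#' @param report Optional output stem: writes `<report>.tsv` and
#'   `<report>.json`.
#' @return A data frame with one row per task: `task`, `queries`,
#'   `targets`, `seconds`, `n_tanimoto`, `n_divisions`, `bytes_examined`.
#' @export
run_benchmark <- function(targets, queries, tasks = NULL, max_queries = 1000L,
                          repetitions = 1L, report = NULL) {
  arena <- as_benchmark_arena(targets)
  qrecs <- as_benchmark_records(queries)
  if (qrecs$n > max_queries) qrecs <- qrecs[seq_len(max_queries)]
  if (is.null(tasks)) tasks <- benchmark_tasks(arena$metadata$num_bits)
  rows <- vector("list", nrow(tasks))
  for (t in seq_len(nrow(tasks))) {
    mode <- tasks$mode[t]
    secs <- Inf
    for (rep in seq_len(repetitions)) {
      t0 <- proc.time()[["elapsed"]]
      res <- search_multiquery(arena, qrecs, mode = mode,
                               threshold = tasks$threshold[t],
                               k = if (is.na(tasks$k[t])) 1L else tasks$k[t])
      secs <- min(secs, proc.time()[["elapsed"]] - t0)
    }
    stats <- lapply(res, hit_stats)
    n_tan <- sum(vapply(stats, `[[`, numeric(1), "candidates"))
    n_div <- sum(vapply(stats, `[[`, numeric(1), "divisions"))
    rows[[t]] <- data.frame(
      task = tasks$task[t], queries = qrecs$n, targets = arena$n,
      seconds = secs, n_tanimoto = n_tan, n_divisions = n_div,
      bytes_examined = n_tan * arena$storage_size,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (!is.null(report)) {
    utils::write.table(out, paste0(report, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out, paste0(report, ".json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

as_benchmark_arena <- function(x) {
  if (inherits(x, "fp_arena")) return(x)
  if (inherits(x, "fpb_file")) return(fpb_arena(x))
  if (inherits(x, "fps_records")) return(fp_arena(x))
  if (is.character(x) && length(x) == 1L) {
    if (endsWith(x, ".fpb")) return(fpb_arena(read_fpb(x)))
    return(fp_arena(read_fps(x)))
  }
  stop("unsupported target collection")
}

as_benchmark_records <- function(x) {
  if (inherits(x, "fps_records")) return(x)
  if (inherits(x, "fp_arena")) return(as_fps_records(x))
  if (inherits(x, "fpb_file")) return(as_fps_records(fpb_arena(x)))
  if (is.character(x) && length(x) == 1L) {
    if (endsWith(x, ".fpb")) return(as_fps_records(fpb_arena(read_fpb(x))))
    return(read_fps(x))
  }
  stop("unsupported query collection")
}
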