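test_that("FPB files have the expected chunk structure", {
  path <- write_lines_tmp(maccs_fixture_lines())
  ar <- fp_arena(read_fps(path))
  out <- tempfile(fileext = ".fpb")
  nbytes <- write_fpb(ar, out)
  expect_equal(nbytes, file.size(out))
  fpb <- read_fpb(out)
  expect_equal(fpb$chunks$tag,
               c("META", "AREN", "POPC", "FPID", "HASH", "FEND"))
  # chunk walker: signature + sum(16 + payload) == file size
  expect_equal(8 + sum(16 + fpb$chunks$length), file.size(out))
  expect_equal(fpb$metadata$num_bits, 166L)
  expect_equal(fpb$metadata$type, "OpenEye-MACCS166/3")
  # alignment: 166-bit fingerprints pad to 24-byte slots, 8-byte aligned
  aren_off <- fpb$chunks$offset[fpb$chunks$tag == "AREN"]
  expect_equal((aren_off + 9 + fpb$spacer) %% 8, 0)
})

test_that("FPB write -> read round-trips arenas exactly", {
  set.seed(61)
  recs <- random_records(5000, 21L, 166L, density = 0.25)
  ar <- fp_arena(recs)
  out <- tempfile(fileext = ".fpb")
  write_fpb(ar, out)
  back <- fpb_arena(read_fpb(out))
  expect_identical(back$block, ar$block)
  expect_identical(back$ids, ar$ids)
  expect_identical(back$popcount_index, ar$popcount_index)
  expect_equal(back$metadata$num_bits, 166L)
  expect_equal(back$storage_size, ar$storage_size)
  # unsorted arenas round-trip without a POPC chunk
  un <- fp_arena(recs[1:50], sort = FALSE)
  out2 <- tempfile(fileext = ".fpb")
  write_fpb(un, out2)
  fpb2 <- read_fpb(out2)
  expect_false("POPC" %in% fpb2$chunks$tag)
  back2 <- fpb_arena(fpb2)
  expect_false(back2$sorted)
  expect_identical(back2$ids, un$ids)
})

test_that("FPB rejects degenerate input and detects corruption", {
  recs <- fps_records(c("a", "b"), lapply(c("c218", "0100"), hex_to_fp))
  ar <- fp_arena(recs)
  out <- tempfile(fileext = ".fpb")
  write_fpb(ar, out)
  # bad signature
  bad <- readBin(out, "raw", file.size(out))
  bad[1] <- as.raw(0x00)
  f1 <- tempfile(); writeBin(bad, f1)
  expect_error(read_fpb(f1), "signature")
  # truncated mid-chunk
  f2 <- tempfile(); writeBin(head(readBin(out, "raw", file.size(out)), 40), f2)
  expect_error(read_fpb(f2), "truncated")
  # missing FEND
  full <- readBin(out, "raw", file.size(out))
  f3 <- tempfile(); writeBin(head(full, length(full) - 16L), f3)
  expect_error(read_fpb(f3), "FEND")
})

test_that("unknown chunks are skipped without error", {
  recs <- fps_records(c("a", "b"), lapply(c("c218", "0100"), hex_to_fp))
  out <- tempfile(fileext = ".fpb")
  write_fpb(fp_arena(recs), out)
  full <- readBin(out, "raw", file.size(out))
  # splice an XTRA chunk right after META
  meta_end <- 8 + 16 + read_fpb(out)$chunks$length[1]
  xtra <- c(fpsearch:::u32_raw(c(3, 0)), charToRaw("XTRA"),
            fpsearch:::u32_raw(0), as.raw(1:3))
  spliced <- c(head(full, meta_end), xtra,
               full[(meta_end + 1):length(full)])
  f <- tempfile(); writeBin(spliced, f)
  fpb <- read_fpb(f)
  expect_true("XTRA" %in% fpb$chunks$tag)
  back <- fpb_arena(fpb)
  expect_equal(back$ids, fp_arena(recs)$ids)
})

test_that("id lookup via the cdb hash chunk is multi-valued", {
  set.seed(62)
  ids <- paste0("mol", 1:500)
  ids[c(17, 303, 442)] <- "shared"
  recs <- fps_records(ids, lapply(seq_along(ids), function(i) random_fp(4L)))
  ar <- fp_arena(recs, sort = FALSE)  # keep input order -> known indices
  out <- tempfile(fileext = ".fpb")
  write_fpb(ar, out)
  fpb <- read_fpb(out)
  expect_equal(lookup_id(fpb, "shared"), c(17L, 303L, 442L))
  expect_equal(lookup_id(fpb, "mol250"), 250L)
  expect_equal(lookup_id(fpb, "not-there"), integer(0))
  # every id resolves to itself (brute scan of the id table as oracle)
  for (i in sample(500, 25)) {
    expect_true(i %in% lookup_id(fpb, ids[i]))
    expect_equal(lookup_id(fpb, ids[i]), which(ids == ids[i]))
  }
  # UTF-8 ids survive
  u <- fps_records(c("café", "ångström"),
                   lapply(1:2, function(i) random_fp(4L)))
  outu <- tempfile(fileext = ".fpb")
  write_fpb(fp_arena(u, sort = FALSE), outu)
  fpbu <- read_fpb(outu)
  expect_equal(lookup_id(fpbu, "café"), 1L)
  expect_equal(fpb_arena(fpbu)$ids[2], "ångström")
})

test_that("lazy and eager loads search identically", {
  set.seed(63)
  recs <- random_records(1000, 21L, 166L, density = 0.25)
  out <- tempfile(fileext = ".fpb")
  write_fpb(fp_arena(recs), out)
  lazy <- fpb_arena(read_fpb(out, lazy = TRUE))
  eager <- fpb_arena(read_fpb(out, lazy = FALSE))
  for (rep in 1:25) {
    q <- random_fp(21L, 166L, 0.25)
    expect_identical(search_threshold(lazy, q, 0.5)$index,
                     search_threshold(eager, q, 0.5)$index)
    expect_identical(search_knearest(lazy, q, 5L)$score,
                     search_knearest(eager, q, 5L)$score)
  }
})

test_that("collated writing matches the direct write byte for byte", {
  set.seed(64)
  recs <- random_records(5000, 8L, density = 0.3)
  direct <- tempfile(fileext = ".fpb")
  write_fpb(fp_arena(recs), direct)
  # small budget: many spills
  coll <- tempfile(fileext = ".fpb")
  write_fpb_collated(recs, coll, memory_budget = 4000)
  expect_identical(readBin(direct, "raw", file.size(direct)),
                   readBin(coll, "raw", file.size(coll)))
  # stream smaller than the budget: same result
  coll2 <- tempfile(fileext = ".fpb")
  write_fpb_collated(recs, coll2, memory_budget = 1e9)
  expect_identical(readBin(direct, "raw", file.size(direct)),
                   readBin(coll2, "raw", file.size(coll2)))
  # chunked pull function as the stream source
  chunks <- split(seq_len(recs$n), ceiling(seq_len(recs$n) / 700))
  i <- 0L
  pull <- function() {
    i <<- i + 1L
    if (i > length(chunks)) return(NULL)
    recs[chunks[[i]]]
  }
  coll3 <- tempfile(fileext = ".fpb")
  write_fpb_collated(pull, coll3, memory_budget = 2500)
  expect_identical(readBin(direct, "raw", file.size(direct)),
                   readBin(coll3, "raw", file.size(coll3)))
  # budget below one record: graceful error
  expect_error(write_fpb_collated(recs, tempfile(), memory_budget = 4),
               "budget")
})

test_that("FPS -> FPB -> FPS preserves records and metadata", {
  set.seed(65)
  recs <- random_records(300, 21L, 166L, density = 0.25)
  recs$metadata <- fp_metadata(166L, type = "OpenEye-MACCS166/3",
                               sources = "x.sdf", date = "2019-01-01T00:00:00")
  f_fps <- tempfile(fileext = ".fps")
  f_fpb <- tempfile(fileext = ".fpb")
  f_out <- tempfile(fileext = ".fps")
  write_fps(recs, f_fps)
  write_fpb(fp_arena(read_fps(f_fps)), f_fpb)
  write_fps(as_fps_records(fpb_arena(read_fpb(f_fpb))), f_out)
  a <- read_fps(f_fps)
  b <- read_fps(f_out)
  # multiset of (id, fingerprint) pairs is preserved (order may differ)
  key <- function(x) sort(paste(x$ids,
                                fpsearch:::cpp_hex_encode_block(
                                  x$block, x$n, x$num_bytes, x$num_bytes, 0L)))
  expect_equal(key(a), key(b))
  expect_equal(a$metadata, b$metadata)
})
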