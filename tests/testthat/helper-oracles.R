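# Independent per-bit oracles: everything here works on expanded bit
# vectors, with no shared machinery with the arena/search code paths.

oracle_bits <- function(fp) as.logical(rawToBits(fp))

oracle_popcount <- function(fp) sum(oracle_bits(fp))

oracle_intersect <- function(a, b) sum(oracle_bits(a) & oracle_bits(b))

oracle_tanimoto <- function(a, b) {
  u <- sum(oracle_bits(a) | oracle_bits(b))
  if (u == 0) return(0)
  sum(oracle_bits(a) & oracle_bits(b)) / u
}

oracle_tversky <- function(a, b, alpha, beta) {
  A <- oracle_popcount(a)
  B <- oracle_popcount(b)
  cc <- oracle_intersect(a, b)
  den <- alpha * (A - cc) + beta * (B - cc) + cc
  if (den == 0) return(0)
  cc / den
}

# Brute-force score of a query against every record of an fps_records set,
# via the lookup-table + double-division path (independent of the arena
# search machinery).
oracle_scores <- function(recs, query) {
  fpsearch:::cpp_all_scores(recs$block, recs$n, recs$num_bytes, query)
}

# Exact test of c/d >= p/q for integer c, d <= 2^10 and p, q <= 2^53,
# via sign(c*q - p*d) computed in split 27-bit limbs (all doubles stay in
# the exactly-representable integer range).  Independent of the package's
# 128-bit integer path.
oracle_ge_threshold <- function(cc, d, p, q) {
  q1 <- q %/% 2^27; q0 <- q %% 2^27
  p1 <- p %/% 2^27; p0 <- p %% 2^27
  X <- cc * q1 - d * p1
  Y <- cc * q0 - d * p0
  s <- ifelse(abs(X) > 2^11, sign(X), sign(X * 2^27 + Y))
  s >= 0
}

# random fingerprint with zeroed pad bits
random_fp <- function(num_bytes, num_bits = 8L * num_bytes, density = 0.5) {
  bits <- runif(8L * num_bytes) < density
  if (num_bits < 8L * num_bytes) bits[(num_bits + 1L):(8L * num_bytes)] <- FALSE
  packBits(bits, type = "raw")
}

random_records <- function(n, num_bytes, num_bits = 8L * num_bytes,
                           density = 0.5, prefix = "FP") {
  fps <- lapply(seq_len(n), function(i) random_fp(num_bytes, num_bits, density))
  fps_records(paste0(prefix, seq_len(n)), fps,
              metadata = fp_metadata(num_bits))
}

# A 3-record MACCS-style FPS fixture in the style of the format docs.
maccs_fixture_lines <- function() {
  set.seed(166)
  fps <- vapply(1:3, function(i) fp_to_hex(random_fp(21L, 166L, 0.3)), "")
  c("#FPS1",
    "#num_bits=166",
    "#type=OpenEye-MACCS166/3",
    "#software=OEGraphSim/2.2.6",
    "#source=example.sdf",
    "#date=2019-04-24T14:12:03",
    paste(fps, c("CHEMBL25", "CHEMBL1000", "CHEMBL2001"), sep = "\t"))
}

write_lines_tmp <- function(lines, ext = ".fps") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Brute-force threshold oracle over a record set (aligned with arena order
# when given as_fps_records(arena)): vectorized double scores decide all
# clear cases; pairs within 1e-9 of the threshold — only possible when the
# exact score equals the threshold's decimal value — are re-decided with
# the exact split-limb comparison.  No popcount bins, no pruning.
brute_threshold <- function(recs, q, rt) {
  scores <- oracle_scores(recs, q)
  if (rt$p == 0) return(list(hits = seq_len(recs$n), scores = scores))
  T <- rt$original
  hit <- scores >= T + 1e-9
  for (i in which(abs(scores - T) < 1e-9)) {
    b <- fps_fingerprint(recs, i)
    cc <- fp_intersect_popcount(q, b, "lookup8")
    d <- fp_popcount(q, "lookup8") + fp_popcount(b, "lookup8") - cc
    hit[i] <- d > 0 && oracle_ge_threshold(cc, d, rt$p, rt$q)
  }
  list(hits = which(hit), scores = scores)
}

# top-k by (score desc, index asc); double ordering equals exact rational
# ordering here because distinct small-denominator scores are far apart
brute_knearest <- function(recs, q, k, rt = rational_threshold(0)) {
  bt <- brute_threshold(recs, q, rt)
  ord <- bt$hits[order(-bt$scores[bt$hits], bt$hits)]
  take <- head(ord, k)
  list(index = take, score = bt$scores[take])
}

expect_same_hits <- function(hits, idx, scores) {
  expect_equal(hits$index, idx)
  expect_equal(hits$score, scores)
}
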