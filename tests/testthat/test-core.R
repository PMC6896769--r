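test_that("hex codec follows the documented byte/bit ordering", {
  expect_equal(fp_bits(hex_to_fp("0100")), 0L)
  expect_equal(fp_bits(hex_to_fp("2000")), 5L)
  expect_equal(fp_bits(hex_to_fp("c218")), c(1L, 6L, 7L, 11L, 12L))
  expect_equal(fp_popcount(hex_to_fp("c218")), 5L)
  expect_equal(fp_to_hex(hex_to_fp("C218")), "c218")

  # single set bit k decodes from the hex of byte k%/%8 with bit k%%8
  expect_equal(fp_to_hex(packBits(c(rep(FALSE, 0), TRUE, rep(FALSE, 15)),
                                  type = "raw")), "0100")

  expect_error(hex_to_fp("abc"), "odd")
  expect_error(hex_to_fp(""), "empty")
  expect_error(hex_to_fp("0g"), "position 2")
  expect_error(fp_to_hex(raw(0)), "empty")
})

test_that("hex round-trip holds for random byte strings of many lengths", {
  set.seed(11)
  for (nb in c(1L, 2L, 7L, 21L, 64L, 111L, 256L)) {
    fp <- as.raw(sample(0:255, nb, replace = TRUE))
    hex <- fp_to_hex(fp)
    expect_equal(nchar(hex), 2L * nb)
    expect_identical(hex_to_fp(hex), fp)
  }
})

test_that("all popcount kernels agree with the per-bit oracle", {
  set.seed(12)
  expect_equal(fp_popcount(raw(16)), 0L)
  for (nb in c(1L, 3L, 21L, 111L, 128L)) {
    for (rep in 1:10) {
      a <- as.raw(sample(0:255, nb, replace = TRUE))
      b <- as.raw(sample(0:255, nb, replace = TRUE))
      expect_equal(fp_popcount(a, "word64"), oracle_popcount(a))
      expect_equal(fp_popcount(a, "lookup8"), oracle_popcount(a))
      expect_equal(fp_popcount(a, "bitwise"), oracle_popcount(a))
      expect_equal(fp_intersect_popcount(a, b), oracle_intersect(a, b))
      expect_equal(fp_intersect_popcount(a, b, "lookup8"),
                   fp_intersect_popcount(b, a, "word64"))
      expect_equal(fp_intersect_popcount(a, a), fp_popcount(a))
      expect_equal(fp_intersect_popcount(a, raw(nb)), 0L)
    }
  }
  expect_error(fp_intersect_popcount(raw(2), raw(3)), "differ")
  expect_error(fp_popcount(raw(2), "avx512"), "unknown")
})

test_that("tanimoto matches the per-bit oracle and its zero convention", {
  expect_equal(tanimoto(raw(4), raw(4)), 0)
  expect_equal(tanimoto(hex_to_fp("0300"), hex_to_fp("0500")), 1 / 3)
  set.seed(13)
  for (nb in c(21L, 111L, 128L, 256L)) {
    for (rep in 1:25) {
      a <- random_fp(nb, density = runif(1, 0.02, 0.6))
      b <- random_fp(nb, density = runif(1, 0.02, 0.6))
      expect_identical(tanimoto(a, b), oracle_tanimoto(a, b))
      expect_identical(tanimoto(a, b), tanimoto(b, a))
    }
    x <- random_fp(nb, density = 0.3)
    if (oracle_popcount(x) > 0) expect_equal(tanimoto(x, x), 1)
  }
})

test_that("tversky uses exact integer arithmetic", {
  set.seed(14)
  grid <- expand.grid(alpha = c(0, 0.3, 1, 2.5, 10),
                      beta = c(0, 0.7, 1, 10))
  for (nb in c(21L, 128L)) {
    x <- random_fp(nb, density = 0.3)
    stopifnot(oracle_popcount(x) > 0)
    for (g in seq_len(nrow(grid))) {
      a <- grid$alpha[g]; b <- grid$beta[g]
      expect_identical(tversky(x, x, a, b), 1)  # exactly 1, never 0.999...
      y <- random_fp(nb, density = 0.3)
      expect_equal(tversky(x, y, a, b), oracle_tversky(x, y, a, b),
                   tolerance = 1e-12)
    }
    y <- random_fp(nb, density = 0.3)
    expect_identical(tversky(x, y, 1, 1), tanimoto(x, y))
  }
  # zero conventions mirror tanimoto
  expect_equal(tversky(raw(4), raw(4), 0.5, 0.5), 0)
  expect_equal(tversky(raw(4), hex_to_fp("ff000000"), 1, 1), 0)
  expect_equal(tversky(hex_to_fp("ff000000"), raw(4), 0, 1), 0)
  expect_error(tversky(raw(2), raw(2), -1, 1), "alpha")
  expect_error(tversky(raw(2), raw(2), 1, 11), "beta")
  expect_warning(tversky(raw(2), raw(2), 0.123456, 1), "rounded")
})

test_that("rational thresholds represent the double exactly", {
  for (t in c(0, 0.1, 0.4, 0.7, 0.75, 0.9, 1, runif(20))) {
    rt <- rational_threshold(t)
    expect_identical(rt$p / rt$q, as.numeric(t))  # p/q rounds back exactly
  }
  expect_equal(rational_threshold(0.75)$p, 3)
  expect_equal(rational_threshold(0.75)$q, 4)
  expect_equal(rational_threshold(0)$p, 0)
  expect_equal(rational_threshold(1)$p, 1)
  expect_error(rational_threshold(1.5), "\\[0, 1\\]")
  expect_error(rational_threshold(-0.1), "\\[0, 1\\]")
})

test_that("min_required_popcount is the exact ceiling over a threshold grid", {
  # The oracle must compare c/d to the threshold's exact rational value:
  # plain double division is wrong at representability boundaries (exact
  # 1/20 is below the double of 0.05, yet c/d = 1/20 rounds to that same
  # double), so the comparison is done in exact split-limb integers.
  grid_T <- c(seq(0.05, 1, by = 0.05), 0.33, 0.66)
  AB <- expand.grid(A = 0:64, B = 0:64)
  for (T in grid_T) {
    rt <- rational_threshold(T)
    bound <- min_required_popcount(rt, AB$A, AB$B)
    for (cc in c(0L, 1L, 7L, 32L, 64L)) {
      ok <- cc <= pmin(AB$A, AB$B) & (AB$A + AB$B) > 0
      d <- AB$A + AB$B - cc
      expect_identical((cc >= bound)[ok],
                       oracle_ge_threshold(cc, d, rt$p, rt$q)[ok],
                       label = paste("T =", T, "c =", cc))
    }
  }
  # for exactly-representable thresholds the double comparison agrees too
  for (T in c(0.25, 0.5, 0.75, 1)) {
    bound <- min_required_popcount(T, AB$A, AB$B)
    ok <- AB$A + AB$B > 0
    for (cc in c(0L, 3L, 16L)) {
      valid <- ok & cc <= pmin(AB$A, AB$B)
      d <- AB$A + AB$B - cc
      expect_identical((cc >= bound)[valid], (cc / d >= T)[valid])
    }
  }
  expect_equal(min_required_popcount(1, 10, 10), 10L)
  expect_equal(min_required_popcount(0.75, 8, 8), 7L)
  expect_error(min_required_popcount(0, 3, 3), "> 0")
})
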