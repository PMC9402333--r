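test_that("the upper envelope of a sine tracks its amplitude", {
  t <- (0:999) / 200
  x <- sin(2 * pi * 5 * t)                       # 5 periods, peaks on-grid
  ext <- find_extrema(x)
  env <- build_envelope(x, ext$maxima, "upper")
  interior <- 101:900
  expect_true(all(abs(env[interior] - 1) < 0.02))
  # envelope passes exactly through every interior extremum
  expect_equal(env[ext$maxima], x[ext$maxima])
})

test_that("two knots give the straight line through them", {
  x <- c(0, 2, 0, 1, 0)
  env <- build_envelope(x, c(2L, 4L), "upper",
                        sift_config(boundary_extrema = 0))
  expect_equal(env, c(2.5, 2, 1.5, 1, 0.5))
})

test_that("envelopes require extrema", {
  expect_error(build_envelope(rep(1, 10), integer(0), "upper"),
               class = "emdecg_insufficient_extrema")
  expect_error(sift_once(seq_len(20)), class = "emdecg_insufficient_extrema")
})

test_that("one sift subtracts the envelope mean", {
  t <- (0:999) / 200
  x <- sin(2 * pi * 5 * t)
  s <- sift_once(x)
  interior <- 101:900
  # symmetric oscillation: envelope mean near zero, iterate unchanged
  expect_true(max(abs(s$m[interior])) < 0.05)
  expect_true(max(abs(s$h_next[interior] - x[interior])) < 0.05)
  expect_equal(s$h_next, x - s$m)
  # constant offset ends up in the mean
  s2 <- sift_once(x + 3)
  expect_true(max(abs(s2$m[interior] - 3)) < 0.05)
})

test_that("the NSD statistic follows its per-sample definition", {
  expect_equal(nsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nsd(c(2, 2, 2), c(1, 1, 1)), 3)
  expect_error(nsd(c(1, 2), c(0, 0)), "identically zero")
  expect_error(nsd(c(1, 2), c(1, 2, 3)), "equal length")
  # samples under the relative floor are skipped, not divided by
  expect_equal(nsd(c(2, 2, 1), c(1, 1, 1e-14)), 2)
})

test_that("sifting a pure tone returns it nearly unchanged", {
  t <- (0:599) / 200
  x <- sin(2 * pi * 5 * t)
  r <- extract_imf(x)
  expect_lte(r$sift_count, sift_config()$max_sift_iters)
  expect_gt(cor(r$imf, x), 0.99)
  expect_true(is_imf(r$imf))
})

test_that("degenerate inputs stop the decomposition cleanly", {
  d <- emd(rep(1, 100), fs = 10)
  expect_length(d$imfs, 0)
  expect_equal(d$residue, rep(1, 100))
  expect_equal(d$stop_reason, "insufficient_extrema")
  d2 <- emd(seq_len(100), fs = 10)       # monotone ramp
  expect_length(d2$imfs, 0)
})

test_that("decomposition is complete, valid and deterministic", {
  set.seed(42)
  x <- rnorm(1500)
  d <- emd(x, fs = 250)
  expect_lt(max(abs(x - reconstruct(d))), 1e-8 * max(abs(x)))
  expect_true(all(vapply(d$imfs, is_imf, logical(1))))
  expect_equal(d$stop_reason, "monotonic_residue")
  # residue is (near-)monotonic
  fe <- find_extrema(d$residue)
  expect_lt(length(fe$maxima) + length(fe$minima), 2)
  expect_identical(emd(x, fs = 250), d)
})

test_that("IMF oscillation rate decreases with mode index", {
  for (seed in c(7, 8)) {
    set.seed(seed)
    d <- emd(rnorm(2000), fs = 250)
    zc <- vapply(d$imfs, emdecg:::count_zero_crossings, numeric(1))
    expect_true(all(diff(zc) <= 0), info = paste("seed", seed))
  }
})

test_that("decomposition is equivariant under amplitude scaling", {
  set.seed(9)
  x <- rnorm(1000)
  d1 <- emd(x, fs = 100)
  d3 <- emd(3 * x, fs = 100)
  expect_equal(length(d1$imfs), length(d3$imfs))
  for (k in seq_along(d1$imfs))
    expect_equal(d3$imfs[[k]], 3 * d1$imfs[[k]], tolerance = 1e-6)
  expect_equal(d3$residue, 3 * d1$residue, tolerance = 1e-6)
})

test_that("well-separated tones land in distinct modes", {
  t <- (0:4999) / 1000
  hi <- sin(2 * pi * 50 * t)
  lo <- sin(2 * pi * 2 * t)
  d <- emd(hi + lo, fs = 1000)
  expect_gte(length(d$imfs), 2)
  interior <- 501:4500
  expect_gt(cor(d$imfs[[1]][interior], hi[interior]), 0.95)
  later <- vapply(d$imfs[-1], function(f) cor(f[interior], lo[interior]), numeric(1))
  expect_gt(max(later), 0.95)
})

test_that("max_imfs caps the cascade", {
  set.seed(10)
  d <- emd(rnorm(2000), fs = 250, cfg = sift_config(max_imfs = 3))
  expect_length(d$imfs, 3)
  expect_equal(d$stop_reason, "max_imfs")
})
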