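test_that("cumulative means and powers follow their definitions", {
  d <- fake_emd(list(c(1, 1), c(3, 3)), residue = c(0.5, 0.5))
  expect_equal(cumulative_mean_profile(d), c(1, 4))
  expect_equal(imf_powers(d), c(2, 18))
  d2 <- fake_emd(list(c(1, -1, 1, -1)), residue = rep(0, 4))
  expect_equal(cumulative_mean_profile(d2), 0)
  expect_equal(imf_powers(d2), 4)
  # linearity: R_K + mean(residue) = mean(source)
  set.seed(3)
  d3 <- emd(rnorm(800), fs = 100)
  R <- cumulative_mean_profile(d3)
  expect_equal(R[length(R)] + mean(d3$residue), mean(d3$source),
               tolerance = 1e-10)
  d0 <- fake_emd(list(), residue = c(1, 2, 3))
  expect_error(cumulative_mean_profile(d0), "no IMFs")
  expect_error(imf_powers(d0), "no IMFs")
})

test_that("noise-IMF selection applies the prefix, cap and power rules", {
  cfg <- denoise_config()
  x <- rep(1, 100)                       # mean 1 -> tau = 0.5
  # |R_1| below tau, tiny power, |R_2| far above: only IMF 1 selected
  sel <- select_noise_imfs(R = c(0, 5), P = c(0.01, 50), x = x, cfg = cfg)
  expect_equal(sel$indices, 1L)
  expect_equal(sel$gains, c(0, 1))
  # every |R_k| above tau: nothing is touched
  sel2 <- select_noise_imfs(R = c(2, 3, 4), P = c(1, 1, 1), x = x, cfg = cfg)
  expect_equal(sel2$indices, integer(0))
  expect_equal(sel2$gains, c(1, 1, 1))
  # three sub-threshold means with tiny powers: capped at the first two
  sel3 <- select_noise_imfs(R = c(0, 0.1, 0.2), P = c(0.01, 0.01, 0.01),
                            x = x, cfg = cfg)
  expect_equal(sel3$indices, c(1L, 2L))
  # the power test blocks a large-amplitude candidate
  big <- 100 * (cfg$power_fraction * 1)^2 + 1   # above n*(pf*max|x|)^2
  sel4 <- select_noise_imfs(R = c(0, 0), P = c(big, 0.01), x = x, cfg = cfg)
  expect_equal(sel4$indices, 2L)
  # proportional mode attenuates by |R_k|/tau
  cfg_p <- denoise_config(attenuation_mode = "proportional")
  sel5 <- select_noise_imfs(R = c(0.25, 5), P = c(0.01, 50), x = x, cfg = cfg_p)
  expect_equal(sel5$gains[1], 0.25 / 0.5)
})

test_that("zero-mean records fall back to the RMS threshold", {
  x <- c(1, -1, 1, -1)                   # mean 0, rms 1
  cfg <- denoise_config()
  sel <- select_noise_imfs(R = c(0.004), P = c(0.001), x = x, cfg = cfg)
  expect_equal(sel$tau, cfg$mean_threshold_factor * 0.01)
  expect_equal(sel$indices, 1L)
})

test_that("the slope metric sums per-segment least-squares slopes", {
  expect_equal(slope_metric(rep(0, 500), fs = 100), 0)
  # a global ramp of slope a over S full segments scores S*|a|
  t <- (0:499) / 100
  expect_equal(slope_metric(2 * t, fs = 100, segment_seconds = 1), 5 * 2,
               tolerance = 1e-9)
  expect_error(slope_metric(1, fs = 100), "at least 2")
  # drift strictly raises the metric
  ecg <- reference_ecg()
  drift <- gen_noise("baseline", length(ecg), ecg$fs, seed = 7, baseline_hz = 0.25)
  expect_gt(slope_metric(ecg$samples + 0.5 * drift, ecg$fs),
            slope_metric(ecg$samples, ecg$fs))
})

test_that("baseline detachment strips drift but keeps the reference level", {
  # pure monotone trend: no IMFs, the residue carries everything
  x <- seq(0, 1, length.out = 500)
  den <- ecg_denoise(x, fs = 100)
  expect_true(0L %in% den$baseline_imf_indices)
  expect_lt(diff(range(fitted(den))), 1e-8)          # flat output
  expect_equal(fitted(den)[1], mean(x), tolerance = 1e-8)

  # drift-free record: at most the (near-constant) residue is detached
  ecg <- reference_ecg()
  d <- emd(ecg)
  bl <- remove_baseline(d, ecg$fs)
  expect_true(all(bl$baseline_indices %in%
                    c(0L, seq_along(d$imfs))))
  removed_imfs <- bl$baseline_indices[bl$baseline_indices > 0]
  if (length(removed_imfs)) {
    dur <- d$source_length / ecg$fs
    hz <- vapply(d$imfs[removed_imfs], emdecg:::count_zero_crossings,
                 numeric(1)) / (2 * dur)
    expect_true(all(hz < denoise_config()$baseline_max_hz))
  }
})

test_that("a strong slow sinusoid is removed from the low band", {
  ecg <- reference_ecg()
  drift <- gen_noise("baseline", length(ecg), ecg$fs, seed = 7, baseline_hz = 0.2)
  corrupted <- ecg$samples + 3 * sqrt(mean(ecg$samples^2)) * drift
  den <- ecg_denoise(corrupted, fs = ecg$fs)
  expect_lt(band_power(fitted(den), ecg$fs, hi = 0.5),
            band_power(corrupted, ecg$fs, hi = 0.5) / 10)
})

test_that("reconstruction is the gain-weighted sum of the modes", {
  set.seed(5)
  x <- rnorm(1200)
  d <- emd(x, fs = 200)
  K <- length(d$imfs)
  expect_lt(max(abs(reconstruct(d) - x)), 1e-8 * max(abs(x)))
  expect_equal(reconstruct(d, rep(0, K), include_residue = FALSE),
               numeric(length(x)))
  g <- c(0, rep(1, K - 1))
  expect_equal(reconstruct(d, g), x - d$imfs[[1]], tolerance = 1e-10)
  # additivity in the gains (residue counted once)
  g1 <- runif(K); g2 <- runif(K)
  expect_equal(reconstruct(d, g1) + reconstruct(d, g2, include_residue = FALSE),
               reconstruct(d, g1 + g2), tolerance = 1e-10)
  expect_error(reconstruct(d, rep(1, K + 1)), "length")
})

test_that("denoising preserves length, rate and the clean signal", {
  ecg <- reference_ecg()
  den <- ecg_denoise(ecg)
  expect_length(fitted(den), length(ecg$samples))
  expect_equal(den$denoised$fs, ecg$fs)
  expect_gt(cor(ecg$samples, fitted(den)), 0.99)
  expect_equal(residuals(den), ecg$samples - fitted(den))
  expect_length(coef(den), length(den$decomposition$imfs))
  expect_true(all(coef(den) >= 0 & coef(den) <= 1))
  # gains are 1 wherever nothing was selected or detached
  untouched <- setdiff(seq_along(den$gains),
                       c(den$noise_imf_indices,
                         den$baseline_imf_indices))
  expect_true(all(den$gains[untouched] == 1))
})

test_that("denoise is the identity when every stage is disabled", {
  ecg <- reference_ecg()
  cfg <- denoise_config(power_fraction = 1e-12, remove_baseline = FALSE)
  den <- ecg_denoise(ecg, den_cfg = cfg)
  expect_lt(max(abs(fitted(den) - ecg$samples)), 1e-8 * max(abs(ecg$samples)))
  expect_equal(den$noise_imf_indices, integer(0))
})

test_that("constant input passes through without crashing", {
  den <- ecg_denoise(rep(2, 100), fs = 10,
                     den_cfg = denoise_config(remove_baseline = FALSE))
  expect_equal(fitted(den), rep(2, 100))
})

test_that("removing noise IMFs lifts the SNR of a corrupted record", {
  ecg <- reference_ecg()
  mixed <- mix_at_snr(ecg, gen_noise("gaussian", length(ecg), ecg$fs, seed = 21), 5)
  den <- ecg_denoise(mixed$corrupted)
  expect_equal(den$noise_imf_indices, c(1L, 2L))
  expect_gt(snr_improvement(ecg$samples, mixed$corrupted$samples, fitted(den)), 0)
})
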