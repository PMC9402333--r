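#' Default ECG wave morphology table
#'
#' Per-wave parameters of the sum-of-Gaussians beat model: amplitude (mV),
#' centre offset as a fraction of the beat period, and width (s). The
#' defaults give a visually plausible normal beat with a dominant R peak.
#'
#' @return A data frame with columns `wave`, `amplitude`, `center`, `width`.
#' @export
ecg_wave_params <- function() {
  data.frame(
    wave      = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.10, 1.00, -0.15, 0.30),
    center    = c(0.10, 0.22, 0.25, 0.28, 0.45),
    width     = c(0.025, 0.010, 0.012, 0.010, 0.060),
    stringsAsFactors = FALSE
  )
}

#' Synthetic ECG generator
#'
#' Builds a quasi-periodic ECG as a sum of Gaussian bumps: each beat at
#' onset `t_b` contributes, for every wave `w`,
#' `amplitude_w * exp(-(t - t_b - center_w * T_b)^2 / (2 width_w^2))` where
#' `T_b` is that beat's period, `60/heart_rate_bpm` perturbed
#' multiplicatively by a uniform jitter in `±rr_jitter_frac`. Deterministic
#' for a fixed seed.
#'
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz (default 360, the MIT-BIH convention).
#' @param heart_rate_bpm Mean heart rate in beats per minute.
#' @param wave_params Morphology table as from [ecg_wave_params()]; widths
#'   must be positive, centre offsets in \[0, 1), and the R amplitude must
#'   exceed `|Q|` and `|S|`.
#' @param rr_jitter_frac Beat-to-beat period jitter as a fraction (0 = a
#'   perfectly periodic record).
#' @param seed Integer seed for the jitter draws; `NULL` uses the current
#'   RNG state.
#' @param name Label for the returned signal.
#' @return An [ecg_signal()].
#' @examples
#' ecg <- synth_ecg(duration_s = 10, heart_rate_bpm = 60, rr_jitter_frac = 0, seed = 1)
#' sum(ecg$samples > 0.5 & c(diff(ecg$samples) < 0, TRUE) & c(TRUE, diff(ecg$samples) > 0))
#' @export
synth_ecg <- function(duration_s, fs = 360, heart_rate_bpm = 72,
                      wave_params = ecg_wave_params(), rr_jitter_frac = 0.05,
                      seed = NULL, name = "synthetic ECG") {
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar(heart_rate_bpm, "heart_rate_bpm", lower = 0, strict_lower = TRUE)
  check_scalar(rr_jitter_frac, "rr_jitter_frac", lower = 0)
  wp <- wave_params
  req <- c("wave", "amplitude", "center", "width")
  if (!is.data.frame(wp) || !all(req %in% names(wp)))
    stop("'wave_params' must be a data frame with columns wave, amplitude, center, width")
  if (any(wp$width <= 0))
    stop("wave widths must be positive")
  if (any(wp$center < 0 | wp$center >= 1))
    stop("wave centre offsets must lie in [0, 1)")
  amp <- stats::setNames(wp$amplitude, wp$wave)
  if (all(c("Q", "R", "S") %in% wp$wave) &&
      !(amp[["R"]] > abs(amp[["Q"]]) && amp[["R"]] > abs(amp[["S"]])))
    stop("the R amplitude must exceed |Q| and |S|")

  t_mean <- 60 / heart_rate_bpm
  onsets <- numeric(0)
  periods <- numeric(0)
  with_seed(seed, {
    t_b <- 0
    while (t_b < duration_s) {
      jitter <- if (rr_jitter_frac > 0) stats::runif(1, -rr_jitter_frac, rr_jitter_frac) else 0
      p <- t_mean * (1 + jitter)
      onsets <- c(onsets, t_b)
      periods <- c(periods, p)
      t_b <- t_b + p
    }
  })
  n <- as.integer(round(duration_s * fs))
  t <- (0:(n - 1L)) / fs
  x <- numeric(n)
  for (b in seq_along(onsets)) {
    for (w in seq_len(nrow(wp))) {
      centre <- onsets[b] + wp$center[w] * periods[b]
      x <- x + wp$amplitude[w] * exp(-(t - centre)^2 / (2 * wp$width[w]^2))
    }
  }
  ecg_signal(x, fs = fs, name = name)
}

#' Generate one of the standard ECG noise models
#'
#' Returns an *unscaled* noise sequence (scaling to a target SNR is done by
#' [mix_at_snr()]):
#' \describe{
#'   \item{gaussian}{iid standard normal draws (white Gaussian noise).}
#'   \item{emg}{broadband muscle-artifact surrogate: white noise
#'     band-limited to `emg_band_hz` by spectral masking (the FFT bins
#'     outside the band are zeroed, preserving determinism and exact band
#'     confinement).}
#'   \item{powerline}{`sin(2 pi powerline_hz t + phase)` with a seeded
#'     uniform phase — mains interference at 50 or 60 Hz.}
#'   \item{baseline}{a slow sinusoid at `baseline_hz` with seeded phase —
#'     respiration-driven baseline drift.}
#' }
#'
#' @param kind One of `"gaussian"`, `"emg"`, `"powerline"`, `"baseline"`.
#' @param n Number of samples (at least 2).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param powerline_hz Mains frequency (must be below Nyquist).
#' @param emg_band_hz Length-2 passband in Hz; both edges below Nyquist.
#' @param baseline_hz Drift frequency in Hz.
#' @return Numeric vector of length `n`.
#' @export
gen_noise <- function(kind = c("gaussian", "emg", "powerline", "baseline"),
                      n, fs, seed = NULL, powerline_hz = 50,
                      emg_band_hz = c(20, min(500, 0.45 * fs)),
                      baseline_hz = 0.25) {
  kind <- match.arg(kind)
  check_scalar(n, "n", lower = 2)
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  n <- as.integer(n)
  t <- (0:(n - 1L)) / fs
  switch(kind,
    gaussian = with_seed(seed, stats::rnorm(n)),
    emg = {
      lo <- emg_band_hz[1]; hi <- emg_band_hz[2]
      if (!(lo > 0 && lo < hi && hi < fs / 2))
        stop("'emg_band_hz' must satisfy 0 < low < high < fs/2")
      w <- with_seed(seed, stats::rnorm(n))
      spec <- stats::fft(w)
      freq <- pmin(0:(n - 1L), n - (0:(n - 1L))) * fs / n
      spec[freq < lo | freq > hi] <- 0 + 0i
      Re(stats::fft(spec, inverse = TRUE)) / n
    },
    powerline = {
      if (!(powerline_hz > 0 && powerline_hz < fs / 2))
        stop("'powerline_hz' must lie in (0, fs/2)")
      phase <- with_seed(seed, stats::runif(1, 0, 2 * pi))
      sin(2 * pi * powerline_hz * t + phase)
    },
    baseline = {
      if (!(baseline_hz > 0 && baseline_hz < fs / 2))
        stop("'baseline_hz' must lie in (0, fs/2)")
      phase <- with_seed(seed, stats::runif(1, 0, 2 * pi))
      sin(2 * pi * baseline_hz * t + phase)
    }
  )
}

#' Mix noise into a clean signal at an exact SNR
#'
#' Scales the noise so that the energy ratio of clean signal to scaled
#' noise equals the target SNR, then adds it:
#' `alpha = sqrt(sum(clean^2) / (sum(noise^2) * 10^(snr/10)))`.
#'
#' @param clean An [ecg_signal()] or numeric vector.
#' @param noise Numeric vector, same length, nonzero energy.
#' @param target_snr_db Target input SNR in dB.
#' @param fs Sampling rate when `clean` is a bare vector.
#' @return A list with `corrupted` (same type as `clean`), `scaled_noise`
#'   and the scale factor `alpha`.
#' @export
mix_at_snr <- function(clean, noise, target_snr_db, fs = NULL) {
  sig <- if (inherits(clean, "ecg_signal")) clean else as_ecg_signal(clean, fs = fs)
  x <- sig$samples
  if (length(x) != length(noise))
    stop("'clean' and 'noise' must have equal length")
  ec <- sum(x^2)
  en <- sum(noise^2)
  if (ec == 0 || en == 0)
    stop("both the clean signal and the noise need nonzero energy")
  check_scalar(target_snr_db, "target_snr_db")
  alpha <- sqrt(ec / (en * 10^(target_snr_db / 10)))
  scaled <- alpha * noise
  corrupted <- ecg_signal(x + scaled, sig$fs,
                          name = sprintf("%s + noise @ %g dB", sig$name, target_snr_db))
  list(corrupted = corrupted, scaled_noise = scaled, alpha = alpha)
}
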