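#' Denoising configuration
#'
#' Parameters of the adaptive IMF selection and baseline-wander removal.
#' High-frequency noise lives in the first one or two IMFs and is
#' near-zero-mean, so the cumulative mean of the partial reconstructions
#' stays below a threshold while only noise modes have been accumulated;
#' candidate noise IMFs must additionally show markedly low power before
#' they are modified.
#'
#' @param mean_threshold_factor Scales the cumulative-mean threshold:
#'   `tau = mean_threshold_factor * |mean(x)|`, with an RMS-based fallback
#'   for zero-mean records.
#' @param power_fraction Power-confirmation cut in (0, 1]: a candidate IMF
#'   is confirmed as noise only if its RMS amplitude is below
#'   `power_fraction` times the record's peak magnitude, i.e.
#'   `P_k < n * (power_fraction * max|x|)^2` — noise modes oscillate with
#'   small amplitude relative to the ECG deflections.
#' @param max_noise_imfs Cap on how many leading IMFs may be treated as
#'   noise (default 2: the first and second mode).
#' @param attenuation_mode `"remove"` zeroes confirmed noise IMFs;
#'   `"proportional"` scales them by `min(1, |R_k|/tau)`.
#' @param baseline_segment_seconds Segment length of the piecewise slope
#'   metric used for baseline-wander removal (about one beat).
#' @param baseline_max_hz Frequency floor for baseline removal: only IMFs
#'   whose zero-crossing rate corresponds to less than this frequency are
#'   candidates for detachment. The default 0.5 Hz is the conventional
#'   upper edge of respiration-driven baseline wander, safely below any
#'   plausible heart rate, so beat-bearing modes are never stripped.
#' @param remove_baseline Whether to run the baseline-wander removal stage.
#' @return A list of class `"denoise_config"`.
#' @export
denoise_config <- function(mean_threshold_factor = 0.5, power_fraction = 0.15,
                           max_noise_imfs = 2L,
                           attenuation_mode = c("remove", "proportional"),
                           baseline_segment_seconds = 1.0,
                           baseline_max_hz = 0.5,
                           remove_baseline = TRUE) {
  attenuation_mode <- match.arg(attenuation_mode)
  check_scalar(mean_threshold_factor, "mean_threshold_factor", lower = 0, strict_lower = TRUE)
  check_scalar(power_fraction, "power_fraction", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(max_noise_imfs, "max_noise_imfs", lower = 1)
  check_scalar(baseline_segment_seconds, "baseline_segment_seconds", lower = 0, strict_lower = TRUE)
  check_scalar(baseline_max_hz, "baseline_max_hz", lower = 0, strict_lower = TRUE)
  structure(list(mean_threshold_factor = mean_threshold_factor,
                 power_fraction = power_fraction,
                 max_noise_imfs = as.integer(max_noise_imfs),
                 attenuation_mode = attenuation_mode,
                 baseline_segment_seconds = baseline_segment_seconds,
                 baseline_max_hz = baseline_max_hz,
                 remove_baseline = isTRUE(remove_baseline)),
            class = "denoise_config")
}

#' Cumulative mean of partial IMF reconstructions
#'
#' `R_k` is the time average of the pointwise sum of IMFs `1..k`. Because
#' the mean is linear this equals the cumulative sum of the per-IMF means.
#' Noise modes are near zero-mean, so `|R_k|` stays small until a
#' signal-bearing mode enters the partial sum.
#'
#' @param d An [emd()] decomposition with at least one IMF.
#' @return Numeric vector `R_1..R_K` (signed).
#' @export
cumulative_mean_profile <- function(d) {
  stopifnot(inherits(d, "emd"))
  if (length(d$imfs) == 0L)
    stop("the decomposition has no IMFs")
  cumsum(vapply(d$imfs, mean, numeric(1)))
}

#' Per-IMF signal power
#'
#' Sum of squares of each IMF, used as the confirmation statistic for noise
#' modes (small amplitude, high frequency implies low power).
#'
#' @param d An [emd()] decomposition with at least one IMF.
#' @return Non-negative numeric vector `P_1..P_K`.
#' @export
imf_powers <- function(d) {
  stopifnot(inherits(d, "emd"))
  if (length(d$imfs) == 0L)
    stop("the decomposition has no IMFs")
  vapply(d$imfs, function(f) sum(f^2), numeric(1))
}

#' Select noise IMFs from the cumulative-mean profile
#'
#' Candidates are the maximal initial run of IMFs whose cumulative mean
#' magnitude `|R_k|` stays below the threshold
#' `tau = mean_threshold_factor * |mean(x)|` (RMS fallback when the record
#' is zero-mean), capped at `max_noise_imfs`. A candidate is confirmed as
#' noise only if it passes the power test: its power must stay below
#' `n * (power_fraction * max|x|)^2`, i.e. its RMS amplitude must be a
#' small fraction of the record's peak deflection (high-frequency noise
#' rides on the ECG with small amplitude, hence minimal power). Confirmed
#' IMFs get gain 0 (`"remove"`) or `min(1, |R_k|/tau)` (`"proportional"`),
#' all others gain 1.
#'
#' @param R Cumulative-mean profile from [cumulative_mean_profile()].
#' @param P IMF powers from [imf_powers()].
#' @param x Numeric vector: the record being denoised (sets the threshold
#'   scale).
#' @param cfg A [denoise_config()].
#' @return A list with `indices` (1-based confirmed noise IMFs), `gains`
#'   (length = number of IMFs, each in \[0, 1\]) and the threshold `tau`.
#' @export
select_noise_imfs <- function(R, P, x, cfg = denoise_config()) {
  if (length(R) != length(P) || length(R) < 1L)
    stop("'R' and 'P' must have equal length >= 1")
  mu <- mean(x)
  r <- rms(x)
  tau <- if (abs(mu) < 1e-6 * r) {
    cfg$mean_threshold_factor * 0.01 * r
  } else {
    cfg$mean_threshold_factor * abs(mu)
  }
  run <- 0L
  while (run < length(R) && abs(R[run + 1L]) < tau) run <- run + 1L
  candidates <- seq_len(min(run, cfg$max_noise_imfs))
  power_cut <- length(x) * (cfg$power_fraction * max(abs(x)))^2
  confirmed <- candidates[P[candidates] < power_cut]
  gains <- rep(1, length(R))
  if (length(confirmed)) {
    gains[confirmed] <- if (cfg$attenuation_mode == "remove") {
      0
    } else {
      pmin(1, abs(R[confirmed]) / tau)
    }
  }
  list(indices = as.integer(confirmed), gains = gains, tau = tau)
}

#' Piecewise slope metric
#'
#' Splits the record into consecutive non-overlapping segments of
#' `segment_seconds` and sums the absolute least-squares slope of each
#' segment (amplitude per second). The sum approximates the amount of
#' baseline drift: detrending a drifting record lowers it, while removing
#' genuine oscillatory content barely changes it.
#'
#' @param samples Numeric vector with at least 2 samples.
#' @param fs Sampling rate in Hz.
#' @param segment_seconds Segment length in seconds; a trailing partial
#'   segment is kept if it has at least 2 samples.
#' @return Non-negative scalar.
#' @export
slope_metric <- function(samples, fs, segment_seconds = 1.0) {
  n <- length(samples)
  if (n < 2L)
    stop("'samples' must have at least 2 samples")
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  seg_len <- max(2L, as.integer(round(segment_seconds * fs)))
  starts <- seq.int(1L, n, by = seg_len)
  total <- 0
  for (s in starts) {
    e <- min(s + seg_len - 1L, n)
    len <- e - s + 1L
    if (len < 2L) next
    t <- (0:(len - 1L)) / fs
    y <- samples[s:e]
    tc <- t - mean(t)
    total <- total + abs(sum(tc * (y - mean(y))) / sum(tc^2))
  }
  total
}

#' Baseline-wander removal by high-order IMF detachment
#'
#' Detaches the residue and then the highest-order IMFs one by one from the
#' reconstruction, recomputing the piecewise slope metric after each
#' removal, and stops at the first removal that increases the metric (that
#' removal is undone). Only sub-baseline-band modes are candidates: an IMF
#' whose zero-crossing rate corresponds to `cfg$baseline_max_hz` (0.5 Hz by
#' default) or more is never touched, so beat-bearing modes survive however
#' many IMFs the decomposition produced.
#'
#' Baseline correction removes *wander*, not the record's reference level:
#' the time-average of everything detached is reported as `level`, and
#' [ecg_denoise()] adds it back so the corrected ECG keeps its DC
#' reference. (The slope metric is blind to constants, so this does not
#' affect the stopping rule.)
#'
#' @param d An [emd()] decomposition.
#' @param fs Sampling rate in Hz (defaults to the decomposition's).
#' @param cfg A [denoise_config()].
#' @param gains Optional per-IMF gains already applied by noise-IMF
#'   selection (default all 1).
#' @return A list with `baseline_indices` (1-based removed IMFs, with 0
#'   marking the residue), the metric `trajectory` (initial value, then one
#'   entry per accepted removal) and `level`, the time-average of the
#'   detached components.
#' @export
remove_baseline <- function(d, fs = d$fs, cfg = denoise_config(),
                            gains = rep(1, length(d$imfs))) {
  stopifnot(inherits(d, "emd"))
  K <- length(d$imfs)
  if (length(gains) != K)
    stop("'gains' length must match the number of IMFs")
  # Oscillation rate per IMF: zero crossings / (2 * record duration).
  duration <- d$source_length / fs
  imf_hz <- vapply(d$imfs, count_zero_crossings, numeric(1)) / (2 * duration)
  detachable <- which(imf_hz < cfg$baseline_max_hz)
  current <- reconstruct(d, gains, include_residue = TRUE)
  metric <- slope_metric(current, fs, cfg$baseline_segment_seconds)
  trajectory <- metric
  removed <- integer(0)
  level <- 0
  # Candidate removals: residue first (marker 0), then IMF K, K-1, ...
  # down to the slowest mode still below the baseline band edge.
  for (j in c(0L, rev(detachable))) {
    component <- if (j == 0L) d$residue else gains[j] * d$imfs[[j]]
    candidate <- current - component
    m_new <- slope_metric(candidate, fs, cfg$baseline_segment_seconds)
    # Stop at the first removal that increases the metric. Negligible
    # components perturb it at rounding level, so "increase" carries a 1%
    # relative tolerance; a genuine beat-bearing removal raises it by far
    # more than that.
    if (m_new > metric * 1.01) break
    current <- candidate
    metric <- m_new
    trajectory <- c(trajectory, m_new)
    removed <- c(removed, j)
    level <- level + mean(component)
  }
  list(baseline_indices = removed, trajectory = trajectory, level = level)
}

#' Selective reconstruction from IMFs
#'
#' Pointwise weighted sum of the IMFs (plus the residue if requested). With
#' all gains 1 and the residue included this reproduces the source signal to
#' floating-point accuracy.
#'
#' @param d An [emd()] decomposition.
#' @param gains Numeric vector, one gain per IMF.
#' @param include_residue Add the residue to the sum?
#' @return Numeric vector of length `d$source_length`.
#' @export
reconstruct <- function(d, gains = rep(1, length(d$imfs)), include_residue = TRUE) {
  stopifnot(inherits(d, "emd"))
  if (length(gains) != length(d$imfs))
    stop("'gains' length must match the number of IMFs")
  out <- if (include_residue) d$residue else numeric(d$source_length)
  for (i in seq_along(d$imfs))
    if (gains[i] != 0) out <- out + gains[i] * d$imfs[[i]]
  out
}

#' Adaptive EMD-based ECG denoising
#'
#' The full pipeline: decompose the record into IMFs, compute the
#' cumulative-mean profile and per-IMF powers, select and attenuate
#' low-order noise IMFs ([select_noise_imfs()]), optionally strip baseline
#' wander by high-order IMF detachment ([remove_baseline()]), and
#' reconstruct. Deterministic given the input and configurations.
#'
#' @param x An [ecg_signal()] or numeric vector.
#' @param fs Sampling rate in Hz, required when `x` is a bare vector.
#' @param sift_cfg A [sift_config()].
#' @param den_cfg A [denoise_config()].
#' @return An object of class `"ecg_denoise"` with the denoised signal and
#'   full provenance: `denoised` (an `ecg_signal`), `gains`,
#'   `noise_imf_indices`, `baseline_imf_indices` (0 marks the residue),
#'   `cumulative_means`, `imf_powers`, `slope_trajectory`, `decomposition`
#'   and the `input` signal. Use [fitted()] for the denoised samples and
#'   [residuals()] for the removed-noise estimate.
#' @examples
#' ecg <- synth_ecg(duration_s = 10, seed = 1)
#' noisy <- mix_at_snr(ecg, gen_noise("gaussian", length(ecg), ecg$fs, seed = 2), 10)
#' den <- ecg_denoise(noisy$corrupted)
#' den
#' snr_improvement(ecg$samples, noisy$corrupted$samples, fitted(den))
#' @export
ecg_denoise <- function(x, fs = NULL, sift_cfg = sift_config(),
                        den_cfg = denoise_config()) {
  sig <- as_ecg_signal(x, fs = fs)
  d <- emd(sig, cfg = sift_cfg)
  K <- length(d$imfs)
  if (K >= 1L) {
    R <- cumulative_mean_profile(d)
    P <- imf_powers(d)
    sel <- select_noise_imfs(R, P, sig$samples, den_cfg)
    gains <- sel$gains
    noise_idx <- sel$indices
  } else {
    R <- numeric(0)
    P <- numeric(0)
    gains <- numeric(0)
    noise_idx <- integer(0)
  }
  baseline_idx <- integer(0)
  trajectory <- numeric(0)
  include_residue <- TRUE
  level <- 0
  if (den_cfg$remove_baseline) {
    bl <- remove_baseline(d, sig$fs, den_cfg, gains)
    baseline_idx <- bl$baseline_indices
    trajectory <- bl$trajectory
    level <- bl$level
    if (0L %in% baseline_idx) include_residue <- FALSE
    gains[baseline_idx[baseline_idx > 0L]] <- 0
  }
  # Re-reference: baseline correction removes wander, not the DC level.
  denoised <- reconstruct(d, gains, include_residue) + level
  structure(
    list(denoised = ecg_signal(denoised, sig$fs,
                               name = paste0(sig$name, " (denoised)")),
         gains = gains,
         noise_imf_indices = noise_idx,
         baseline_imf_indices = baseline_idx,
         cumulative_means = R,
         imf_powers = P,
         slope_trajectory = trajectory,
         decomposition = d,
         input = sig,
         sift_cfg = sift_cfg,
         den_cfg = den_cfg),
    class = "ecg_denoise"
  )
}

#' @export
print.ecg_denoise <- function(x, ...) {
  K <- length(x$decomposition$imfs)
  cat(sprintf("Adaptive EMD denoising of '%s' (%d samples @ %g Hz)\n",
              x$input$name, length(x$input$samples), x$input$fs))
  cat(sprintf("  %d IMFs; noise IMFs removed/attenuated: %s\n", K,
              if (length(x$noise_imf_indices)) paste(x$noise_imf_indices, collapse = ", ") else "none"))
  bl <- x$baseline_imf_indices
  bl_txt <- if (length(bl)) {
    paste(ifelse(bl == 0L, "residue", paste0("IMF ", bl)), collapse = ", ")
  } else "none"
  cat(sprintf("  baseline components detached: %s\n", bl_txt))
  invisible(x)
}

#' @export
summary.ecg_denoise <- function(object, ...) {
  d <- object$decomposition
  out <- list(
    name = object$input$name,
    n = length(object$input$samples),
    fs = object$input$fs,
    n_imfs = length(d$imfs),
    stop_reason = d$stop_reason,
    table = if (length(d$imfs)) data.frame(
      imf = seq_along(d$imfs),
      cumulative_mean = object$cumulative_means,
      power = object$imf_powers,
      gain = object$gains,
      zero_crossings = vapply(d$imfs, count_zero_crossings, numeric(1))
    ) else NULL,
    noise_imf_indices = object$noise_imf_indices,
    baseline_imf_indices = object$baseline_imf_indices,
    slope_trajectory = object$slope_trajectory
  )
  class(out) <- "summary.ecg_denoise"
  out
}

#' @export
print.summary.ecg_denoise <- function(x, ...) {
  cat(sprintf("Adaptive EMD denoising of '%s': %d samples @ %g Hz\n",
              x$name, x$n, x$fs))
  cat(sprintf("Decomposition: %d IMFs (stop: %s)\n", x$n_imfs, x$stop_reason))
  if (!is.null(x$table)) {
    print(x$table, row.names = FALSE, digits = 4)
  }
  if (length(x$slope_trajectory))
    cat("Slope-metric trajectory:", paste(signif(x$slope_trajectory, 4), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
fitted.ecg_denoise <- function(object, ...) object$denoised$samples

#' @export
residuals.ecg_denoise <- function(object, ...) {
  object$input$samples - object$denoised$samples
}

#' @export
coef.ecg_denoise <- function(object, ...) {
  g <- object$gains
  if (length(g)) names(g) <- paste0("imf", seq_along(g))
  g
}

#' @export
plot.ecg_denoise <- function(x, ...) {
  old <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  t <- (seq_along(x$input$samples) - 1) / x$input$fs
  graphics::plot(t, x$input$samples, type = "l", xlab = "", ylab = "mV",
                 main = "input")
  graphics::plot(t, x$denoised$samples, type = "l", xlab = "", ylab = "mV",
                 main = "denoised")
  graphics::plot(t, residuals(x), type = "l", xlab = "time [s]", ylab = "mV",
                 main = "removed components")
  invisible(x)
}
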