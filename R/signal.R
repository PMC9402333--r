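#' Single-channel ECG signal
#'
#' Lightweight container for a uniformly sampled, finite, real-valued signal.
#' Everything in the package — decomposition, denoising, the synthetic
#' generator, the evaluation grid — operates on these objects.
#'
#' @param samples Numeric vector of amplitudes (mV by convention), length
#'   at least 3, all finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param name Free-text label carried through for reporting.
#'
#' @return An object of class `"ecg_signal"`: a list with elements
#'   `samples`, `fs` and `name`.
#' @examples
#' s <- ecg_signal(sin(2 * pi * 5 * (0:999) / 250), fs = 250, name = "tone")
#' s
#' @export
ecg_signal <- function(samples, fs, name = "signal") {
  samples <- as.numeric(samples)
  if (length(samples) < 3L)
    stop("a signal needs at least 3 samples")
  if (!all(is.finite(samples)))
    stop("all samples must be finite")
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  structure(
    list(samples = samples, fs = as.numeric(fs), name = as.character(name)[1L]),
    class = "ecg_signal"
  )
}

#' Coerce to an ECG signal
#'
#' Numeric vectors need an explicit sampling rate; `ecg_signal` objects pass
#' through unchanged.
#'
#' @param x Numeric vector or `ecg_signal`.
#' @param fs Sampling rate in Hz; required when `x` is a bare vector.
#' @param name Label used when constructing from a vector.
#' @return An `ecg_signal`.
#' @export
as_ecg_signal <- function(x, fs = NULL, name = "signal") {
  if (inherits(x, "ecg_signal")) return(x)
  if (is.null(fs))
    stop("'fs' is required when the input is a plain numeric vector")
  ecg_signal(x, fs = fs, name = name)
}

#' @export
print.ecg_signal <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("ECG signal '%s': %d samples @ %g Hz (%.3f s)\n",
              x$name, n, x$fs, n / x$fs))
  cat(sprintf("  amplitude range [%.4g, %.4g], mean %.4g\n",
              min(x$samples), max(x$samples), mean(x$samples)))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' @export
plot.ecg_signal <- function(x, ...) {
  t <- (seq_along(x$samples) - 1) / x$fs
  graphics::plot(t, x$samples, type = "l", xlab = "time [s]",
                 ylab = "amplitude [mV]", main = x$name, ...)
  invisible(x)
}
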