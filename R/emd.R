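#' Sifting configuration
#'
#' Parameters controlling the empirical mode decomposition. The
#' normalised-standard-difference (NSD) threshold is the conventional 0.2;
#' sifting for one mode stops as soon as the NSD between consecutive
#' iterates falls below it *and* the iterate satisfies the IMF criterion, or
#' when `max_sift_iters` is reached.
#'
#' @param nsd_threshold Positive sifting-convergence threshold
#'   (dimensionless).
#' @param max_sift_iters Maximum sift iterations per IMF.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param boundary_extrema How many maxima/minima to mirror about each end
#'   of the record before spline fitting, to suppress envelope end swings.
#' @param zero_floor Relative denominator guard for the NSD statistic:
#'   samples with `|f(t)| < zero_floor * RMS(f)` are skipped.
#' @return A list of class `"sift_config"`.
#' @export
sift_config <- function(nsd_threshold = 0.2, max_sift_iters = 50L,
                        max_imfs = 12L, boundary_extrema = 2L,
                        zero_floor = 1e-10) {
  check_scalar(nsd_threshold, "nsd_threshold", lower = 0, strict_lower = TRUE)
  check_scalar(max_sift_iters, "max_sift_iters", lower = 1)
  check_scalar(max_imfs, "max_imfs", lower = 1)
  check_scalar(boundary_extrema, "boundary_extrema", lower = 0)
  check_scalar(zero_floor, "zero_floor", lower = 0)
  structure(list(nsd_threshold = nsd_threshold,
                 max_sift_iters = as.integer(max_sift_iters),
                 max_imfs = as.integer(max_imfs),
                 boundary_extrema = as.integer(boundary_extrema),
                 zero_floor = zero_floor),
            class = "sift_config")
}

#' Cubic-spline envelope through local extrema
#'
#' Interpolates a natural cubic spline through the given extrema, after
#' mirroring up to `cfg$boundary_extrema` of them about each endpoint to tame
#' the spline near the record edges. The envelope passes exactly through
#' every (interior and mirrored) knot.
#'
#' @param samples Numeric vector.
#' @param extrema_indices 1-based indices of the local maxima (upper side)
#'   or minima (lower side) of `samples`.
#' @param side `"upper"` or `"lower"`; informational (the spline is defined
#'   by the knots either way).
#' @param cfg A [sift_config()].
#' @return Numeric vector of the envelope, same length as `samples`.
#' @export
build_envelope <- function(samples, extrema_indices,
                           side = c("upper", "lower"), cfg = sift_config()) {
  side <- match.arg(side)
  n <- length(samples)
  idx <- as.integer(extrema_indices)
  if (length(idx) == 0L)
    stop_insufficient_extrema(sprintf("no extrema for the %s envelope", side))
  b <- cfg$boundary_extrema
  knots_t <- idx
  knots_v <- samples[idx]
  if (b > 0L) {
    nl <- min(b, length(idx))
    left_t <- 2L - idx[seq_len(nl)]           # mirror about t = 1
    left_v <- samples[idx[seq_len(nl)]]
    tail_idx <- idx[seq.int(length(idx), by = -1L, length.out = nl)]
    right_t <- 2L * n - tail_idx              # mirror about t = n
    right_v <- samples[tail_idx]
    knots_t <- c(left_t, knots_t, right_t)
    knots_v <- c(left_v, knots_v, right_v)
  }
  o <- order(knots_t)
  knots_t <- knots_t[o]
  knots_v <- knots_v[o]
  keep <- !duplicated(knots_t)
  knots_t <- knots_t[keep]
  knots_v <- knots_v[keep]
  if (length(knots_t) < 2L)
    stop_insufficient_extrema(sprintf("fewer than 2 usable knots for the %s envelope", side))
  f <- stats::splinefun(knots_t, knots_v, method = "natural")
  f(seq_len(n))
}

#' One sifting step
#'
#' Computes the mean of the upper and lower cubic-spline envelopes and
#' subtracts it from the candidate mode.
#'
#' @param h Numeric vector (current candidate mode).
#' @param cfg A [sift_config()].
#' @return A list with `h_next = h - m` and the envelope mean `m`.
#' @export
sift_once <- function(h, cfg = sift_config()) {
  ext <- find_extrema(h)
  upper <- build_envelope(h, ext$maxima, "upper", cfg)
  lower <- build_envelope(h, ext$minima, "lower", cfg)
  m <- (upper + lower) / 2
  list(h_next = h - m, m = m)
}

#' Normalised standard difference between sift iterates
#'
#' The sifting convergence statistic: the sum over time of the squared
#' change between consecutive iterates, normalised per sample by the squared
#' current iterate. Samples whose magnitude falls below
#' `zero_floor * RMS(f_cur)` are skipped, since the ratio is undefined at
#' zeros.
#'
#' @param f_prev,f_cur Equal-length numeric vectors: the previous and
#'   current sift iterates.
#' @param zero_floor Relative denominator guard.
#' @return Non-negative scalar.
#' @examples
#' nsd(c(2, 2, 2), c(1, 1, 1)) # 3
#' @export
nsd <- function(f_prev, f_cur, zero_floor = 1e-10) {
  if (length(f_prev) != length(f_cur))
    stop("'f_prev' and 'f_cur' must have equal length")
  if (length(f_cur) < 1L)
    stop("empty input")
  r <- rms(f_cur)
  if (r == 0)
    stop("'f_cur' is identically zero: no valid NSD denominators")
  valid <- abs(f_cur) >= zero_floor * r
  if (!any(valid))
    stop("no valid NSD denominators above the zero floor")
  sum((f_prev[valid] - f_cur[valid])^2 / f_cur[valid]^2)
}

#' Extract one intrinsic mode function by repeated sifting
#'
#' Sifts the given residual until the NSD between consecutive iterates drops
#' below `cfg$nsd_threshold` and the iterate passes the IMF criterion, or
#' until `cfg$max_sift_iters` is reached. Because an accepted mode must
#' actually be an IMF, hitting the cap with an iterate that fails the
#' extrema/zero-crossing test falls back to the most recent iterate that
#' passed it (over-sifting can momentarily break the criterion after it was
#' first met).
#'
#' @param residual Numeric vector to sift.
#' @param cfg A [sift_config()].
#' @return A list with `imf` and `sift_count`.
#' @export
extract_imf <- function(residual, cfg = sift_config()) {
  h <- residual
  count <- 0L
  last_valid <- NULL
  last_valid_count <- 0L
  for (i in seq_len(cfg$max_sift_iters)) {
    s <- sift_once(h, cfg)
    count <- i
    h_new <- s$h_next
    # If the envelope mean annihilates the candidate, the residual is
    # trend-like (it IS its own envelope mean): nothing oscillatory is left
    # to extract, so hand the residual back as the final residue.
    if (all(abs(h_new) < 1e-12 * max(abs(residual)))) {
      if (i == 1L)
        stop_insufficient_extrema("envelope mean annihilates the candidate")
      count <- i - 1L
      break
    }
    v <- nsd(h, h_new, cfg$zero_floor)
    h <- h_new
    valid <- is_imf(h)
    if (valid) {
      last_valid <- h
      last_valid_count <- i
    }
    if (v < cfg$nsd_threshold && valid) break
  }
  if (!is.null(last_valid) && !is_imf(h)) {
    h <- last_valid
    count <- last_valid_count
  }
  list(imf = h, sift_count = count)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) and a residue by
#' iterative sifting: each mode is obtained by repeatedly subtracting the
#' mean of the cubic-spline envelopes of the extrema, then subtracted from
#' the running residual before the next mode is extracted. IMF 1 is the
#' highest-frequency mode. The cascade stops when the residual is
#' (near-)monotonic — fewer than 2 interior extrema — when `cfg$max_imfs`
#' modes have been extracted, or when envelopes can no longer be built.
#'
#' By construction the IMFs and the residue sum back to the input to
#' floating-point accuracy.
#'
#' @param x An [ecg_signal()] or numeric vector.
#' @param fs Sampling rate in Hz, required when `x` is a bare vector.
#' @param cfg A [sift_config()].
#' @return An object of class `"emd"`: a list with `imfs` (list of numeric
#'   vectors, highest frequency first), `residue`, `source`, `fs`, `name`,
#'   `source_length`, `stop_reason` (one of `"monotonic_residue"`,
#'   `"max_imfs"`, `"insufficient_extrema"`) and per-IMF `sift_counts`.
#' @examples
#' t <- (0:4999) / 1000
#' d <- emd(sin(2 * pi * 50 * t) + sin(2 * pi * 2 * t), fs = 1000)
#' d
#' @export
emd <- function(x, fs = NULL, cfg = sift_config()) {
  sig <- as_ecg_signal(x, fs = fs)
  residual <- sig$samples
  n <- length(residual)
  imfs <- list()
  sift_counts <- integer(0)
  stop_reason <- NA_character_
  src_scale <- max(abs(residual))
  repeat {
    # a residual at rounding level carries no further modes
    if (max(abs(residual)) < 1e-12 * src_scale) {
      stop_reason <- "monotonic_residue"
      break
    }
    ext <- find_extrema(residual)
    if (length(ext$maxima) + length(ext$minima) < 2L) {
      stop_reason <- if (length(imfs) == 0L) "insufficient_extrema" else "monotonic_residue"
      break
    }
    if (length(imfs) >= cfg$max_imfs) {
      stop_reason <- "max_imfs"
      break
    }
    r <- tryCatch(extract_imf(residual, cfg), error = function(e) {
      if (is_insufficient_extrema(e)) NULL else stop(e)
    })
    if (is.null(r)) {
      stop_reason <- "insufficient_extrema"
      break
    }
    imfs[[length(imfs) + 1L]] <- r$imf
    sift_counts <- c(sift_counts, r$sift_count)
    residual <- residual - r$imf
  }
  structure(
    list(imfs = imfs, residue = residual, source = sig$samples,
         fs = sig$fs, name = sig$name, source_length = n,
         stop_reason = stop_reason, sift_counts = sift_counts),
    class = "emd"
  )
}

#' @export
print.emd <- function(x, ...) {
  cat(sprintf("Empirical mode decomposition of '%s' (%d samples @ %g Hz)\n",
              x$name, x$source_length, x$fs))
  cat(sprintf("  %d IMFs + residue; stop: %s\n", length(x$imfs), x$stop_reason))
  if (length(x$imfs)) {
    zc <- vapply(x$imfs, count_zero_crossings, numeric(1))
    cat("  zero crossings per IMF:", paste(zc, collapse = ", "), "\n")
    cat("  sift counts:          ", paste(x$sift_counts, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.emd <- function(x, max_panels = 6L, ...) {
  k <- length(x$imfs)
  shown <- min(k, max_panels)
  old <- graphics::par(mfrow = c(shown + 2L, 1L), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  t <- (seq_len(x$source_length) - 1) / x$fs
  graphics::plot(t, x$source, type = "l", ylab = "x", ...)
  for (i in seq_len(shown))
    graphics::plot(t, x$imfs[[i]], type = "l", ylab = sprintf("IMF %d", i))
  graphics::plot(t, x$residue, type = "l", ylab = "residue")
  invisible(x)
}
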