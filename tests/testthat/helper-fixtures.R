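# Shared fixtures, built in code. The random-signal suite used by the
# completeness/validity checks is decomposed once and cached for the session.

fixture_cache <- new.env(parent = emptyenv())

# 50 seeded random signals, lengths 256..4096, with their decompositions.
random_decomposition_suite <- function() {
  if (!is.null(fixture_cache$suite)) return(fixture_cache$suite)
  suite <- lapply(seq_len(50), function(i) {
    set.seed(1000 + i)
    n <- sample(256:4096, 1)
    x <- rnorm(n)
    list(x = x, d = emd(x, fs = 250))
  })
  fixture_cache$suite <- suite
  suite
}

# Reference 30 s synthetic record used by the denoising checks.
reference_ecg <- function() {
  if (is.null(fixture_cache$ecg))
    fixture_cache$ecg <- synth_ecg(duration_s = 30, fs = 360,
                                   heart_rate_bpm = 72, seed = 11)
  fixture_cache$ecg
}

# Hand-built decomposition object for unit-testing the selection stage
# without running the sifter.
fake_emd <- function(imfs, residue, fs = 1) {
  structure(list(imfs = imfs, residue = residue,
                 source = Reduce(`+`, imfs, residue), fs = fs,
                 name = "fake", source_length = length(residue),
                 stop_reason = "monotonic_residue",
                 sift_counts = rep(1L, length(imfs))),
            class = "emd")
}

# Power in (0, hi] Hz via the FFT, DC excluded (periodogram convention).
band_power <- function(x, fs, hi = 0.5) {
  n <- length(x)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  sum(Mod(stats::fft(x)[f > 0 & f <= hi])^2) / n
}

# Brute-force interior-extrema scan implementing the first-index-of-a-
# plateau rule, used as the independent oracle for find_extrema.
scan_extrema <- function(x) {
  n <- length(x)
  maxima <- integer(0); minima <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L  # plateau end
    if (j < n) {
      if (x[i] > x[i - 1L] && x[i] > x[j + 1L]) maxima <- c(maxima, i)
      if (x[i] < x[i - 1L] && x[i] < x[j + 1L]) minima <- c(minima, i)
    }
    i <- j + 1L
  }
  list(maxima = maxima, minima = minima)
}
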