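#' Locate interior local extrema
#'
#' Finds the strictly interior local maxima and minima of a sequence. A flat
#' run (plateau) counts as a single extremum located at its first index, so
#' the result is deterministic and maxima/minima strictly alternate when
#' merged in index order. The first and last samples are never reported.
#'
#' @param samples Numeric vector, length at least 3.
#' @return A list with integer vectors `maxima` and `minima` (1-based
#'   indices, strictly increasing).
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0)) # maxima 2, minima 4
#' find_extrema(c(0, 1, 1, 0))     # plateau: maxima 2
#' @export
find_extrema <- function(samples) {
  if (length(samples) < 3L)
    stop("'samples' must have length >= 3")
  r <- rle(as.numeric(samples))
  v <- r$values
  m <- length(v)
  if (m < 3L)
    return(list(maxima = integer(0), minima = integer(0)))
  starts <- cumsum(c(1L, r$lengths[-m]))
  j <- 2:(m - 1L)
  is_max <- v[j] > v[j - 1L] & v[j] > v[j + 1L]
  is_min <- v[j] < v[j - 1L] & v[j] < v[j + 1L]
  list(maxima = as.integer(starts[j][is_max]),
       minima = as.integer(starts[j][is_min]))
}

# Zero crossings: a strict sign change between consecutive samples counts
# once; a run of exact zeros entered from a nonzero value counts as a single
# crossing (never double-counted against its neighbours).
count_zero_crossings <- function(samples) {
  s <- sign(samples)
  strict <- sum(s[-length(s)] * s[-1L] < 0)
  runs <- rle(s)
  zero_runs <- which(runs$values == 0)
  zero_runs <- zero_runs[zero_runs > 1L] # a leading zero run is not a crossing
  strict + length(zero_runs)
}

#' Test the intrinsic-mode-function criterion
#'
#' An intrinsic mode function (IMF) must have extrema and zero-crossing
#' counts that agree to within one. Extrema are interior local maxima and
#' minima per [find_extrema()]; zero crossings follow the convention that an
#' exact zero sample counts once.
#'
#' @param samples Numeric vector, length at least 3.
#' @return `TRUE` if `|#extrema - #zero crossings| <= 1`.
#' @examples
#' is_imf(sin(2 * pi * (0:99) / 100)) # one period of a sine: TRUE
#' is_imf(sin(2 * pi * (0:99) / 10) + 10) # offset kills the crossings: FALSE
#' @export
is_imf <- function(samples) {
  if (length(samples) < 3L)
    stop("'samples' must have length >= 3")
  ext <- find_extrema(samples)
  n_ext <- length(ext$maxima) + length(ext$minima)
  abs(n_ext - count_zero_crossings(samples)) <= 1L
}
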