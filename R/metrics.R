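#' Output SNR improvement in dB
#'
#' `10 log10` of the corrupted-error energy over the denoised-error energy:
#' positive when denoising moved the record closer to the clean reference.
#' A perfect reconstruction reports `+Inf`; a corrupted record identical to
#' the reference reports `-Inf`. Both sentinels are dropped (with a logged
#' count) by the Monte-Carlo aggregator.
#'
#' @param original Clean reference samples.
#' @param corrupted Noisy samples.
#' @param denoised Denoised samples.
#' @return SNR improvement in dB.
#' @examples
#' snr_improvement(c(0, 0), c(1, 1), c(1, 1)) # 0 dB
#' @export
snr_improvement <- function(original, corrupted, denoised) {
  if (length(original) != length(corrupted) || length(original) != length(denoised))
    stop("all three sequences must have equal length")
  num <- sum((corrupted - original)^2)
  den <- sum((denoised - original)^2)
  if (den == 0) return(Inf)
  if (num == 0) return(-Inf)
  10 * log10(num / den)
}

#' Mean squared error
#'
#' @param original,estimate Equal-length numeric vectors.
#' @return `mean((original - estimate)^2)`.
#' @export
mse <- function(original, estimate) {
  if (length(original) != length(estimate))
    stop("'original' and 'estimate' must have equal length")
  if (length(original) < 1L)
    stop("empty input")
  mean((original - estimate)^2)
}

#' Percentage root-mean-square difference (as a ratio)
#'
#' Square root of the error energy over the reference energy. Reported as a
#' plain ratio; multiply by 100 for the conventional percentage.
#'
#' @param original Reference samples (must not be identically zero).
#' @param estimate Estimate samples, same length.
#' @return Non-negative ratio.
#' @export
prd <- function(original, estimate) {
  if (length(original) != length(estimate))
    stop("'original' and 'estimate' must have equal length")
  e0 <- sum(original^2)
  if (e0 == 0)
    stop("'original' has zero energy: PRD is undefined")
  sqrt(sum((original - estimate)^2) / e0)
}

#' Input signal-to-noise ratio in dB
#'
#' Energy ratio of a clean signal to an additive noise component, used to
#' verify noise mixing.
#'
#' @param clean,noise Equal-length numeric vectors with nonzero energy.
#' @return `10 log10(sum(clean^2) / sum(noise^2))` in dB.
#' @export
input_snr <- function(clean, noise) {
  if (length(clean) != length(noise))
    stop("'clean' and 'noise' must have equal length")
  ec <- sum(clean^2)
  en <- sum(noise^2)
  if (ec == 0 || en == 0)
    stop("both sequences need nonzero energy")
  10 * log10(ec / en)
}
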