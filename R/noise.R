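#' Noise standard deviation for a target SNR
#'
#' The SNR of a synthetic dataset is referenced to the white matter b = 0
#' signal of the DW block: \code{sigma = mean(noise-free b = 0 signal over
#' voxels with vWM >= 0.99) / snr}.
#'
#' @param clean noise-free 4D array (as from \code{synthesize_dataset}).
#' @param phantom the \code{sc_phantom} the data were synthesized from.
#' @param protocol the matching \code{qmri_protocol}.
#' @param snr target signal-to-noise ratio (> 0).
#' @return noise standard deviation in signal units.
#' @export
sigma_from_snr <- function(clean, phantom, protocol, snr) {
  stopifnot(snr > 0)
  b0 <- which(protocol$modality == "DW" & protocol$b == 0)
  if (length(b0) == 0) stop("protocol contains no b = 0 DW measurement")
  wm <- which(as.vector(phantom$fractions$vWM) >= 0.99)
  if (length(wm) == 0) stop("no voxels with vWM >= 0.99")
  S <- matrix(clean, ncol = dim(clean)[4])
  mean(S[wm, b0]) / snr
}

#' Corrupt data with additive Gaussian noise
#'
#' @param data numeric array.
#' @param sigma noise standard deviation (> 0).
#' @param seed integer seed.
#' @return array of the same shape, \code{data + N(0, sigma^2)} i.i.d.
#' @export
add_gaussian_noise <- function(data, sigma, seed = 1L) {
  stopifnot(sigma > 0)
  noise <- withr::with_seed(as.integer(seed),
    stats::rnorm(length(data), 0, sigma))
  data + array(noise, dim = dim(data))
}

#' Corrupt data with Rician noise
#'
#' Magnitude of a complex signal with i.i.d. Gaussian noise on both channels:
#' \code{sqrt((S + n1)^2 + n2^2)} with \code{n1, n2 ~ N(0, sigma^2)}.
#'
#' @param data non-negative numeric array.
#' @param sigma noise standard deviation (> 0).
#' @param seed integer seed.
#' @return non-negative array of the same shape.
#' @export
add_rician_noise <- function(data, sigma, seed = 1L) {
  stopifnot(sigma > 0, all(data >= 0))
  n <- withr::with_seed(as.integer(seed),
    stats::rnorm(2L * length(data), 0, sigma))
  n1 <- n[seq_along(data)]
  n2 <- n[length(data) + seq_along(data)]
  array(sqrt((data + n1)^2 + n2^2), dim = dim(data))
}

#' Rician noise floor correction (method of moments)
#'
#' Second-moment inversion of the Rician bias,
#' \code{sqrt(max(m^2 - 2 sigma^2, 0))}, applied voxel-wise to denoised
#' magnitudes (E[m^2] = S^2 + 2 sigma^2 for a Rician magnitude m).
#'
#' @param x denoised magnitude value(s).
#' @param sigma_hat estimated noise standard deviation (>= 0).
#' @return corrected value(s), clamped at zero.
#' @export
floor_correct <- function(x, sigma_hat) {
  stopifnot(all(sigma_hat >= 0))
  sqrt(pmax(x^2 - 2 * sigma_hat^2, 0))
}

#' Reproducible per-cell seed for the study grid
#'
#' Mixes the base seed with the grid coordinates (SNR, noise model,
#' realization index) into a 31-bit seed so that any single cell of the
#' study grid is independently reproducible.
#'
#' @param base_seed integer base seed.
#' @param snr target SNR of the cell.
#' @param model \code{"gaussian"} or \code{"rician"}.
#' @param realization realization index (1-based).
#' @return integer in [1, 2^31 - 1].
#' @export
realization_seed <- function(base_seed, snr, model, realization) {
  mid <- if (identical(model, "rician")) 2 else 1
  h <- (as.double(base_seed) * 2654435761 + snr * 97003 +
          mid * 7919 + realization * 104729) %% (2^31 - 2)
  as.integer(h) + 1L
}
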