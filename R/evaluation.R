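# All quantile-based statistics use the linear-interpolation quantile rule
# (R's default type 7), fixed project-wide.
.iqr <- function(x) diff(stats::quantile(x, c(0.25, 0.75), names = FALSE,
                                         type = 7))

#' Percentage relative error of denoised signals
#'
#' \code{eps = 100 (denoised - truth)/truth} for every (voxel, measurement)
#' of the selected rows inside the mask. Error distributions from several
#' noise realizations are meant to be pooled before summarising: the median
#' of the pooled distribution measures accuracy, its interquartile range
#' measures precision.
#'
#' @param denoised,truth 4D arrays of identical shape; \code{truth} must be
#'   strictly positive inside the mask on the selected rows.
#' @param mask logical 3D array (e.g. the cord mask).
#' @param rows measurement (4th-dimension) indices to evaluate; default all.
#' @return numeric vector of percentage errors, voxels x measurements.
#' @export
relative_error <- function(denoised, truth, mask, rows = NULL) {
  stopifnot(identical(dim(denoised), dim(truth)))
  if (is.null(rows)) rows <- seq_len(dim(truth)[4])
  idx <- which(mask)
  D <- matrix(denoised, ncol = dim(truth)[4])[idx, rows, drop = FALSE]
  Tr <- matrix(truth, ncol = dim(truth)[4])[idx, rows, drop = FALSE]
  if (any(Tr <= 0)) stop("ground-truth signal must be > 0 inside the mask")
  as.vector(100 * (D - Tr) / Tr)
}

#' Summarise pooled relative errors
#'
#' @param eps vector of percentage relative errors (pooled over voxels,
#'   measurements and realizations).
#' @param n_realizations bookkeeping: how many realizations were pooled.
#' @return data frame with \code{median_eps}, \code{iqr_eps},
#'   \code{n_values}, \code{n_realizations}.
#' @export
error_summary <- function(eps, n_realizations = 1L) {
  data.frame(median_eps = stats::median(eps), iqr_eps = .iqr(eps),
             n_values = length(eps), n_realizations = n_realizations)
}

#' Relative-error accuracy/precision statistics
#'
#' Convenience wrapper: pools the percentage relative errors of one or more
#' denoised realizations against the shared ground truth and returns median
#' (accuracy) and IQR (precision).
#'
#' @param denoised a 4D array or list of 4D arrays (one per realization).
#' @param truth noise-free 4D array.
#' @param mask logical 3D array.
#' @param rows measurement indices of the modality of interest.
#' @return data frame as in \code{\link{error_summary}}.
#' @export
relative_error_stats <- function(denoised, truth, mask, rows = NULL) {
  if (!is.list(denoised)) denoised <- list(denoised)
  eps <- unlist(lapply(denoised, relative_error, truth = truth, mask = mask,
                       rows = rows))
  error_summary(eps, n_realizations = length(denoised))
}

#' Percentage coefficient of variation of a map within a tissue
#'
#' \code{CoV = 100 * IQR/median} over mask voxels; quantiles use linear
#' interpolation. Scale-invariant for positive scalings.
#'
#' @param map 3D numeric array (or vector of values).
#' @param tissue_mask logical array selecting the tissue voxels (ignored if
#'   \code{map} is already a vector of values).
#' @return CoV in percent.
#' @export
cov_percent <- function(map, tissue_mask = NULL) {
  x <- if (is.null(tissue_mask)) as.vector(map) else map[tissue_mask]
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("empty tissue mask")
  med <- stats::median(x)
  if (med == 0) stop("zero median; CoV undefined")
  100 * .iqr(x) / med
}

#' Scan-rescan variability of a metric
#'
#' \code{100 * IQR(m1 - m2) / median((m1 + m2)/2)} over tissue voxels.
#'
#' @param m1,m2 3D metric maps at scan and rescan (co-registered).
#' @param tissue_mask logical array.
#' @return variability in percent.
#' @export
scan_rescan_variability <- function(m1, m2, tissue_mask) {
  d <- (m1 - m2)[tissue_mask]
  a <- ((m1 + m2) / 2)[tissue_mask]
  ok <- is.finite(d) & is.finite(a)
  if (!any(ok)) stop("empty tissue mask")
  med <- stats::median(a[ok])
  if (med == 0) stop("zero median average; variability undefined")
  100 * .iqr(d[ok]) / med
}

#' White/grey matter contrast-to-noise ratio of a metric map
#'
#' \code{|median(m_WM) - median(m_GM)| / sqrt((IQR_WM/1.349)^2 +
#' (IQR_GM/1.349)^2)}; IQR/1.349 estimates the standard deviation of a
#' normal distribution.
#'
#' @param map 3D metric map.
#' @param wm_mask,gm_mask logical arrays (non-empty).
#' @return unitless CNR (defined as 0 when both spreads and the median gap
#'   vanish).
#' @export
cnr <- function(map, wm_mask, gm_mask) {
  wm <- map[wm_mask]; gm <- map[gm_mask]
  wm <- wm[is.finite(wm)]; gm <- gm[is.finite(gm)]
  if (length(wm) == 0 || length(gm) == 0) stop("empty tissue mask")
  gap <- abs(stats::median(wm) - stats::median(gm))
  spread <- sqrt((.iqr(wm) / 1.349)^2 + (.iqr(gm) / 1.349)^2)
  if (spread == 0) {
    if (gap == 0) {
      message("degenerate CNR (zero gap and spread); returning 0")
      return(0)
    }
    stop("zero denominator in CNR with non-zero contrast")
  }
  gap / spread
}

#' Estimate the mean cord SNR of a dataset
#'
#' Normalises the mean b = 0 image by the noise standard deviation estimated
#' by MP-PCA (conventionally from denoising the DW block alone) and averages
#' over cord voxels.
#'
#' @param data 4D array.
#' @param protocol the matching \code{qmri_protocol}.
#' @param sigma_map 3D array of noise sd estimates (NA outside the cord).
#' @param cord_mask logical 3D array.
#' @return mean SNR within the cord.
#' @export
estimate_snr <- function(data, protocol, sigma_map, cord_mask) {
  b0 <- which(protocol$modality == "DW" & protocol$b == 0)
  if (length(b0) == 0) stop("protocol contains no b = 0 DW measurement")
  mb0 <- apply(data[, , , b0, drop = FALSE], 1:3, mean)
  sig <- sigma_map[cord_mask]
  if (any(!is.finite(sig)) || any(sig == 0)) {
    stop("sigma map must be positive on all cord voxels")
  }
  mean(mb0[cord_mask] / sig)
}

#' Normalised-residual diagnostics of a denoising run
#'
#' Residuals \code{r = (noisy - denoised)/sigma_hat} pooled over mask voxels
#' and measurements. Well-behaved denoising leaves residuals that look like
#' unit-variance white noise: near-zero mean, sd close to 1, no skewness or
#' excess kurtosis, and no spatial correlation between in-plane neighbours.
#'
#' @param noisy,denoised 4D arrays of identical shape.
#' @param sigma_hat scalar or 3D array of noise sd estimates (> 0 in mask).
#' @param mask logical 3D array.
#' @return data frame with \code{mean}, \code{sd}, \code{skewness},
#'   \code{excess_kurtosis} and \code{lag1_autocorrelation} (in-plane
#'   x-neighbour correlation of residuals within the mask).
#' @export
residual_diagnostics <- function(noisy, denoised, sigma_hat, mask) {
  stopifnot(identical(dim(noisy), dim(denoised)))
  dims <- dim(noisy)
  sig <- if (length(sigma_hat) == 1L) {
    array(sigma_hat, dims[1:3])
  } else sigma_hat
  if (any(!is.finite(sig[mask])) || any(sig[mask] <= 0)) {
    stop("sigma_hat must be > 0 inside the mask")
  }
  R <- (noisy - denoised) / array(rep(sig, dims[4]), dims)
  r <- matrix(R, ncol = dims[4])[which(mask), , drop = FALSE]
  x <- as.vector(r)
  m <- mean(x); s <- stats::sd(x)
  z <- if (s > 0) (x - m) / s else x * 0
  # lag-1 spatial correlation: pairs of x-adjacent in-mask voxels
  pairs_a <- NULL; pairs_b <- NULL
  shifted <- array(FALSE, dims[1:3])
  shifted[-dims[1], , ] <- mask[-1, , , drop = FALSE]
  both <- mask & shifted
  if (any(both)) {
    idx_a <- which(both)
    idx_b <- which(both) + 1L
    A <- matrix(R, ncol = dims[4])
    pairs_a <- as.vector(A[idx_a, , drop = FALSE])
    pairs_b <- as.vector(A[idx_b, , drop = FALSE])
  }
  lag1 <- if (!is.null(pairs_a) && stats::sd(pairs_a) > 0 &&
                stats::sd(pairs_b) > 0) {
    stats::cor(pairs_a, pairs_b)
  } else NA_real_
  data.frame(mean = m, sd = s,
             skewness = mean(z^3),
             excess_kurtosis = mean(z^4) - 3,
             lag1_autocorrelation = lag1)
}

#' Tabulate noise-level estimates across denoising runs
#'
#' Aggregates the per-call logs of \code{\link{denoise_slicewise}} into one
#' table of sigma estimates per (row set, slice), the raw material for
#' checking that noise levels estimated from different modality subsets
#' agree on homoscedastic data (and that subsets with few measurements give
#' unstable estimates).
#'
#' @param runs list of \code{denoise_slicewise} results (or of their
#'   \code{log} data frames).
#' @return data frame with columns \code{run, slice, set, M, N, P,
#'   sigma_hat}; empty input gives an empty table.
#' @export
sigma_trend_report <- function(runs) {
  if (length(runs) == 0) {
    return(data.frame(run = integer(), slice = integer(), set = character(),
                      M = integer(), N = integer(), P = integer(),
                      sigma_hat = numeric()))
  }
  do.call(rbind, lapply(seq_along(runs), function(i) {
    lg <- if (is.data.frame(runs[[i]])) runs[[i]] else runs[[i]]$log
    cbind(run = i, lg)
  }))
}
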