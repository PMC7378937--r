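#' Squared singular value spectrum
#'
#' @param A numeric matrix.
#' @return squared singular values, descending. An all-zero matrix returns an
#'   all-zero spectrum.
#' @export
sv_spectrum <- function(A) {
  A <- as.matrix(A)
  if (all(A == 0)) return(rep(0, min(dim(A))))
  sort(svd(A, nu = 0, nv = 0)$d^2, decreasing = TRUE)
}

#' Marchenko-Pastur PCA denoising of a signal matrix
#'
#' Singular-value truncation where the noise-only components are identified
#' as those whose eigenvalue distribution is compatible with the
#' Marchenko-Pastur law. Writing R = min(M, N) and L = max(M, N), the
#' eigenvalues of the scaled covariance are \code{lambda_k = s_k^2 / L}
#' (squared singular values over the larger dimension), descending. The
#' number of retained components P is the smallest p in [0, R - 1] such that
#' the Marchenko-Pastur range-based noise estimate
#' \code{(lambda_(p+1) - lambda_R) / (4 sqrt((R - p)/L))} does not exceed the
#' tail-mean estimate \code{mean(lambda_(p+1..R))}; the noise variance
#' estimate is the tail mean at the selected p. Components beyond P are
#' nullified and the matrix reconstructed. The matrix is not mean-centred.
#' If no p satisfies the criterion the input is returned unchanged with
#' sigma_hat = 0 (noise-free fallback).
#'
#' @param A numeric matrix, M measurements x N voxels, min(M, N) >= 2; all
#'   entries finite.
#' @return object of class \code{denoise_result}: list with \code{denoised}
#'   (same shape as input), \code{sigma_hat}, \code{P} and \code{sv_squared}
#'   (descending squared singular values of the input).
#' @export
mp_pca <- function(A) {
  A <- as.matrix(A)
  if (any(!is.finite(A))) stop("non-finite entries in input matrix")
  M <- nrow(A); N <- ncol(A)
  if (min(M, N) < 2) stop("matrix must have at least 2 rows and 2 columns")
  R <- min(M, N); L <- max(M, N)
  sv <- svd(A)
  lam <- sv$d^2 / L
  P <- NA_integer_
  sigma2 <- 0
  for (p in 0:(R - 1L)) {
    tail <- lam[(p + 1L):R]
    rng <- (lam[p + 1L] - lam[R]) / (4 * sqrt((R - p) / L))
    if (rng <= mean(tail)) {
      P <- p
      sigma2 <- mean(tail)
      break
    }
  }
  if (is.na(P)) {
    den <- A
    P <- R
    sigma2 <- 0
  } else if (P == 0L) {
    den <- matrix(0, M, N)
  } else {
    den <- sv$u[, seq_len(P), drop = FALSE] %*%
      (sv$d[seq_len(P)] * t(sv$v[, seq_len(P), drop = FALSE]))
  }
  structure(list(denoised = den, sigma_hat = sqrt(sigma2), P = P,
                 sv_squared = sort(sv$d^2, decreasing = TRUE)),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("MP-PCA result: %d x %d, P = %d, sigma_hat = %.5g\n",
              nrow(x$denoised), ncol(x$denoised), x$P, x$sigma_hat))
  invisible(x)
}

#' Denoising strategy descriptor
#'
#' The three schemes evaluated by the study: \code{individual} (each modality
#' denoised in a separate MP-PCA call), \code{joint_all} (the full
#' concatenated measurement set denoised at once), and \code{joint_dwi_plus}
#' (the DW block concatenated with one partner modality; other modalities
#' pass through untouched).
#'
#' @param name one of \code{"individual"}, \code{"joint_all"},
#'   \code{"joint_dwi_plus"}.
#' @param partner partner modality for \code{joint_dwi_plus}: \code{"qMT"},
#'   \code{"IR"} or \code{"mTE"}.
#' @return object of class \code{denoise_strategy}.
#' @export
denoise_strategy <- function(name = c("individual", "joint_all",
                                      "joint_dwi_plus"), partner = NULL) {
  name <- match.arg(name)
  if (name == "joint_dwi_plus") {
    partner <- match.arg(partner, c("qMT", "IR", "mTE"))
  } else {
    partner <- NULL
  }
  structure(list(name = name, partner = partner), class = "denoise_strategy")
}

#' Measurement-row sets denoised by a strategy
#'
#' @param strategy a \code{denoise_strategy}.
#' @param protocol a \code{qmri_protocol}.
#' @return named list of integer row-index vectors, one per MP-PCA call.
#' @export
strategy_row_sets <- function(strategy, protocol) {
  stopifnot(inherits(strategy, "denoise_strategy"))
  switch(strategy$name,
    individual = {
      sets <- lapply(c("DW", "qMT", "IR", "mTE"), modality_rows,
                     protocol = protocol)
      names(sets) <- c("DW", "qMT", "IR", "mTE")
      sets[vapply(sets, length, 1L) > 0]
    },
    joint_all = list(all = seq_len(nrow(protocol))),
    joint_dwi_plus = {
      s <- list(c(modality_rows(protocol, "DW"),
                  modality_rows(protocol, strategy$partner)))
      names(s) <- paste0("DW+", strategy$partner)
      s
    })
}

#' Slice-wise MP-PCA denoising of a 4D dataset
#'
#' For every slice, cord voxels are arranged as columns of a measurements x
#' voxels matrix (columns ordered by in-plane position, y-major with x
#' varying fastest, so results are bit-reproducible), the rows selected by
#' the strategy are denoised jointly per set, and written back. Rows not in
#' any of the strategy's sets pass through untouched. Slices with fewer than
#' 2 cord voxels pass through with a warning.
#'
#' @param data 4D array (nx, ny, nslices, M).
#' @param cord_mask logical 3D array of cord voxels.
#' @param protocol a \code{qmri_protocol} with M rows.
#' @param strategy a \code{denoise_strategy}.
#' @return list with \code{denoised} (4D array), \code{sigma_maps} and
#'   \code{P_maps} (named lists of 3D arrays, one per denoised row set, with
#'   the per-slice estimate broadcast over that slice's cord voxels, NA
#'   elsewhere), and \code{log} (data frame with one row per MP-PCA call:
#'   slice, set, M, N, P, sigma_hat).
#' @export
denoise_slicewise <- function(data, cord_mask, protocol, strategy) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == nrow(protocol))
  sets <- strategy_row_sets(strategy, protocol)
  dims <- dim(data)
  out <- data
  sigma_maps <- lapply(sets, function(s) array(NA_real_, dims[1:3]))
  P_maps <- lapply(sets, function(s) array(NA_real_, dims[1:3]))
  log <- NULL
  for (z in seq_len(dims[3])) {
    msk <- cord_mask[, , z]
    idx <- which(msk)
    if (length(idx) < 2L) {
      if (length(idx) > 0L) {
        warning(sprintf("slice %d has < 2 cord voxels; passed through", z))
      }
      next
    }
    ij <- arrayInd(idx, dims[1:2])
    ord <- order(ij[, 2L], ij[, 1L]) # y-major, x fastest
    idx <- idx[ord]
    flat <- matrix(data[, , z, ], nrow = prod(dims[1:2]))
    for (sname in names(sets)) {
      rows <- sets[[sname]]
      A <- t(flat[idx, rows, drop = FALSE]) # M x N
      res <- mp_pca(A)
      flat[idx, rows] <- t(res$denoised)
      sl <- sigma_maps[[sname]][, , z]
      sl[idx] <- res$sigma_hat
      sigma_maps[[sname]][, , z] <- sl
      pl <- P_maps[[sname]][, , z]
      pl[idx] <- res$P
      P_maps[[sname]][, , z] <- pl
      log <- rbind(log, data.frame(slice = z, set = sname,
                                   M = nrow(A), N = ncol(A), P = res$P,
                                   sigma_hat = res$sigma_hat))
    }
    out[, , z, ] <- array(flat, c(dims[1:2], 1L, dims[4]))
  }
  list(denoised = out, sigma_maps = sigma_maps, P_maps = P_maps, log = log)
}

#' Rough SNR gain of singular-value truncation
#'
#' With M measurements and P retained components the thermal-noise SNR gain
#' of the truncation is roughly M/P.
#'
#' @param M number of measurements.
#' @param P number of retained components (>= 1).
#' @return M / P.
#' @export
snr_gain_estimate <- function(M, P) {
  if (any(P < 1)) stop("P must be >= 1")
  M / P
}
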