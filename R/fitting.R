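# unique index sets of a symmetric order-4 tensor and their multiplicities
.kt_idx <- local({
  combs <- expand.grid(i = 1:3, j = 1:3, k = 1:3, l = 1:3)
  key <- apply(combs, 1L, function(r) paste(sort(r), collapse = ""))
  uk <- unique(key)
  mult <- as.integer(table(key)[uk])
  idx <- do.call(rbind, lapply(uk, function(k)
    as.integer(strsplit(k, "")[[1]])))
  list(idx = idx, mult = mult)
})

# design row blocks for the kurtosis representation
.dki_design <- function(bvals, bvecs) {
  b <- bvals * 1e-3 # ms/um^2 so that b*D is dimensionless with D in um^2/ms
  g <- bvecs
  g[bvals == 0, ] <- 0
  d_terms <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                   2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                   2 * g[, 2] * g[, 3])
  w_terms <- sapply(seq_len(nrow(.kt_idx$idx)), function(c0) {
    ii <- .kt_idx$idx[c0, ]
    .kt_idx$mult[c0] * g[, ii[1]] * g[, ii[2]] * g[, ii[3]] * g[, ii[4]]
  })
  cbind(1, -b * d_terms, (b^2 / 6) * w_terms)
}

.dki_voxel <- function(s, X, bvals, bvecs, k_clamp = c(-2, 10)) {
  y <- log(pmax(s, 1e-10))
  # WLS weighted by the squared observed signals: near-zero (sub-noise-floor
  # or clamped) measurements get vanishing weight, so their log outliers
  # cannot poison the fit
  w <- pmax(s, 1e-8)^2
  fit <- stats::lm.fit(X * sqrt(w), y * sqrt(w))
  beta <- fit$coefficients
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  md <- mean(ev)
  fa <- if (sum(ev^2) > 0) {
    sqrt(1.5 * sum((ev - md)^2) / sum(ev^2))
  } else 0
  V <- beta[-(1:7)] # = MD_app^2 * W tensor elements (with multiplicities out)
  dirs <- unique(bvecs[bvals > 0, , drop = FALSE])
  kapp <- apply(dirs, 1L, function(gd) {
    dg <- as.numeric(t(gd) %*% D %*% gd)
    vg <- sum(V * .kt_idx$mult *
                gd[.kt_idx$idx[, 1]] * gd[.kt_idx$idx[, 2]] *
                gd[.kt_idx$idx[, 3]] * gd[.kt_idx$idx[, 4]])
    vg / max(dg, 1e-6)^2
  })
  kapp <- pmin(pmax(kapp, k_clamp[1]), k_clamp[2])
  c(FA = min(max(fa, 0), 1), MD = md, MK = mean(kapp))
}

#' Diffusion kurtosis fit
#'
#' Voxel-wise weighted-least-squares fit of the log-signal kurtosis
#' representation \code{ln S = ln S0 - b g:D:g + (b^2/6) (MD_app^2 W):gggg},
#' with weights equal to the squared observed signals. MD is
#' trace(D)/3; FA follows from the tensor eigenvalues; MK is the mean of the
#' directional apparent kurtosis over the acquired diffusion directions,
#' clamped to [-2, 10] before averaging.
#'
#' @param dwi 4D array (nx, ny, nz, n_meas) of DW signals.
#' @param bvals b-values, s/mm^2, one per measurement.
#' @param bvecs n_meas x 3 matrix of gradient directions.
#' @param mask logical 3D array of voxels to fit.
#' @return list of 3D arrays \code{FA}, \code{MD}, \code{MK} and logical
#'   \code{valid}.
#' @export
fit_dki <- function(dwi, bvals, bvecs, mask) {
  if (length(bvals) < 22) stop("underdetermined: need >= 22 DW measurements")
  dims <- dim(dwi)
  X <- .dki_design(bvals, bvecs)
  FA <- MD <- MK <- array(NA_real_, dims[1:3])
  valid <- array(FALSE, dims[1:3])
  S <- matrix(dwi, ncol = dims[4])
  for (v in which(mask)) {
    est <- tryCatch(.dki_voxel(S[v, ], X, bvals, bvecs),
                    error = function(e) NULL)
    if (!is.null(est) && all(is.finite(est))) {
      FA[v] <- est["FA"]; MD[v] <- est["MD"]; MK[v] <- est["MK"]
      valid[v] <- TRUE
    }
  }
  list(FA = FA, MD = MD, MK = MK, valid = valid)
}

#' Mono-exponential T2 fit
#'
#' Voxel-wise nonlinear fit of \code{A exp(-TE/T2)} on multi-echo data,
#' initialised from the log-linear solution; T2 bounded to (1, 3000] ms.
#' Voxels whose log-linear trend is non-decreasing are flagged invalid.
#'
#' @param mte 4D array of multi-echo signals.
#' @param TEs echo times, ms (>= 3).
#' @param mask logical 3D array.
#' @return list of 3D arrays \code{T2}, \code{A} and logical \code{valid}.
#' @export
fit_t2 <- function(mte, TEs, mask) {
  if (length(TEs) < 3) stop("need >= 3 echo times")
  dims <- dim(mte)
  T2 <- A <- array(NA_real_, dims[1:3])
  valid <- array(FALSE, dims[1:3])
  S <- matrix(mte, ncol = dims[4])
  for (v in which(mask)) {
    s <- S[v, ]
    if (all(s <= 0)) next
    ll <- stats::lm.fit(cbind(1, TEs), log(pmax(s, 1e-10)))
    if (ll$coefficients[2] >= 0) next
    t2_0 <- min(max(-1 / ll$coefficients[2], 2), 3000)
    fit <- tryCatch(minpack.lm::nlsLM(
      s ~ A * exp(-TEs / T2),
      start = list(A = exp(ll$coefficients[1]), T2 = t2_0),
      lower = c(0, 1.001), upper = c(Inf, 3000),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    T2[v] <- cf["T2"]; A[v] <- cf["A"]; valid[v] <- TRUE
  }
  list(T2 = T2, A = A, valid = valid)
}

#' Inversion recovery T1 fit (magnitude model)
#'
#' Voxel-wise nonlinear fit of \code{A |1 - 2 exp(-TI/T1)|} with three
#' starting points around the null-point estimate (the magnitude model has a
#' local minimum at the signal null, which multi-start escapes); T1 bounded
#' to (10, 10000] ms.
#'
#' @param ir 4D array of inversion recovery signals.
#' @param TIs inversion times, ms (>= 3).
#' @param mask logical 3D array.
#' @return list of 3D arrays \code{T1}, \code{A} and logical \code{valid}.
#' @export
fit_t1_ir <- function(ir, TIs, mask) {
  if (length(TIs) < 3) stop("need >= 3 inversion times")
  dims <- dim(ir)
  T1 <- A <- array(NA_real_, dims[1:3])
  valid <- array(FALSE, dims[1:3])
  S <- matrix(ir, ncol = dims[4])
  for (v in which(mask)) {
    s <- S[v, ]
    if (all(s == 0)) next
    t1_null <- TIs[which.min(s)] / log(2)
    best <- NULL
    for (t1_0 in t1_null * c(0.5, 1, 2)) {
      fit <- tryCatch(minpack.lm::nlsLM(
        s ~ A * abs(1 - 2 * exp(-TIs / T1)),
        start = list(A = max(s), T1 = min(max(t1_0, 11), 9999)),
        lower = c(0, 10.001), upper = c(Inf, 10000),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) {
          best <- list(coef = stats::coef(fit), rss = rss)
        }
      }
    }
    if (is.null(best)) next
    T1[v] <- best$coef["T1"]; A[v] <- best$coef["A"]; valid[v] <- TRUE
  }
  list(T1 = T1, A = A, valid = valid)
}

# model predictions for one voxel's saturated qMT measurements
.qmt_predict <- function(bpf, k, t2b, T1, T2F, pairs, delays, n_seg,
                         b1_scale = 1, b0_offset = 0) {
  pr <- data.frame(theta_deg = pairs$theta_deg * b1_scale,
                   delta_f_khz = pairs$delta_f_khz + b0_offset)
  params <- data.frame(T1 = T1, T2F = T2F, k = k, T2B = t2b, BPF = bpf)
  as.vector(mt_weighting_profile(params, pr, delays_ms = delays,
                                 n_seg = n_seg,
                                 lineshape_fun = .lineshape_interp))
}

#' Two-pool quantitative magnetisation transfer fit
#'
#' Per voxel, the MT-weighted signals of each repetition are normalised by
#' the same-repetition theta = 0 reference (which cancels proton density and
#' echo-time weighting, leaving the pure MT-weighting factor), then
#' (BPF, k, T2B) are estimated by bounded nonlinear least squares with the
#' two-pool Bloch simulator as forward model: a coarse grid search followed
#' by local refinement. T1 is constrained to the supplied map and the free
#' pool T2 is fixed to the supplied T2 map. Optional per-voxel B1 scale
#' (multiplies the nominal flip angles) and B0 offset (adds to the offset
#' frequencies) maps support field-corrected fitting; they default to ideal.
#' Bounds: BPF in [0, 0.5], k in [0.1, 10] 1/s, T2B in [5, 20] us.
#'
#' @param qmt 4D array of the qMT block (n_meas = rows of the qMT protocol
#'   block).
#' @param protocol the full \code{qmri_protocol} (its qMT rows describe the
#'   block, in order).
#' @param T1_map,T2_map 3D arrays of fixed relaxation times, ms.
#' @param mask logical 3D array.
#' @param b1_scale_map,b0_offset_map optional 3D arrays (default 1 and 0).
#' @param n_seg MT discretisation (must match synthesis for simulation
#'   studies).
#' @return list of 3D arrays \code{BPF}, \code{k}, \code{T2B} and logical
#'   \code{valid}.
#' @export
fit_qmt <- function(qmt, protocol, T1_map, T2_map, mask,
                    b1_scale_map = NULL, b0_offset_map = NULL, n_seg = 64L) {
  qrows <- modality_rows(protocol, "qMT")
  qp <- protocol[qrows, ]
  dims <- dim(qmt)
  stopifnot(dims[4] == nrow(qp))
  ref <- which(qp$theta_deg == 0)
  if (length(ref) == 0) stop("qMT block has no theta = 0 reference")
  sat <- which(qp$theta_deg > 0)
  pairs <- unique(qp[sat, c("theta_deg", "delta_f_khz")])
  delays <- sort(unique(qp$train_delay_ms))
  ip <- match(paste(qp$theta_deg[sat], qp$delta_f_khz[sat]),
              paste(pairs$theta_deg, pairs$delta_f_khz))
  id <- match(qp$train_delay_ms[sat], delays)
  pred_col <- (ip - 1L) * length(delays) + id # measurement -> profile column
  ref_of <- match(qp$train_delay_ms[sat], qp$train_delay_ms[ref])
  BPF <- K <- T2B <- array(NA_real_, dims[1:3])
  valid <- array(FALSE, dims[1:3])
  S <- matrix(qmt, ncol = dims[4])
  grid <- expand.grid(bpf = c(0.03, 0.09, 0.16, 0.3),
                      k = c(0.6, 1.5, 3, 6),
                      t2b = c(7, 11, 16))
  for (v in which(mask)) {
    sref <- S[v, ref]
    if (any(sref <= 0) || !is.finite(T1_map[v]) || !is.finite(T2_map[v])) next
    wobs <- S[v, sat] / sref[ref_of]
    b1 <- if (is.null(b1_scale_map)) 1 else b1_scale_map[v]
    b0 <- if (is.null(b0_offset_map)) 0 else b0_offset_map[v]
    obj <- function(par) {
      wpred <- .qmt_predict(par[1], par[2], par[3], T1_map[v], T2_map[v],
                            pairs, delays, n_seg, b1, b0)[pred_col]
      sum((wpred - wobs)^2)
    }
    sse <- apply(grid, 1L, function(r) obj(as.numeric(r)))
    start <- as.numeric(grid[which.min(sse), ])
    fit <- tryCatch(stats::optim(start, obj, method = "L-BFGS-B",
                                 lower = c(0, 0.1, 5), upper = c(0.5, 10, 20),
                                 control = list(factr = 1e6, maxit = 60)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    BPF[v] <- fit$par[1]; K[v] <- fit$par[2]; T2B[v] <- fit$par[3]
    valid[v] <- TRUE
  }
  list(BPF = BPF, k = K, T2B = T2B, valid = valid)
}
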