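#' Gaussian diffusion attenuation of an axially symmetric tensor
#'
#' The diffusion tensor is axially symmetric with its principal axis along the
#' cord longitudinal direction z = (0, 0, 1): attenuation
#' \code{exp(-b * 1e-3 * (RD + (AD - RD) * (g.z)^2))} with b in s/mm^2 and
#' diffusivities in um^2/ms (hence the 1e-3 unit factor).
#'
#' @param b b-value, s/mm^2 (>= 0).
#' @param g gradient direction, unit 3-vector (ignored at b = 0).
#' @param AD,RD axial and radial diffusivity, um^2/ms.
#' @return attenuation in (0, 1].
#' @export
diffusion_attenuation <- function(b, g, AD, RD) {
  if (any(b < 0)) stop("negative b-value")
  gz2 <- if (is.matrix(g)) g[, 3]^2 else g[3]^2
  ifelse(b == 0, 1, exp(-b * 1e-3 * (RD + (AD - RD) * gz2)))
}

#' Inversion recovery weighting
#'
#' Magnitude longitudinal recovery factor \code{|1 - 2 exp(-TI/T1)|}.
#'
#' @param TI inversion time, ms.
#' @param T1 longitudinal relaxation time, ms (> 0).
#' @return value in [0, 1].
#' @export
ir_factor <- function(TI, T1) {
  if (any(T1 <= 0)) stop("non-positive T1")
  abs(1 - 2 * exp(-TI / T1))
}

#' Echo time weighting
#'
#' Transverse decay factor \code{exp(-TE/T2)}.
#'
#' @param TE echo time, ms (>= 0).
#' @param T2 transverse relaxation time, ms (> 0).
#' @return value in (0, 1].
#' @export
te_factor <- function(TE, T2) {
  if (any(T2 <= 0)) stop("non-positive T2")
  exp(-TE / T2)
}

.lineshape_cache <- new.env(parent = emptyenv())

.super_lorentzian_raw <- function(delta_hz, T2B_s) {
  key <- paste(signif(c(delta_hz, T2B_s), 12), collapse = "|")
  hit <- .lineshape_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- function(phi) {
    u <- 3 * cos(phi)^2 - 1
    arg <- 2 * (2 * pi * delta_hz * T2B_s / u)^2
    val <- sin(phi) * sqrt(2 / pi) * (T2B_s / abs(u)) * exp(-arg)
    val[!is.finite(val)] <- 0
    val
  }
  val <- stats::integrate(f, 0, pi / 2, rel.tol = 1e-10,
                          subdivisions = 500L)$value
  .lineshape_cache[[key]] <- val
  val
}

#' Super-Lorentzian absorption lineshape
#'
#' Absorption lineshape of the semi-solid (bound) proton pool,
#' \deqn{G(\Delta) = \int_0^{\pi/2} \sin\phi \sqrt{2/\pi}
#'   \frac{T_{2B}}{|3\cos^2\phi - 1|}
#'   \exp\left(-2 \left(\frac{2\pi\Delta T_{2B}}{3\cos^2\phi-1}\right)^2\right)
#'   d\phi,}
#' evaluated by adaptive quadrature. G is symmetric in \eqn{\Delta}. The
#' on-resonance singularity is handled conventionally: for offsets below
#' 1 kHz the lineshape is cubic-polynomial extrapolated from its values at
#' \{1, 1.33, 1.67, 2\} kHz (all saturation offsets used in the default
#' protocol are >= 1 kHz, so the extrapolation never enters synthesis).
#'
#' @param delta_f_khz offset frequency, kHz (may be negative).
#' @param T2B_us bound pool transverse relaxation time, microseconds (> 0).
#' @return lineshape value in seconds.
#' @export
super_lorentzian <- function(delta_f_khz, T2B_us) {
  if (any(T2B_us <= 0)) stop("non-positive T2B")
  if (length(delta_f_khz) > 1L) {
    return(vapply(delta_f_khz, super_lorentzian, numeric(1), T2B_us = T2B_us))
  }
  T2B_s <- T2B_us * 1e-6
  ad <- abs(delta_f_khz)
  if (ad >= 1) return(.super_lorentzian_raw(ad * 1e3, T2B_s))
  knots <- c(1, 4 / 3, 5 / 3, 2)
  gv <- vapply(knots, function(k) .super_lorentzian_raw(k * 1e3, T2B_s),
               numeric(1))
  coefs <- solve(outer(knots, 0:3, `^`), gv) # cubic through the four knots
  sum(coefs * ad^(0:3))
}

#' Sinc-Gaussian pulse envelope, discretised
#'
#' Piecewise-constant discretisation of the saturation pulse envelope: a sinc
#' of the stated bandwidth windowed by a Gaussian (sd = duration/4), sampled
#' at segment midpoints and scaled so the on-resonance flip integral of a
#' unit-flip pulse equals 1 radian.
#'
#' @param n_seg number of piecewise-constant segments (>= 8).
#' @param pulse_ms pulse duration, ms.
#' @param bw_hz sinc main-lobe bandwidth, Hz.
#' @return list with \code{env} (rad/s per radian of flip, length
#'   \code{n_seg}) and \code{dt_s} (segment duration, seconds).
#' @keywords internal
mt_pulse_envelope <- function(n_seg = 64L, pulse_ms = 15, bw_hz = 122) {
  stopifnot(n_seg >= 8)
  T_s <- pulse_ms * 1e-3
  dt <- T_s / n_seg
  tau <- (seq_len(n_seg) - 0.5) * dt - T_s / 2
  x <- pi * bw_hz * tau
  s <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  raw <- s * exp(-tau^2 / (2 * (T_s / 4)^2))
  list(env = raw / (sum(raw) * dt), dt_s = dt)
}

# Spline-tabulated lineshape in T2B, one spline per offset frequency, for
# iterative fitting where T2B varies continuously: avoids re-running the
# quadrature at every objective evaluation. Knots every 0.25 us over
# [4, 22] us bracket the fitting bounds; interpolation error is ~1e-8
# relative, far below fit tolerances.
.lineshape_interp <- local({
  cache <- new.env(parent = emptyenv())
  function(delta_f_khz, T2B_us) {
    key <- paste0("d", signif(delta_f_khz, 12))
    fn <- cache[[key]]
    if (is.null(fn)) {
      knots <- seq(4, 22, by = 0.25)
      gv <- vapply(knots, function(t2b) super_lorentzian(delta_f_khz, t2b),
                   numeric(1))
      fn <- stats::splinefun(knots, gv, method = "natural")
      cache[[key]] <- fn
    }
    fn(T2B_us)
  }
})

# package-local cache of MT weightings (keyed by train + tissue parameters)
.mt_cache <- new.env(parent = emptyenv())

#' Clear the magnetisation-transfer weighting cache
#' @export
mt_cache_clear <- function() {
  rm(list = ls(.mt_cache), envir = .mt_cache)
  invisible(NULL)
}

# core batch evaluation: w for every (voxel, saturation setting, delay)
# combination. params: data frame with T1, T2F, k, T2B, BPF (one row per
# voxel); pairs: data frame with theta_deg, delta_f_khz (theta > 0 only).
# Returns nvox x (npairs * ndelays) matrix, delay index fastest.
mt_weighting_profile <- function(params, pairs, delays_ms = .qmt_delays_ms,
                                 n_seg = 64L, n_pulses = 25L, pulse_ms = 15,
                                 gap_ms = 15, bw_hz = 122,
                                 lineshape_fun = super_lorentzian) {
  if (any(params$BPF >= 1)) stop("BPF must be < 1")
  if (any(pairs$theta_deg <= 0)) stop("saturation settings require theta > 0")
  nv <- nrow(params)
  np <- nrow(pairs)
  pe <- mt_pulse_envelope(n_seg, pulse_ms, bw_hz)
  theta_rad <- pairs$theta_deg * pi / 180
  omega1 <- outer(pe$env, theta_rad) # n_seg x npairs, rad/s
  # lineshape at each (voxel, setting); a vanishing bound pool (BPF below
  # 1e-4, physically negligible) is treated as absent, which also keeps the
  # back-exchange rate k*(1-BPF)/BPF bounded
  BPF <- params$BPF
  has_bound <- BPF > 1e-4
  G <- matrix(0, nv, np)
  for (v in seq_len(nv)) {
    if (has_bound[v]) {
      for (p in seq_len(np)) {
        G[v, p] <- lineshape_fun(pairs$delta_f_khz[p], params$T2B[v])
      }
    }
  }
  kf <- ifelse(has_bound, params$k, 0)
  Fpool <- ifelse(has_bound, BPF / (1 - BPF), 0)
  kb <- ifelse(has_bound, params$k * (1 - BPF) / pmax(BPF, 1e-12), 0)
  mt_weighting_batch_cpp(
    omega1, 2 * pi * pairs$delta_f_khz * 1e3, G, pe$dt_s,
    as.integer(n_pulses), gap_ms * 1e-3, delays_ms * 1e-3,
    1000 / params$T1, 1000 / params$T2F, kf, kb, Fpool)
}

#' Magnetisation-transfer weighting of a saturation train
#'
#' Integrates the coupled two-pool system over the pulse train (free pool:
#' full Bloch with off-resonance RF; bound pool: longitudinal magnetisation
#' saturated at rate \code{W(t) = pi * omega1(t)^2 * G(delta_f)} with the
#' super-Lorentzian lineshape; exchange \code{k} from free to bound, with
#' back-exchange \code{k (1 - BPF)/BPF} to satisfy equilibrium), starting
#' from thermal equilibrium, followed by free relaxation over the post-train
#' delay. The weighting is the free-pool longitudinal magnetisation at
#' readout divided by its equilibrium value. \code{theta = 0} means no
#' saturation and returns exactly 1. Results are cached per (train, tissue
#' parameters, discretisation) key.
#'
#' @param train a \code{pulse_train_spec}.
#' @param params tissue parameters: list/row with \code{T1}, \code{T2F},
#'   \code{k}, \code{T2B}, \code{BPF}.
#' @param n_seg piecewise-constant segments per pulse (default 64).
#' @return scalar weighting in (0, 1].
#' @export
simulate_mt_weighting <- function(train, params, n_seg = 64L) {
  stopifnot(inherits(train, "pulse_train_spec"))
  if (params$BPF >= 1) stop("BPF must be < 1")
  if (train$theta_deg == 0) return(1)
  key <- paste(signif(c(train$theta_deg, train$delta_f_khz,
                        train$post_delay_ms, train$n_pulses, train$pulse_ms,
                        train$gap_ms, train$bw_hz, params$T1, params$T2F,
                        params$k, params$T2B, params$BPF, n_seg), 12),
               collapse = "|")
  if (!is.null(.mt_cache[[key]])) return(.mt_cache[[key]])
  w <- mt_weighting_profile(
    as.data.frame(params[c("T1", "T2F", "k", "T2B", "BPF")]),
    data.frame(theta_deg = train$theta_deg,
               delta_f_khz = train$delta_f_khz),
    delays_ms = train$post_delay_ms, n_seg = n_seg,
    n_pulses = train$n_pulses, pulse_ms = train$pulse_ms,
    gap_ms = train$gap_ms, bw_hz = train$bw_hz)[1, 1]
  .mt_cache[[key]] <- w
  w
}

#' Noise-free signal of one tissue for one measurement
#'
#' Product of the proton density, echo-time, inversion-recovery, diffusion
#' and magnetisation-transfer factors; each factor defaults to 1 when its
#' mechanism is absent from the measurement (no inversion pulse, no diffusion
#' encoding, no off-resonance saturation).
#'
#' @param m one row of a \code{qmri_protocol}.
#' @param params a tissue parameter row (as from \code{sample_tissue_params}).
#' @param n_seg MT discretisation (see \code{simulate_mt_weighting}).
#' @return non-negative scalar signal (arbitrary units).
#' @export
synthesize_tissue_signal <- function(m, params, n_seg = 64L) {
  s <- params$rho * te_factor(m$TE, params$T2)
  if (!is.na(m$TI)) s <- s * ir_factor(m$TI, params$T1)
  if (!is.na(m$b) && m$b > 0) {
    s <- s * diffusion_attenuation(m$b, c(m$gx, m$gy, m$gz),
                                   params$AD, params$RD)
  }
  if (!is.na(m$theta_deg) && m$theta_deg > 0) {
    train <- pulse_train_spec(m$theta_deg, m$delta_f_khz, m$train_delay_ms)
    s <- s * simulate_mt_weighting(train, params, n_seg = n_seg)
  }
  s
}

#' Partial-volume voxel signal
#'
#' Volume-fraction-weighted sum of the WM, GM and CSF signals.
#'
#' @param m one row of a \code{qmri_protocol}.
#' @param fractions numeric 3-vector (vWM, vGM, vCSF) summing to 1.
#' @param wm,gm,csf tissue parameter rows.
#' @param n_seg MT discretisation.
#' @return list with \code{S_WM}, \code{S_GM}, \code{S_CSF}, \code{S_TOT}.
#' @export
synthesize_voxel <- function(m, fractions, wm, gm, csf, n_seg = 64L) {
  if (abs(sum(fractions) - 1) > 1e-6) stop("volume fractions must sum to 1")
  s <- list(S_WM = synthesize_tissue_signal(m, wm, n_seg),
            S_GM = synthesize_tissue_signal(m, gm, n_seg),
            S_CSF = synthesize_tissue_signal(m, csf, n_seg))
  s$S_TOT <- fractions[1] * s$S_WM + fractions[2] * s$S_GM +
    fractions[3] * s$S_CSF
  s
}

# vectorised per-tissue signal table: nvox x nmeas for a parameter data frame
.tissue_signal_matrix <- function(params, protocol, n_seg = 64L) {
  nv <- nrow(params)
  M <- nrow(protocol)
  S <- matrix(0, nv, M)
  for (j in seq_len(M)) {
    m <- protocol[j, ]
    s <- params$rho * te_factor(m$TE, params$T2)
    if (!is.na(m$TI)) s <- s * ir_factor(m$TI, params$T1)
    if (!is.na(m$b) && m$b > 0) {
      s <- s * exp(-m$b * 1e-3 * (params$RD + (params$AD - params$RD) * m$gz^2))
    }
    S[, j] <- s
  }
  # MT weighting: one train integration per (voxel, saturation setting)
  # serves all four repetition delays
  qrows <- which(protocol$modality == "qMT" & protocol$theta_deg > 0)
  if (length(qrows) > 0) {
    qsub <- protocol[qrows, ]
    pairs <- unique(qsub[, c("theta_deg", "delta_f_khz")])
    delays <- sort(unique(qsub$train_delay_ms))
    W <- mt_weighting_profile(params, pairs, delays_ms = delays, n_seg = n_seg)
    ip <- match(paste(qsub$theta_deg, qsub$delta_f_khz),
                paste(pairs$theta_deg, pairs$delta_f_khz))
    id <- match(qsub$train_delay_ms, delays)
    S[, qrows] <- S[, qrows, drop = FALSE] *
      W[, (ip - 1L) * length(delays) + id, drop = FALSE]
  }
  S
}

#' Synthesize the noise-free multi-contrast dataset
#'
#' Evaluates the noise-free signal of every voxel of the phantom for every
#' measurement of the protocol, weighting the per-tissue signals by the voxel
#' volume fractions. Pure-CSF background voxels share the fixed CSF signal
#' profile.
#'
#' @param phantom an \code{sc_phantom}.
#' @param protocol a \code{qmri_protocol}.
#' @param n_seg MT discretisation (segments per saturation pulse).
#' @param zero_background if TRUE, zero all voxels outside the cord mask
#'   dilated by one voxel in-plane.
#' @return 4D array \code{nx x ny x nslices x M} of noise-free signals.
#' @export
synthesize_dataset <- function(phantom, protocol, n_seg = 64L,
                               zero_background = FALSE) {
  stopifnot(inherits(phantom, "sc_phantom"))
  fr <- phantom$fractions
  dims <- fr$grid_shape
  M <- nrow(protocol)
  nvox <- prod(dims)
  S <- matrix(0, nvox, M)
  csf_sig <- .tissue_signal_matrix(phantom$csf_params, protocol, n_seg)[1, ]
  vCSF <- as.vector(fr$vCSF)
  S <- S + outer(vCSF, csf_sig)
  wm_sig <- .tissue_signal_matrix(phantom$wm_params, protocol, n_seg)
  S[phantom$wm_params$voxel, ] <- S[phantom$wm_params$voxel, , drop = FALSE] +
    as.vector(fr$vWM)[phantom$wm_params$voxel] * wm_sig
  gm_sig <- .tissue_signal_matrix(phantom$gm_params, protocol, n_seg)
  S[phantom$gm_params$voxel, ] <- S[phantom$gm_params$voxel, , drop = FALSE] +
    as.vector(fr$vGM)[phantom$gm_params$voxel] * gm_sig
  if (zero_background) {
    keep <- .dilate_mask(fr$cord_mask)
    S[!as.vector(keep), ] <- 0
  }
  array(S, dim = c(dims, M))
}

# one-voxel in-plane dilation of a logical 3D mask
.dilate_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) {
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    out <- out | mask[xs, ys, , drop = FALSE]
  }
  out
}
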