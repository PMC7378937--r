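#' Reference tissue parameter distributions
#'
#' Mean values (and, for white and grey matter, Gaussian standard deviations
#' equal to 10\% of the mean) of the nine tissue parameters that drive signal
#' synthesis: relative proton density \code{rho}, longitudinal relaxation time
#' \code{T1} (ms), transverse relaxation time \code{T2} (ms), axial and radial
#' diffusivity \code{AD}, \code{RD} (um^2/ms), free-to-bound exchange rate
#' \code{k} (1/s), free-pool transverse relaxation time \code{T2F} (ms, fixed
#' equal to \code{T2}), bound-pool transverse relaxation time \code{T2B} (us)
#' and bound pool fraction \code{BPF}. CSF has no bound pool, so its \code{k},
#' \code{T2B} and \code{BPF} are stored as inert zeros.
#'
#' @param tissue one of \code{"WM"}, \code{"GM"}, \code{"CSF"}.
#' @return named numeric vector of parameter means.
#' @export
tissue_reference_values <- function(tissue = c("WM", "GM", "CSF")) {
  tissue <- match.arg(tissue)
  switch(tissue,
    WM  = c(rho = 0.70, T1 = 1000, T2 = 70, AD = 2.10, RD = 0.40,
            k = 2.3, T2F = 70, T2B = 12, BPF = 0.14),
    GM  = c(rho = 0.80, T1 = 1200, T2 = 80, AD = 1.60, RD = 0.55,
            k = 1.7, T2F = 80, T2B = 12, BPF = 0.08),
    CSF = c(rho = 1.00, T1 = 4000, T2 = 800, AD = 3.00, RD = 3.00,
            k = 0, T2F = 800, T2B = 0, BPF = 0))
}

# parameters drawn from Gaussians; everything except T2F (slaved to T2) is
# sampled independently
.sampled_params <- c("rho", "T1", "T2", "AD", "RD", "k", "T2B", "BPF")

#' Sample per-voxel tissue parameters
#'
#' White and grey matter parameters are drawn independently per voxel from
#' Gaussian distributions with sd = 10\% of the mean, emulating within-tissue
#' biological variability; non-positive draws (probability ~ 1e-23 per draw
#' at 10\% relative sd) are redrawn. CSF parameters are fixed: every CSF draw
#' is the same vector. \code{T2F} is always set equal to the drawn \code{T2}.
#'
#' @param tissue one of \code{"WM"}, \code{"GM"}, \code{"CSF"}.
#' @param n number of voxels to draw.
#' @param seed integer seed; draws are reproducible given \code{(tissue, n, seed)}.
#' @return data frame with \code{n} rows and columns
#'   \code{rho, T1, T2, AD, RD, k, T2F, T2B, BPF}.
#' @export
sample_tissue_params <- function(tissue = c("WM", "GM", "CSF"), n, seed = 1L) {
  tissue <- match.arg(tissue)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive integer")
  }
  n <- as.integer(n)
  mu <- tissue_reference_values(tissue)
  if (tissue == "CSF") {
    out <- as.data.frame(as.list(mu))[rep(1L, n), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  out <- withr::with_seed(as.integer(seed), {
    draws <- lapply(.sampled_params, function(p) {
      x <- stats::rnorm(n, mu[[p]], 0.1 * mu[[p]])
      while (any(bad <- x <= 0)) {
        x[bad] <- stats::rnorm(sum(bad), mu[[p]], 0.1 * mu[[p]])
      }
      x
    })
    names(draws) <- .sampled_params
    as.data.frame(draws)
  })
  out$T2F <- out$T2
  out[, names(mu)]
}

# Stylised axial cross-section of the cervical cord, in mm, centred at the
# cord axis: an elliptical cord containing a butterfly-shaped grey matter
# region (two ventral horns, two dorsal horns, central commissure), bathed in
# CSF. Radii chosen so one 1x1 mm slice holds ~44 cord voxels, the scale at
# which slice-wise denoising matrices are formed.
.cord_radii <- c(ax = 3.80, ay = 2.90)

.in_ellipse <- function(x, y, cx, cy, a, b, angle = 0) {
  ca <- cos(angle); sa <- sin(angle)
  xr <- ca * (x - cx) + sa * (y - cy)
  yr <- -sa * (x - cx) + ca * (y - cy)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# classify supersampled points: 0 = CSF, 1 = WM, 2 = GM
.classify_cross_section <- function(x, y, scale = 1) {
  ax <- .cord_radii[["ax"]] * scale
  ay <- .cord_radii[["ay"]] * scale
  cord <- (x / ax)^2 + (y / ay)^2 <= 1
  gm <- .in_ellipse(x, y, 1.5, -1.2, 1.45, 1.15) |
    .in_ellipse(x, y, -1.5, -1.2, 1.45, 1.15) |
    .in_ellipse(x, y, 1.0, 1.6, 0.95, 0.58, -0.45) |
    .in_ellipse(x, y, -1.0, 1.6, 0.95, 0.58, 0.45) |
    (abs(x) <= 1.6 & abs(y + 0.1) <= 0.42)
  out <- integer(length(x))
  out[cord] <- 1L
  out[cord & gm] <- 2L
  out
}

#' Generate the synthetic spinal cord geometry
#'
#' Renders a parametric cord cross-section (elliptical cord with a
#' butterfly-shaped grey matter region, surrounded by CSF) onto a low
#' resolution voxel grid. Each voxel is supersampled \code{supersample} times
#' per in-plane axis so boundary voxels acquire realistic partial-volume
#' fractions. Slices vary smoothly in cord calibre (+/- 4\%) and receive a
#' small seeded in-plane jitter (< 0.2 mm) so that no two slices are exact
#' copies, mimicking anatomy sampled along the cord. Defaults yield roughly
#' 44 cord voxels per slice and ~1700 over 40 slices of 5 mm (200 mm
#' foot-head coverage).
#'
#' @param nx,ny in-plane grid size (>= 8).
#' @param nslices number of 5 mm slices (>= 1).
#' @param seed integer seed controlling the per-slice jitter.
#' @param supersample supersampling factor per in-plane axis (>= 8 advised).
#' @return object of class \code{vol_fractions}: list with \code{grid_shape},
#'   \code{voxel_size} (mm), 3D arrays \code{vWM}, \code{vGM}, \code{vCSF}
#'   summing to one everywhere, and logical array \code{cord_mask}
#'   (\code{vWM + vGM > 0}).
#' @export
generate_geometry <- function(nx = 16L, ny = 16L, nslices = 40L, seed = 1L,
                              supersample = 8L) {
  if (nx < 8 || ny < 8 || nslices < 1) {
    stop("grid must satisfy nx, ny >= 8 and nslices >= 1")
  }
  nx <- as.integer(nx); ny <- as.integer(ny); nslices <- as.integer(nslices)
  ss <- as.integer(supersample)
  vWM <- vGM <- vCSF <- array(0, dim = c(nx, ny, nslices))
  # voxel centres in mm, grid centred on the cord axis
  xc <- seq_len(nx) - (nx + 1) / 2
  yc <- seq_len(ny) - (ny + 1) / 2
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  # subsample coordinates: for every (voxel, suboffset) pair in-plane
  grid <- expand.grid(ix = seq_len(nx), ox = off, iy = seq_len(ny), oy = off)
  px <- xc[grid$ix] + grid$ox
  py <- yc[grid$iy] + grid$oy
  vox <- grid$ix + (grid$iy - 1L) * nx  # linear in-plane voxel id
  jitter <- withr::with_seed(as.integer(seed),
    matrix(stats::runif(2L * nslices, -0.18, 0.18), ncol = 2L))
  for (z in seq_len(nslices)) {
    scale <- 1 + 0.04 * sin(2 * pi * (z - 1) / max(nslices, 2L))
    cls <- .classify_cross_section(px - jitter[z, 1L], py - jitter[z, 2L],
                                   scale = scale)
    vWM[, , z] <- rowsum(as.numeric(cls == 1L), vox) / (ss * ss)
    vGM[, , z] <- rowsum(as.numeric(cls == 2L), vox) / (ss * ss)
  }
  vCSF <- 1 - vWM - vGM
  structure(list(
    grid_shape = c(nx, ny, nslices),
    voxel_size = c(1, 1, 5),
    vWM = vWM, vGM = vGM, vCSF = vCSF,
    cord_mask = (vWM + vGM) > 0,
    seed = as.integer(seed)
  ), class = "vol_fractions")
}

#' @export
print.vol_fractions <- function(x, ...) {
  cat("Spinal cord volume fractions:", paste(x$grid_shape, collapse = " x "),
      "voxels of", paste(x$voxel_size, collapse = " x "), "mm\n")
  cat("  cord voxels:", sum(x$cord_mask),
      sprintf("(%.1f per slice)\n", sum(x$cord_mask) / x$grid_shape[3]))
  invisible(x)
}

#' Build the ground-truth phantom
#'
#' Assigns a unique white matter parameter draw to every voxel with
#' \code{vWM > 0} and a unique grey matter draw to every voxel with
#' \code{vGM > 0}, so each voxel carries its own noise-free signal profile.
#' CSF parameters are fixed across all CSF-containing voxels.
#'
#' @param fractions a \code{vol_fractions} object.
#' @param seed integer seed for the parameter draws.
#' @return object of class \code{sc_phantom}: list with \code{fractions},
#'   data frames \code{wm_params} / \code{gm_params} (one row per voxel,
#'   column \code{voxel} holding the linear array index), single-row
#'   \code{csf_params}, and \code{seed}.
#' @export
build_phantom <- function(fractions, seed = 1L) {
  stopifnot(inherits(fractions, "vol_fractions"))
  wm_idx <- which(fractions$vWM > 0)
  gm_idx <- which(fractions$vGM > 0)
  wm <- sample_tissue_params("WM", length(wm_idx), seed = seed)
  gm <- sample_tissue_params("GM", length(gm_idx), seed = seed + 1L)
  wm$voxel <- wm_idx
  gm$voxel <- gm_idx
  structure(list(
    fractions = fractions,
    wm_params = wm,
    gm_params = gm,
    csf_params = sample_tissue_params("CSF", 1L),
    seed = as.integer(seed)
  ), class = "sc_phantom")
}

#' Default spinal cord phantom
#'
#' Convenience wrapper generating the default 16 x 16 x \code{nslices}
#' geometry and drawing tissue parameters.
#'
#' @param seed integer seed.
#' @param nslices number of slices (default 40, i.e. 200 mm coverage).
#' @return an \code{sc_phantom}.
#' @export
default_phantom <- function(seed = 1L, nslices = 40L) {
  build_phantom(generate_geometry(nslices = nslices, seed = seed), seed = seed)
}

#' @export
print.sc_phantom <- function(x, ...) {
  print(x$fractions)
  cat("  WM draws:", nrow(x$wm_params), " GM draws:", nrow(x$gm_params),
      " seed:", x$seed, "\n")
  invisible(x)
}
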