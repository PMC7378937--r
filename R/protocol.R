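#' Off-resonance pulse train description
#'
#' A saturation train of identical sinc-Gaussian pulses applied before the
#' readout in magnetisation-transfer-weighted measurements.
#'
#' @param theta_deg nominal on-resonance flip angle of each pulse, degrees.
#' @param delta_f_khz offset frequency of the pulses, kHz.
#' @param post_delay_ms delay between end of the train and the readout, ms.
#' @param n_pulses number of pulses (default 25).
#' @param pulse_ms single pulse duration, ms (default 15).
#' @param gap_ms inter-pulse delay, ms (default 15).
#' @param bw_hz pulse bandwidth, Hz (default 122).
#' @return object of class \code{pulse_train_spec}.
#' @export
pulse_train_spec <- function(theta_deg, delta_f_khz, post_delay_ms,
                             n_pulses = 25L, pulse_ms = 15, gap_ms = 15,
                             bw_hz = 122) {
  stopifnot(n_pulses >= 1, pulse_ms >= 0, gap_ms >= 0, theta_deg >= 0)
  structure(list(theta_deg = theta_deg, delta_f_khz = delta_f_khz,
                 post_delay_ms = post_delay_ms, n_pulses = as.integer(n_pulses),
                 pulse_ms = pulse_ms, gap_ms = gap_ms, bw_hz = bw_hz),
            class = "pulse_train_spec")
}

# the 11 (theta, delta_f) saturation settings per repetition; the first entry
# (theta = 0) is the unsaturated reference
.qmt_theta_deg <- c(0, 426, 433, 524, 1429, 1438, 1440, 1459, 1460, 1462, 1465)
.qmt_delta_khz <- c(0.00, 1.07, 1.00, 2.70, 14.13, 3.78, 13.60, 1.05, 1.01,
                    3.76, 8.39)
.qmt_delays_ms <- c(17, 95, 173, 251)

#' Approximately uniform gradient directions
#'
#' Unit vectors spread over the sphere by minimising an electrostatic
#' repulsion energy with antipodal symmetry (charges interact with both a
#' point and its antipode, the symmetry relevant to diffusion encoding).
#' Deterministic given \code{(n, seed)}.
#'
#' @param n number of directions (>= 1).
#' @param seed integer seed for the initial configuration.
#' @return \code{n x 3} matrix of unit row vectors (unit norm to 1e-12).
#' @export
gradient_directions <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  init <- withr::with_seed(as.integer(seed), matrix(stats::rnorm(3 * n), ncol = 3))
  init <- init / sqrt(rowSums(init^2))
  if (n == 1L) return(init)
  to_angles <- function(v) c(acos(pmin(pmax(v[, 3], -1), 1)), atan2(v[, 2], v[, 1]))
  from_angles <- function(a) {
    th <- a[seq_len(n)]; ph <- a[n + seq_len(n)]
    cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  ut <- upper.tri(matrix(0, n, n))
  energy <- function(a) {
    v <- from_angles(a)
    cij <- tcrossprod(v)[ut] # |xi - xj|^2 = 2 - 2 cij, |xi + xj|^2 = 2 + 2 cij
    sum(1 / pmax(sqrt(2 - 2 * cij), 1e-9) + 1 / pmax(sqrt(2 + 2 * cij), 1e-9))
  }
  fit <- stats::optim(to_angles(init), energy, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-12))
  v <- from_angles(fit$par)
  v / sqrt(rowSums(v^2))
}

.protocol_columns <- c("modality", "TE", "TI", "b", "gx", "gy", "gz",
                       "theta_deg", "delta_f_khz", "train_delay_ms")

#' The default unified 131-measurement protocol
#'
#' Multi-contrast acquisition with a shared spin-echo EPI readout and long TR
#' (no TR weighting is modelled):
#' \itemize{
#'   \item DW block (68 rows, TE = 72 ms): 8 b = 0 measurements plus shells
#'     b = \{300, 1000, 2000, 2800\} s/mm^2 with \{4, 10, 18, 28\} directions;
#'   \item qMT block (44 rows, TE = 24 ms): 4 repetitions of 11
#'     (flip angle, offset) saturation settings, each repetition with a
#'     different post-train delay \{17, 95, 173, 251\} ms; the theta = 0 entry
#'     is the unsaturated reference;
#'   \item IR block (12 rows, TE = 24 ms): inversion times linearly spaced in
#'     [200, 2300] ms;
#'   \item mTE block (7 rows): echo times \{25, 40, 55, 70, 85, 100, 200\} ms.
#' }
#'
#' @param dir_seed seed for the per-shell gradient direction sets.
#' @return object of class \code{qmri_protocol}: a data frame with one row per
#'   measurement and columns \code{modality, TE, TI, b, gx, gy, gz, theta_deg,
#'   delta_f_khz, train_delay_ms}; fields irrelevant to a modality are NA.
#' @export
default_protocol <- function(dir_seed = 20L) {
  shells <- c(300, 1000, 2000, 2800)
  ndirs <- c(4L, 10L, 18L, 28L)
  dw <- data.frame(modality = "DW", TE = 72, TI = NA_real_,
                   b = rep(0, 8), gx = 0, gy = 0, gz = 0,
                   theta_deg = NA_real_, delta_f_khz = NA_real_,
                   train_delay_ms = NA_real_)
  for (s in seq_along(shells)) {
    g <- gradient_directions(ndirs[s], seed = dir_seed + s)
    dw <- rbind(dw, data.frame(modality = "DW", TE = 72, TI = NA_real_,
                               b = shells[s], gx = g[, 1], gy = g[, 2],
                               gz = g[, 3], theta_deg = NA_real_,
                               delta_f_khz = NA_real_,
                               train_delay_ms = NA_real_))
  }
  qmt <- do.call(rbind, lapply(.qmt_delays_ms, function(d) {
    data.frame(modality = "qMT", TE = 24, TI = NA_real_, b = NA_real_,
               gx = NA_real_, gy = NA_real_, gz = NA_real_,
               theta_deg = .qmt_theta_deg, delta_f_khz = .qmt_delta_khz,
               train_delay_ms = d)
  }))
  ir <- data.frame(modality = "IR", TE = 24,
                   TI = seq(200, 2300, length.out = 12), b = NA_real_,
                   gx = NA_real_, gy = NA_real_, gz = NA_real_,
                   theta_deg = NA_real_, delta_f_khz = NA_real_,
                   train_delay_ms = NA_real_)
  mte <- data.frame(modality = "mTE", TE = c(25, 40, 55, 70, 85, 100, 200),
                    TI = NA_real_, b = NA_real_, gx = NA_real_, gy = NA_real_,
                    gz = NA_real_, theta_deg = NA_real_,
                    delta_f_khz = NA_real_, train_delay_ms = NA_real_)
  p <- rbind(dw, qmt, ir, mte)
  rownames(p) <- NULL
  class(p) <- c("qmri_protocol", "data.frame")
  p
}

#' Row indices of a modality block
#'
#' @param protocol a \code{qmri_protocol}.
#' @param modality one of \code{"DW"}, \code{"qMT"}, \code{"IR"}, \code{"mTE"}.
#' @return integer vector of row indices.
#' @export
modality_rows <- function(protocol, modality) {
  modality <- match.arg(modality, c("DW", "qMT", "IR", "mTE"))
  which(protocol$modality == modality)
}

#' @export
print.qmri_protocol <- function(x, ...) {
  tab <- table(factor(x$modality, levels = c("DW", "qMT", "IR", "mTE")))
  cat("Unified multi-contrast protocol:", nrow(x), "measurements (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  invisible(x)
}

#' Serialize / deserialize a protocol as JSON
#'
#' The JSON round trip is lossless (numeric values are written in full
#' precision).
#'
#' @param protocol a \code{qmri_protocol}.
#' @param path file path.
#' @return \code{protocol_from_json} returns a \code{qmri_protocol}.
#' @export
protocol_to_json <- function(protocol, path) {
  jsonlite::write_json(as.data.frame(protocol), path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname protocol_to_json
#' @export
protocol_from_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  for (col in setdiff(.protocol_columns, "modality")) {
    p[[col]] <- as.numeric(p[[col]])
  }
  p <- p[, .protocol_columns]
  class(p) <- c("qmri_protocol", "data.frame")
  p
}

#' Export / import the DW block as FSL-style bval/bvec text files
#'
#' bvals are written as one space-separated row; bvecs as three rows (x, y, z
#' components). On import, non-zero b vectors are required to have unit norm
#' within 1e-3.
#'
#' @param protocol a \code{qmri_protocol}.
#' @param bval_path,bvec_path file paths.
#' @return \code{read_bvalbvec} returns a list with \code{bvals} (numeric
#'   vector) and \code{bvecs} (n x 3 matrix).
#' @export
write_bvalbvec <- function(protocol, bval_path, bvec_path) {
  rows <- modality_rows(protocol, "DW")
  b <- protocol$b[rows]
  g <- as.matrix(protocol[rows, c("gx", "gy", "gz")])
  g[b == 0, ] <- 0
  writeLines(paste(format(b, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(g), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' @rdname write_bvalbvec
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  b <- scan(bval_path, quiet = TRUE)
  g <- t(as.matrix(utils::read.table(bvec_path)))
  if (nrow(g) != length(b)) stop("bval/bvec length mismatch")
  nrm <- sqrt(rowSums(g^2))
  if (any(b > 0 & abs(nrm - 1) > 1e-3)) {
    stop("non-unit gradient direction in bvec file")
  }
  list(bvals = b, bvecs = g)
}
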