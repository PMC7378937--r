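# protocol-derived acquisition tables used across fitting tests
.dw_tables <- function(p = fx_protocol()) {
  rows <- modality_rows(p, "DW")
  b <- p$b[rows]
  g <- as.matrix(p[rows, c("gx", "gy", "gz")])
  g[b == 0, ] <- 0
  list(b = b, g = g)
}

.one_voxel <- function(signal) array(signal, c(1, 1, 1, length(signal)))
.one_mask <- array(TRUE, c(1, 1, 1))

test_that("kurtosis fit recovers single-tensor metrics exactly and flags
           non-Gaussian mixtures", {
  dw <- .dw_tables()
  wm <- fx_wm_means()
  S <- 0.25 * diffusion_attenuation(dw$b, dw$g, wm$AD, wm$RD)
  fit <- fit_dki(.one_voxel(S), dw$b, dw$g, .one_mask)
  md_true <- (wm$AD + 2 * wm$RD) / 3
  ev <- c(wm$AD, wm$RD, wm$RD)
  fa_true <- sqrt(1.5 * sum((ev - md_true)^2) / sum(ev^2))
  expect_equal(fit$MD[1], md_true, tolerance = 1e-6)
  expect_equal(fit$FA[1], fa_true, tolerance = 1e-6)
  expect_lt(abs(fit$MK[1]), 0.02) # Gaussian signal has zero kurtosis
  # isotropic tensor: FA ~ 0
  Siso <- 0.25 * diffusion_attenuation(dw$b, dw$g, 1.0, 1.0)
  expect_lt(fit_dki(.one_voxel(Siso), dw$b, dw$g, .one_mask)$FA[1], 1e-3)
  # 50/50 WM/CSF bi-Gaussian mixture has positive kurtosis; cross-check the
  # directional kurtosis against a numeric cumulant oracle along z
  csf <- fx_csf()
  Smix <- 0.5 * 0.25 * diffusion_attenuation(dw$b, dw$g, wm$AD, wm$RD) +
    0.5 * 0.25 * diffusion_attenuation(dw$b, dw$g, csf$AD, csf$RD)
  mkfit <- fit_dki(.one_voxel(Smix), dw$b, dw$g, .one_mask)
  expect_gt(mkfit$MK[1], 0)
  # cumulant oracle: the apparent kurtosis of an equal-fraction bi-Gaussian
  # mixture along any axis is 3 Var(D)/mean(D)^2 > 0 (radial direction here)
  d <- c(wm$RD, csf$RD)
  k_oracle <- 3 * mean((d - mean(d))^2) / mean(d)^2
  expect_gt(k_oracle, 0)
  expect_gt(mkfit$MK[1], 0.1 * k_oracle)
  expect_error(fit_dki(.one_voxel(S[1:10]), dw$b[1:10], dw$g[1:10, ],
                       .one_mask), "22")
})

test_that("relaxometry fits recover exact inputs and bound their domains", {
  p <- fx_protocol()
  TEs <- p$TE[modality_rows(p, "mTE")]
  fit <- fit_t2(.one_voxel(0.7 * exp(-TEs / 70)), TEs, .one_mask)
  expect_equal(fit$T2[1], 70, tolerance = 1e-6)
  fit_csf <- fit_t2(.one_voxel(1.0 * exp(-TEs / 800)), TEs, .one_mask)
  expect_equal(fit_csf$T2[1], 800, tolerance = 1e-3)
  # rising signal is not a decay: flagged invalid, no error
  bad <- fit_t2(.one_voxel(seq(0.1, 0.7, length.out = 7)), TEs, .one_mask)
  expect_false(bad$valid[1])
  expect_error(fit_t2(.one_voxel(c(1, 2)), c(10, 20), .one_mask), "3")
  TIs <- p$TI[modality_rows(p, "IR")]
  f1 <- fit_t1_ir(.one_voxel(0.5 * abs(1 - 2 * exp(-TIs / 1000))), TIs,
                  .one_mask)
  expect_equal(f1$T1[1], 1000, tolerance = 1e-4)
  # all TIs below the null point of CSF: harder conditioning, still < 2%
  f4 <- fit_t1_ir(.one_voxel(0.9 * abs(1 - 2 * exp(-TIs / 4000))), TIs,
                  .one_mask)
  expect_equal(f4$T1[1], 4000, tolerance = 0.02)
  expect_false(fit_t1_ir(.one_voxel(rep(0, 12)), TIs, .one_mask)$valid[1])
})

test_that("relaxometry is robust to Rician noise after floor correction", {
  p <- fx_protocol()
  TEs <- p$TE[modality_rows(p, "mTE")]
  n <- 60
  sigma <- 0.25 / 20 # SNR 20 on the b = 0-scale reference signal
  wm <- sample_tissue_params("WM", n, seed = 3)
  truth <- outer(wm$rho, rep(1, 7)) * exp(-outer(rep(1, n), TEs) /
                                            outer(wm$T2, rep(1, 7)))
  noisy <- add_rician_noise(array(truth, c(n, 1, 1, 7)), sigma, seed = 4)
  corrected <- floor_correct(noisy, sigma)
  fit <- fit_t2(corrected, TEs, array(TRUE, c(n, 1, 1)))
  expect_lt(abs(median(fit$T2 / wm$T2, na.rm = TRUE) - 1), 0.05)
})

test_that("two-pool qMT fit is an inverse of the forward model", {
  p <- fx_protocol()
  qrows <- modality_rows(p, "qMT")
  qp <- p[qrows, ]
  for (tis in c("WM", "GM")) {
    tp <- as.data.frame(as.list(tissue_reference_values(tis)))
    sig <- vapply(seq_len(nrow(qp)), function(i)
      synthesize_tissue_signal(qp[i, ], tp), numeric(1))
    fit <- fit_qmt(.one_voxel(sig), p, array(tp$T1, c(1, 1, 1)),
                   array(tp$T2, c(1, 1, 1)), .one_mask)
    expect_equal(fit$BPF[1], tp$BPF, tolerance = 0.02)
    expect_equal(fit$k[1], tp$k, tolerance = 0.02)
    expect_equal(fit$T2B[1], tp$T2B, tolerance = 0.02)
  }
  # CSF: no bound pool; fitted BPF collapses to (near) zero
  csf <- fx_csf()
  sig_csf <- vapply(seq_len(nrow(qp)), function(i)
    synthesize_tissue_signal(qp[i, ], csf), numeric(1))
  fit0 <- fit_qmt(.one_voxel(sig_csf), p, array(csf$T1, c(1, 1, 1)),
                  array(csf$T2, c(1, 1, 1)), .one_mask)
  expect_lt(fit0$BPF[1], 0.01)
  # a missing unsaturated reference is a usage error
  p_noref <- p
  ref_idx <- qrows[qp$theta_deg == 0]
  p_noref$theta_deg[ref_idx] <- 1
  p_noref$delta_f_khz[ref_idx] <- 1
  expect_error(fit_qmt(.one_voxel(sig_csf), p_noref,
                       array(1000, c(1, 1, 1)), array(70, c(1, 1, 1)),
                       .one_mask), "reference")
})

test_that("map dispersion in pure tissue does not increase after joint
           denoising", {
  ph <- fx_phantom_small()
  p <- fx_protocol()
  fr <- ph$fractions
  clean <- fx_clean_small()
  sigma <- sigma_from_snr(clean, ph, p, 10)
  noisy <- add_gaussian_noise(clean, sigma, 77)
  den <- denoise_slicewise(noisy, fr$cord_mask, p,
                           denoise_strategy("joint_all"))$denoised
  TEs <- p$TE[modality_rows(p, "mTE")]
  wm_mask <- fr$vWM >= 0.99
  t2_raw <- fit_t2(noisy[, , , modality_rows(p, "mTE"), drop = FALSE], TEs,
                   wm_mask)
  t2_den <- fit_t2(den[, , , modality_rows(p, "mTE"), drop = FALSE], TEs,
                   wm_mask)
  iqr <- function(x) diff(quantile(x, c(0.25, 0.75), na.rm = TRUE,
                                   names = FALSE))
  expect_lte(iqr(t2_den$T2[wm_mask]), iqr(t2_raw$T2[wm_mask]))
})
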