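test_that("closed-form signal factors are exact", {
  # diffusion: axial and radial limits with WM means
  expect_equal(diffusion_attenuation(0, c(1, 0, 0), 2.1, 0.4), 1)
  expect_equal(diffusion_attenuation(1000, c(0, 0, 1), 2.1, 0.4), exp(-2.1))
  expect_equal(diffusion_attenuation(1000, c(1, 0, 0), 2.1, 0.4), exp(-0.4))
  expect_error(diffusion_attenuation(-5, c(0, 0, 1), 2.1, 0.4), "negative")
  # inversion recovery: null point, asymptote, closed form
  expect_equal(ir_factor(1000 * log(2), 1000), 0)
  expect_equal(ir_factor(1e9, 1000), 1)
  expect_equal(ir_factor(200, 1000), abs(1 - 2 * exp(-0.2)))
  expect_error(ir_factor(200, -1), "T1")
  # echo time factor
  expect_equal(te_factor(0, 70), 1)
  expect_equal(te_factor(70, 70), exp(-1))
  expect_error(te_factor(10, 0), "T2")
})

test_that("super-Lorentzian lineshape is symmetric, positive and matches a
           fine-grid quadrature oracle", {
  expect_equal(super_lorentzian(2.7, 12), super_lorentzian(-2.7, 12))
  expect_true(all(super_lorentzian(c(1, 3, 8, 14), 12) > 0))
  # brute-force trapezoid oracle at 1e6 points
  phi <- seq(0, pi / 2, length.out = 1e6)
  T2B <- 12e-6
  u <- 3 * cos(phi)^2 - 1
  f <- sin(phi) * sqrt(2 / pi) * (T2B / abs(u)) *
    exp(-2 * (2 * pi * 2700 * T2B / u)^2)
  f[!is.finite(f)] <- 0
  oracle <- sum((f[-1] + f[-length(f)]) / 2) * diff(phi[1:2])
  expect_equal(super_lorentzian(2.7, 12), oracle, tolerance = 1e-6)
  expect_error(super_lorentzian(2.7, -1), "T2B")
})

test_that("MT weighting behaves physically and converges under step
           refinement", {
  wm <- fx_wm_means()
  # no saturation -> exactly 1
  expect_identical(simulate_mt_weighting(pulse_train_spec(0, 0, 17), wm), 1)
  # stronger saturation at comparable offset depresses the free pool more
  w_hi <- simulate_mt_weighting(pulse_train_spec(1465, 1.01, 17), wm)
  w_lo <- simulate_mt_weighting(pulse_train_spec(426, 1.07, 17), wm)
  expect_lt(w_hi, w_lo)
  expect_gt(w_hi, 0)
  expect_lte(w_lo, 1)
  # longer post-train delay lets the free pool recover
  w_late <- simulate_mt_weighting(pulse_train_spec(1465, 1.01, 251), wm)
  expect_gt(w_late, w_hi)
  # halving the integration step changes w by < 1e-4 at every saturation
  # setting of the default protocol (Cauchy convergence of the integrator)
  p <- fx_protocol()
  qmt <- unique(p[p$modality == "qMT" & p$theta_deg > 0,
                  c("theta_deg", "delta_f_khz")])
  for (i in seq_len(nrow(qmt))) {
    tr <- pulse_train_spec(qmt$theta_deg[i], qmt$delta_f_khz[i], 17)
    expect_lt(abs(simulate_mt_weighting(tr, wm, n_seg = 64) -
                    simulate_mt_weighting(tr, wm, n_seg = 128)), 1e-4)
  }
  expect_error(simulate_mt_weighting(pulse_train_spec(400, 1, 17),
                                     within(wm, BPF <- 1)), "BPF")
})

test_that("tissue and voxel signals follow the multiplicative model", {
  p <- fx_protocol()
  wm <- fx_wm_means()
  gm <- fx_gm_means()
  csf <- fx_csf()
  mte25 <- p[p$modality == "mTE" & p$TE == 25, ]
  expect_equal(synthesize_tissue_signal(mte25, wm), 0.70 * exp(-25 / 70))
  b0 <- p[p$modality == "DW" & p$b == 0, ][1, ]
  expect_equal(synthesize_tissue_signal(b0, wm), 0.70 * exp(-72 / 70))
  ir_null <- p[p$modality == "IR", ][1, ]
  ir_null$TI <- wm$T1 * log(2)
  expect_equal(synthesize_tissue_signal(ir_null, wm), 0)
  # partial volume: pure-tissue limits and linearity
  s <- synthesize_voxel(mte25, c(1, 0, 0), wm, gm, csf)
  expect_equal(s$S_TOT, s$S_WM)
  s50 <- synthesize_voxel(mte25, c(0.5, 0.5, 0), wm, gm, csf)
  expect_equal(s50$S_TOT, (s50$S_WM + s50$S_GM) / 2)
  expect_error(synthesize_voxel(mte25, c(0.5, 0.2, 0.2), wm, gm, csf),
               "sum to 1")
  # pure CSF voxel through a saturated qMT measurement: no bound pool, only
  # direct saturation, so the weighting stays close to (and below) 1
  qsat <- p[p$modality == "qMT" & p$theta_deg > 0, ][1, ]
  scsf <- synthesize_voxel(qsat, c(0, 0, 1), wm, gm, csf)
  expect_lte(scsf$S_TOT, csf$rho * te_factor(qsat$TE, csf$T2))
  expect_gt(scsf$S_TOT, 0.95 * csf$rho * te_factor(qsat$TE, csf$T2))
})

test_that("vectorised dataset synthesis matches the per-voxel reference and
           is non-negative", {
  ph <- fx_phantom_small()
  p <- fx_protocol()
  data <- fx_clean_small()
  expect_true(all(data >= 0))
  expect_equal(dim(data), c(ph$fractions$grid_shape, 131L))
  # brute-force per-voxel oracle on a handful of voxels spanning all blocks
  fr <- ph$fractions
  vox <- c(which(fr$cord_mask)[c(1, 11, 30)], which(fr$vCSF == 1)[1])
  meas <- c(1, 9, 30, 69, 70, 112, 113, 125, 131) # b0, shells, qMT, IR, mTE
  for (v in vox) {
    coord <- arrayInd(v, fr$grid_shape)
    wm <- ph$wm_params[match(v, ph$wm_params$voxel), ]
    gm <- ph$gm_params[match(v, ph$gm_params$voxel), ]
    if (is.na(wm$rho[1])) wm <- fx_wm_means()
    if (is.na(gm$rho[1])) gm <- fx_gm_means()
    for (m in meas) {
      s <- synthesize_voxel(p[m, ],
                            c(fr$vWM[v], fr$vGM[v], fr$vCSF[v]),
                            wm, gm, ph$csf_params)
      expect_equal(data[coord[1], coord[2], coord[3], m], s$S_TOT,
                   tolerance = 1e-10)
    }
  }
})

test_that("background zeroing masks everything outside the dilated cord", {
  ph <- fx_phantom_small()
  p <- fx_protocol()
  d <- synthesize_dataset(ph, p[p$modality == "mTE", ], zero_background = TRUE)
  far <- d[1, 1, 1, ]
  expect_true(all(far == 0))
  msk <- ph$fractions$cord_mask
  expect_true(all(d[, , , 1][msk] > 0))
})
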