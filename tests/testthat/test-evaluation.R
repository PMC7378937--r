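.map3 <- function(x) array(x, c(length(x), 1, 1))
.mask3 <- function(n) array(TRUE, c(n, 1, 1))

test_that("relative error statistics recover closed forms", {
  truth <- array(runif(200, 0.5, 1.5), c(10, 5, 2, 2))
  mask <- array(TRUE, c(10, 5, 2))
  expect_equal(unname(error_summary(
    relative_error(truth, truth, mask))[, c("median_eps", "iqr_eps")]),
    data.frame(0, 0), ignore_attr = TRUE)
  s <- error_summary(relative_error(1.1 * truth, truth, mask))
  expect_equal(s$median_eps, 10)
  expect_equal(s$iqr_eps, 0, tolerance = 1e-10)
  # pure Gaussian noise with sigma/truth = 0.10: IQR -> 13.49%
  big <- array(1, c(200, 200, 1, 4))
  noisy <- add_gaussian_noise(big, 0.1, seed = 13)
  s2 <- error_summary(relative_error(noisy, big, array(TRUE, c(200, 200, 1))))
  expect_equal(s2$iqr_eps, 100 * 0.1 * 2 * qnorm(0.75), tolerance = 0.02)
  bad <- truth
  bad[1] <- 0
  expect_error(relative_error(truth, bad, mask), "> 0")
})

test_that("coefficient of variation follows its quantile convention and is
           scale invariant", {
  expect_equal(cov_percent(.map3(rep(4, 50)), .mask3(50)), 0)
  expect_equal(cov_percent(.map3(1:5), .mask3(5)), 100 * 2 / 3)
  x <- .map3(rexp(100) + 1)
  expect_equal(cov_percent(3.7 * x, .mask3(100)),
               cov_percent(x, .mask3(100)))
  expect_error(cov_percent(.map3(c(-1, 0, 1)), .mask3(3)), "median")
})

test_that("scan-rescan variability matches its closed form", {
  m1 <- .map3(rep(2, 100))
  expect_equal(scan_rescan_variability(m1, m1, .mask3(100)), 0)
  expect_equal(scan_rescan_variability(m1, m1 + 0.5, .mask3(100)), 0)
  # independent Gaussian perturbations sd s on both maps around mean mu:
  # variability -> 100 * 1.349 * s * sqrt(2) / mu
  mu <- 5; s <- 0.25
  withr::with_seed(8, {
    a <- .map3(mu + rnorm(2e5, 0, s))
    b <- .map3(mu + rnorm(2e5, 0, s))
  })
  expect_equal(scan_rescan_variability(a, b, .mask3(2e5)),
               100 * 2 * qnorm(0.75) * s * sqrt(2) / mu, tolerance = 0.02)
})

test_that("contrast-to-noise ratio matches the IQR-based normal estimate", {
  wm_mask <- array(c(rep(TRUE, 5e4), rep(FALSE, 5e4)), c(1e5, 1, 1))
  gm_mask <- !wm_mask
  withr::with_seed(9, {
    map <- .map3(c(rnorm(5e4, 1, 1), rnorm(5e4, 2, 1)))
  })
  expect_equal(cnr(map, wm_mask, gm_mask), 1 / sqrt(2), tolerance = 0.03)
  # same distribution in both tissues: CNR ~ 0; widening the gap raises it
  withr::with_seed(10, same <- .map3(rnorm(1e5, 1, 1)))
  expect_lt(cnr(same, wm_mask, gm_mask), 0.05)
  wide <- map
  wide[gm_mask] <- wide[gm_mask] + 3
  expect_gt(cnr(wide, wm_mask, gm_mask), cnr(map, wm_mask, gm_mask))
  # degenerate all-constant case is defined as zero
  expect_message(z <- cnr(.map3(rep(1, 10)), .mask3(10) & c(TRUE, rep(FALSE, 9)),
                          .mask3(10) & c(FALSE, TRUE, rep(FALSE, 8))),
                 "degenerate")
  expect_equal(z, 0)
})

test_that("cord SNR estimation agrees with the ground-truth oracle", {
  ph <- fx_phantom_small()
  p <- fx_protocol()
  fr <- ph$fractions
  clean <- fx_clean_small()
  sigma <- sigma_from_snr(clean, ph, p, 20)
  noisy <- add_gaussian_noise(clean, sigma, 41)
  dw_run <- denoise_slicewise(noisy, fr$cord_mask, p,
                              denoise_strategy("individual"))
  est <- estimate_snr(noisy, p, dw_run$sigma_maps[["DW"]], fr$cord_mask)
  b0 <- which(p$modality == "DW" & p$b == 0)
  oracle <- mean(apply(clean[, , , b0], 1:3, mean)[fr$cord_mask]) / sigma
  expect_equal(est, oracle, tolerance = 0.15)
  # doubling sigma halves the estimate; non-DW rows are irrelevant
  expect_equal(estimate_snr(noisy, p, 2 * dw_run$sigma_maps[["DW"]],
                            fr$cord_mask), est / 2)
  noisy2 <- noisy
  noisy2[, , , modality_rows(p, "qMT")] <- 0
  expect_equal(estimate_snr(noisy2, p, dw_run$sigma_maps[["DW"]],
                            fr$cord_mask), est)
})

test_that("residual diagnostics separate healthy from over-truncated runs", {
  ph <- fx_phantom_small()
  p <- fx_protocol()
  fr <- ph$fractions
  clean <- fx_clean_small()
  sigma <- sigma_from_snr(clean, ph, p, 20)
  noisy <- add_gaussian_noise(clean, sigma, 42)
  run <- denoise_slicewise(noisy, fr$cord_mask, p,
                           denoise_strategy("joint_all"))
  d <- residual_diagnostics(noisy, run$denoised, run$sigma_maps[["all"]],
                            fr$cord_mask)
  expect_lt(abs(d$mean), 0.05)
  expect_gt(d$sd, 0.8)
  expect_lt(d$sd, 1.1)
  # degenerate case: no denoising at all
  d0 <- residual_diagnostics(noisy, noisy, sigma, fr$cord_mask)
  expect_equal(d0$sd, 0)
  # deliberately over-truncated reconstruction (rank 1 per slice): residuals
  # contain signal, inflating their normalised spread
  hard <- noisy
  for (z in seq_len(fr$grid_shape[3])) {
    idx <- which(fr$cord_mask[, , z])
    flat <- matrix(hard[, , z, ], nrow = prod(fr$grid_shape[1:2]))
    A <- t(flat[idx, ])
    sv <- svd(A)
    flat[idx, ] <- t(sv$u[, 1, drop = FALSE] %*%
                       (sv$d[1] * t(sv$v[, 1, drop = FALSE])))
    hard[, , z, ] <- array(flat, c(fr$grid_shape[1:2], 1, 131))
  }
  dh <- residual_diagnostics(noisy, hard, run$sigma_maps[["all"]],
                             fr$cord_mask)
  expect_gt(dh$sd, 1.1)
})

test_that("noise-level trend report aggregates runs and flags unstable
           small-block estimates", {
  expect_equal(nrow(sigma_trend_report(list())), 0)
  ph <- fx_phantom_small()
  p <- fx_protocol()
  fr <- ph$fractions
  clean <- fx_clean_small()
  sigma <- sigma_from_snr(clean, ph, p, 15)
  noisy <- add_gaussian_noise(clean, sigma, 43)
  ind <- denoise_slicewise(noisy, fr$cord_mask, p,
                           denoise_strategy("individual"))
  joint <- denoise_slicewise(noisy, fr$cord_mask, p,
                             denoise_strategy("joint_all"))
  rep <- sigma_trend_report(list(ind, joint))
  expect_true(all(c("run", "slice", "set", "sigma_hat") %in% names(rep)))
  # homoscedastic data: DW-alone and joint estimates within 10% of truth
  expect_lt(abs(median(rep$sigma_hat[rep$set == "DW"]) / sigma - 1), 0.10)
  expect_lt(abs(median(rep$sigma_hat[rep$set == "all"]) / sigma - 1), 0.10)
})
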