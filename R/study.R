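#' Configuration of the in-silico denoising study
#'
#' @param snrs SNR grid (referenced to the white matter b = 0 signal);
#'   default \{10, 15, 20, 25, 30, 35, 40\}.
#' @param models noise models, subset of \code{c("gaussian", "rician")}.
#' @param strategies character vector naming the denoising strategies to run:
#'   any of \code{"individual"}, \code{"joint_all"}, \code{"dwi+mte"},
#'   \code{"dwi+ir"}, \code{"dwi+qmt"}.
#' @param n_realizations noise realizations per (SNR, model) cell (>= 1).
#' @param base_seed integer base seed; every cell derives its own seed.
#' @param nslices phantom slices.
#' @param outdir optional output directory for checkpoint/result files; NULL
#'   keeps everything in memory.
#' @return object of class \code{study_config}.
#' @export
study_config <- function(snrs = c(10, 15, 20, 25, 30, 35, 40),
                         models = c("gaussian", "rician"),
                         strategies = c("individual", "joint_all",
                                        "dwi+mte", "dwi+ir", "dwi+qmt"),
                         n_realizations = 100L, base_seed = 1L,
                         nslices = 40L, outdir = NULL) {
  stopifnot(all(snrs > 0), n_realizations >= 1)
  models <- match.arg(models, several.ok = TRUE)
  strategies <- match.arg(strategies,
                          c("individual", "joint_all", "dwi+mte", "dwi+ir",
                            "dwi+qmt"), several.ok = TRUE)
  structure(list(snrs = snrs, models = models, strategies = strategies,
                 n_realizations = as.integer(n_realizations),
                 base_seed = as.integer(base_seed),
                 nslices = as.integer(nslices), outdir = outdir),
            class = "study_config")
}

.strategy_from_label <- function(label) {
  switch(label,
    individual = denoise_strategy("individual"),
    joint_all = denoise_strategy("joint_all"),
    `dwi+mte` = denoise_strategy("joint_dwi_plus", "mTE"),
    `dwi+ir` = denoise_strategy("joint_dwi_plus", "IR"),
    `dwi+qmt` = denoise_strategy("joint_dwi_plus", "qMT"),
    stop("unknown strategy label: ", label))
}

# modalities whose error statistics a strategy can report (those it denoises)
.strategy_modalities <- function(label) {
  switch(label,
    individual = c("DW", "qMT", "IR", "mTE"),
    joint_all = c("DW", "qMT", "IR", "mTE"),
    `dwi+mte` = c("DW", "mTE"),
    `dwi+ir` = c("DW", "IR"),
    `dwi+qmt` = c("DW", "qMT"))
}

#' Run the in-silico denoising study
#'
#' Builds the phantom, synthesizes the noise-free 131-measurement dataset,
#' then loops over the (SNR x noise model x realization) grid: corrupts the
#' data, applies every configured denoising strategy slice-wise, pools
#' percentage relative errors per modality, and collects singular-value
#' spectra for one representative slice plus residual and noise-level
#' diagnostics. Fully reproducible from \code{base_seed}; per-(SNR, model)
#' result tables are checkpointed to \code{outdir} (if set) and skipped on
#' resume.
#'
#' @param config a \code{study_config}.
#' @param phantom optionally, a pre-built \code{sc_phantom} (defaults to
#'   \code{default_phantom(config$base_seed, config$nslices)}).
#' @param verbose print progress.
#' @return list with \code{errors} (tidy data frame: modality, strategy,
#'   model, snr, median_eps, iqr_eps, n_realizations), \code{sv_spectra}
#'   (squared singular values of the representative slice: noise-free, noisy
#'   and denoised at each SNR), \code{residuals} (normalised-residual
#'   diagnostics per cell for the joint strategy), \code{sigma_log}
#'   (noise-level estimates of every MP-PCA call) and \code{sigma_true}.
#' @export
run_insilico_study <- function(config, phantom = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(config$outdir) &&
      !dir.exists(config$outdir) &&
      !dir.create(config$outdir, recursive = TRUE)) {
    stop("cannot create output directory: ", config$outdir)
  }
  protocol <- default_protocol()
  if (is.null(phantom)) {
    phantom <- default_phantom(config$base_seed, config$nslices)
  }
  mask <- phantom$fractions$cord_mask
  clean <- synthesize_dataset(phantom, protocol)
  # representative slice: the one with the median cord voxel count
  counts <- apply(mask, 3, sum)
  rep_slice <- order(counts)[ceiling(length(counts) / 2)]
  rep_idx <- which(mask[, , rep_slice])
  rep_matrix <- function(x) t(matrix(x[, , rep_slice, ],
                                     nrow = prod(dim(x)[1:2]))[rep_idx, ])
  sv_spectra <- list(noise_free = sv_spectrum(rep_matrix(clean)))
  sigma_true <- vapply(config$snrs, function(s)
    sigma_from_snr(clean, phantom, protocol, s), numeric(1))
  names(sigma_true) <- as.character(config$snrs)
  mods <- c("DW", "qMT", "IR", "mTE")
  rowsets <- lapply(mods, modality_rows, protocol = protocol)
  names(rowsets) <- mods
  errors <- NULL
  residuals <- NULL
  sigma_log <- NULL
  for (model in config$models) {
    for (si in seq_along(config$snrs)) {
      snr <- config$snrs[si]
      ck <- if (!is.null(config$outdir)) {
        file.path(config$outdir, sprintf("errors_%s_snr%g.csv", model, snr))
      } else NULL
      if (!is.null(ck) && file.exists(ck)) {
        errors <- rbind(errors, utils::read.csv(ck))
        next
      }
      if (verbose) message(sprintf("model=%s snr=%g", model, snr))
      eps <- list() # strategy|modality -> accumulated error vectors
      for (r in seq_len(config$n_realizations)) {
        seed <- realization_seed(config$base_seed, snr, model, r)
        noisy <- if (model == "gaussian") {
          add_gaussian_noise(clean, sigma_true[si], seed)
        } else {
          add_rician_noise(clean, sigma_true[si], seed)
        }
        for (label in config$strategies) {
          strat <- .strategy_from_label(label)
          run <- denoise_slicewise(noisy, mask, protocol, strat)
          den <- run$denoised
          if (model == "rician") {
            # floor mitigation is part of the magnitude pipeline: correct
            # denoised signals with each set's own noise-level estimate
            for (sname in names(run$sigma_maps)) {
              rows <- strategy_row_sets(strat, protocol)[[sname]]
              sm <- run$sigma_maps[[sname]]
              sm[is.na(sm)] <- 0
              den[, , , rows] <- floor_correct(
                den[, , , rows, drop = FALSE],
                array(rep(sm, length(rows)),
                      c(dim(sm), length(rows))))
            }
          }
          if (r == 1L) sigma_log <- rbind(sigma_log,
            cbind(model = model, snr = snr, strategy = label,
                  realization = r, run$log))
          for (mod in .strategy_modalities(label)) {
            key <- paste(label, mod, sep = "|")
            eps[[key]] <- c(eps[[key]],
              relative_error(den, clean, mask, rowsets[[mod]]))
          }
          if (label == "joint_all" && r == 1L) {
            sig <- run$sigma_maps[["all"]]
            if (all(is.finite(sig[mask])) && all(sig[mask] > 0)) {
              residuals <- rbind(residuals,
                cbind(model = model, snr = snr,
                      residual_diagnostics(noisy, run$denoised, sig, mask)))
            }
            if (si == 1L) {
              sv_spectra[[paste0("noisy_", model, "_snr", snr)]] <-
                sv_spectrum(rep_matrix(noisy))
              sv_spectra[[paste0("denoised_", model, "_snr", snr)]] <-
                sv_spectrum(rep_matrix(run$denoised))
            }
          }
        }
      }
      tab <- do.call(rbind, lapply(names(eps), function(key) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        cbind(data.frame(modality = parts[2], strategy = parts[1],
                         model = model, snr = snr),
              error_summary(eps[[key]], config$n_realizations))
      }))
      if (!is.null(ck)) utils::write.csv(tab, ck, row.names = FALSE)
      errors <- rbind(errors, tab)
    }
  }
  out <- list(errors = errors, sv_spectra = sv_spectra,
              residuals = residuals, sigma_log = sigma_log,
              sigma_true = sigma_true)
  if (!is.null(config$outdir)) {
    utils::write.csv(errors, file.path(config$outdir, "error_summary.csv"),
                     row.names = FALSE)
  }
  out
}

#' Plot accuracy/precision versus SNR
#'
#' Renders the study's error summaries as median and IQR panels per modality
#' (one line per denoising strategy). Requires ggplot2.
#'
#' @param errors the \code{errors} table of \code{run_insilico_study}.
#' @return a ggplot object.
#' @export
plot_error_summary <- function(errors) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  long <- rbind(
    data.frame(errors[c("modality", "strategy", "model", "snr")],
               stat = "median (accuracy)", value = errors$median_eps),
    data.frame(errors[c("modality", "strategy", "model", "snr")],
               stat = "IQR (precision)", value = errors$iqr_eps))
  ggplot2::ggplot(long, ggplot2::aes(x = snr, y = value,
                                     colour = strategy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(stat ~ modality, scales = "free_y") +
    ggplot2::labs(x = "SNR (WM, b = 0)", y = "percentage relative error")
}
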