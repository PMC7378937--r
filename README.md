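# cordqmri

Simulation and evaluation toolkit for **multi-parametric quantitative MRI of
the cervical spinal cord with a unified signal readout**, centred on
**Marchenko–Pastur PCA (MP-PCA) multi-contrast denoising**.

When diffusion-weighted (DW), quantitative magnetisation transfer (qMT),
inversion recovery (IR) and multi-echo-time (mTE) images share one EPI
readout, they share noise statistics — so a slice's full measurement set can
be denoised as one matrix. MP-PCA truncates the singular value decomposition
of an M×N (measurements × voxels) matrix, identifying noise-only singular
values as those following the Marchenko–Pastur law, and returns the denoised
matrix, a noise estimate σ̂ and the retained component count P (rough SNR
gain ≈ M/P). Low-redundancy modalities (7-echo T2 mapping, 12-point IR)
benefit from being concatenated with redundant ones (a 68-volume DW series):
that redundancy-transfer effect is what this package quantifies, entirely
in silico.

The package provides, as tested R functions:

* a partial-volume spinal cord phantom (elliptical cord with butterfly grey
  matter, 1×1×5 mm voxels, ~44 cord voxels/slice, per-voxel Gaussian tissue
  parameter draws);
* the unified 131-measurement protocol (68 DW + 44 qMT + 12 IR + 7 mTE) and
  its JSON/bval/bvec serialisations;
* noise-free signal synthesis per the weighted-sum partial-volume model,
  including two-pool Bloch simulation of 25-pulse sinc-Gaussian MT
  saturation trains with a super-Lorentzian lineshape (RcppArmadillo
  kernel);
* Gaussian/Rician corruption at a WM-b=0-referenced SNR, and moment-based
  noise-floor correction;
* MP-PCA (`mp_pca`), slice-wise denoising under `individual`, `joint_all`
  and `joint_dwi_plus` strategies;
* model fitting: DKI (FA, MD, MK), mono-exponential T2, magnitude IR T1,
  and two-pool qMT (BPF, k, T2B) with the Bloch simulator as forward model;
* evaluation: relative-error median/IQR, CoV, scan-rescan variability,
  WM/GM CNR, SNR estimation, residual and σ̂ diagnostics, and a
  checkpointed study runner (`run_insilico_study`).

## Worked example

```r
library(cordqmri)

protocol <- default_protocol()          # 131 measurements
phantom  <- default_phantom(seed = 1)   # 40 slices, 1787 cord voxels
clean    <- synthesize_dataset(phantom, protocol)

sigma <- sigma_from_snr(clean, phantom, protocol, snr = 10)
noisy <- add_gaussian_noise(clean, sigma, seed = 101)
mask  <- phantom$fractions$cord_mask

alone <- denoise_slicewise(noisy, mask, protocol, denoise_strategy("individual"))
joint <- denoise_slicewise(noisy, mask, protocol, denoise_strategy("joint_all"))

mte <- modality_rows(protocol, "mTE")
error_summary(relative_error(alone$denoised, clean, mask, mte))
#>   median_eps  iqr_eps n_values n_realizations
#> 1 -0.0743     4.507    12509              1
error_summary(relative_error(joint$denoised, clean, mask, mte))
#>   median_eps  iqr_eps n_values n_realizations
#> 1 -0.0629     3.643    12509              1
```

Both strategies are unbiased (medians ≈ 0), but the 7-measurement mTE block
is denoised more *precisely* when concatenated with the other 124
measurements (error IQR 3.6% vs 4.5% at SNR 10) — the central
redundancy-transfer result. Each joint slice call retains P = 5 of 131
components and estimates σ̂ = 0.0241 against a true σ of 0.0243
(`joint$log`).

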