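# Shared fixtures, built lazily once per test run. The "small" phantom (4
# slices, ~180 cord voxels) keeps unit tests fast; study-scale objects used
# by the acceptance tests live in the same cache and are built on first use.
.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_protocol <- function() fx("protocol", default_protocol)

fx_phantom_small <- function() fx("phantom_small", function() {
  default_phantom(seed = 42L, nslices = 4L)
})

fx_clean_small <- function() fx("clean_small", function() {
  synthesize_dataset(fx_phantom_small(), fx_protocol())
})

fx_wm_means <- function() {
  as.data.frame(as.list(tissue_reference_values("WM")))
}

fx_gm_means <- function() {
  as.data.frame(as.list(tissue_reference_values("GM")))
}

fx_csf <- function() {
  as.data.frame(as.list(tissue_reference_values("CSF")))
}

# study-scale fixtures (acceptance tests)
fx_phantom_full <- function() fx("phantom_full", function() {
  default_phantom(seed = 1L)
})

fx_clean_full <- function() fx("clean_full", function() {
  synthesize_dataset(fx_phantom_full(), fx_protocol())
})
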