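# Shared fixtures, all generated in code.

# The default study is expensive enough to build once per test run.
.study_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.study_cache$study)) {
    .study_cache$study <- generate_study(study_config())
  }
  .study_cache$study
}

default_study_wells <- function() {
  if (is.null(.study_cache$wells)) {
    .study_cache$wells <- quantify_study(default_study())
  }
  .study_cache$wells
}

# A reduced study for cheap end-to-end tests.
small_config <- function(seed = 7L) {
  study_config(plates_per_arm = 4L, n_excluded = 2L, seed = seed)
}

# One-well six-well plate with known truth.
one_well_plate <- function(cells = 1e6, sa = 10) {
  plate_spec("six_well", tibble::tibble(
    cell_number = cells, specific_activity = sa
  ))
}

noiseless_scanner <- function(id = "petct", fwhm = 0, bg = 0) {
  scanner_model(id, psf_fwhm = fwhm, background_concentration = bg,
                noise_scale = Inf)
}
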