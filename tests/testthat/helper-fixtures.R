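# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small noise-free cohort: deterministic link, no B0, no acquisition noise
clean_cohort <- function() {
  fixture("clean_cohort", function() {
    generate_cohort(phantom_config(
      n_subjects = 3L, grid_shape = c(14L, 14L, 8L),
      noise_sd_dsc = 0, noise_sd_cest = 0, link_noise_sd = 0,
      b0_amplitude_ppm = 0, seed = 42L))
  })
}

# same geometry with the default noise and B0 conditions
noisy_cohort <- function() {
  fixture("noisy_cohort", function() {
    generate_cohort(phantom_config(
      n_subjects = 3L, grid_shape = c(14L, 14L, 8L), seed = 42L))
  })
}

# build a single-voxel-replicated CEST acquisition on a tiny grid
uniform_cest <- function(acidity, b0, noise_sd = 0,
                         grid = c(6L, 6L, 4L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  offs <- offset_schedule()
  nv <- prod(grid)
  vols <- array(0, c(grid, length(offs)))
  s0 <- array(0, grid)
  for (i in seq_len(nv)) {
    z <- simulate_zspectrum(acidity, b0, offs, noise_sd)
    vols[(seq_along(offs) - 1L) * nv + i] <- z$spectrum
    s0[i] <- z$s0
  }
  cest_acquisition(offs, vols, s0, array(TRUE, grid))
}

# CEST acquisition with per-voxel acidity/B0 arrays (noise-free)
varied_cest <- function(acidity, b0_field) {
  grid <- dim(acidity)
  offs <- offset_schedule()
  nv <- prod(grid)
  vols <- array(0, c(grid, length(offs)))
  for (i in seq_len(nv)) {
    z <- simulate_zspectrum(acidity[i], b0_field[i], offs, 0)
    vols[(seq_along(offs) - 1L) * nv + i] <- z$spectrum
  }
  cest_acquisition(offs, vols, array(1, grid), array(TRUE, grid))
}
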