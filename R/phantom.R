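#' Phantom generator configuration
#'
#' Bundles the study conditions for a synthetic multi-subject cohort of
#' glioblastoma digital phantoms: grid geometry, DSC timing, noise levels,
#' B0 inhomogeneity amplitude, and the scatter of the hemodynamics-to-acidity
#' link. Defaults reproduce the package's reference cohort (12 subjects,
#' 20 x 20 x 12 voxel grid, 60 DSC frames at TR = 2 s).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param grid_shape integer vector of length 3, voxels per axis (each >= 4).
#' @param n_timepoints number of DSC frames.
#' @param tr_seconds repetition time of the DSC series in seconds.
#' @param baseline_frames number of pre-bolus frames (< `n_timepoints`).
#' @param noise_sd_dsc Gaussian noise SD on DSC signal, as a fraction of the
#'   baseline signal level.
#' @param noise_sd_cest Gaussian noise SD on CEST signal, as a fraction of S0.
#' @param b0_amplitude_ppm maximum magnitude of the B0 offset field, ppm.
#' @param link_noise_sd SD of the Gaussian scatter added to the deterministic
#'   hemodynamics-to-acidity link (on the MTR_asym fraction scale).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_subjects = 12L,
                           grid_shape = c(20L, 20L, 12L),
                           n_timepoints = 60L,
                           tr_seconds = 2,
                           baseline_frames = 10L,
                           noise_sd_dsc = 0.01,
                           noise_sd_cest = 0.005,
                           b0_amplitude_ppm = 0.2,
                           link_noise_sd = 0.01,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3L)
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 4L)) stop("every grid_shape entry must be >= 4")
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (baseline_frames >= n_timepoints) {
    stop("baseline_frames must be smaller than n_timepoints")
  }
  if (baseline_frames < 1L) stop("baseline_frames must be >= 1")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (noise_sd_dsc < 0 || noise_sd_cest < 0 || link_noise_sd < 0 ||
      b0_amplitude_ppm < 0) {
    stop("noise and B0 amplitude parameters must be nonnegative")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    grid_shape = grid_shape,
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    baseline_frames = as.integer(baseline_frames),
    noise_sd_dsc = noise_sd_dsc,
    noise_sd_cest = noise_sd_cest,
    b0_amplitude_ppm = b0_amplitude_ppm,
    link_noise_sd = link_noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("phantom_config:", x$n_subjects, "subjects,",
      paste(x$grid_shape, collapse = "x"), "grid,",
      x$n_timepoints, "frames @ TR", x$tr_seconds, "s\n")
  cat("  noise: dsc", x$noise_sd_dsc, "| cest", x$noise_sd_cest,
      "| B0 amp", x$b0_amplitude_ppm, "ppm | link scatter", x$link_noise_sd,
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Z-spectral saturation offset schedule
#'
#' The 29-point offset schedule used for the amine CEST acquisition: the union
#' of three arithmetic ranges in 0.1 ppm increments, -3.5..-2.5 ppm around the
#' downfield window, -0.3..+0.3 ppm densely sampling the water resonance for
#' B0 estimation, and +2.5..+3.5 ppm around the amine resonance. Sorted
#' ascending with duplicates removed.
#'
#' @return numeric vector of 29 offsets in ppm.
#' @export
offset_schedule <- function() {
  offs <- c(seq(-3.5, -2.5, by = 0.1),
            seq(-0.3, 0.3, by = 0.1),
            seq(2.5, 3.5, by = 0.1))
  sort(unique(round(offs, 1)))
}

## unit-peak gamma-variate bolus: g(tp) = 1, g = 0 for t <= t0
gamma_variate <- function(t, t0, tp, alpha) {
  g <- numeric(length(t))
  up <- t > t0
  x <- (t[up] - t0) / (tp - t0)
  g[up] <- x^alpha * exp(alpha * (1 - x))
  g
}

## recovery time constant of the leakage step, seconds
.dsc_tau_recovery <- 8

#' Noise-free DSC signal expectation
#'
#' Closed-form expectation of the simulated DSC signal-time curve:
#' `L * (1 - D*g(t) - D*(1-R)*c(t))` where `g` is a unit-peak gamma-variate
#' bolus (peak at `tp = t0 + 20/k`, shape `alpha = k`) and
#' `c(t) = (1 - exp(-(t - tp)/tau)) * (1 - g(t))` is a smoothed recovery step
#' gated off at the bolus peak, so the curve attains baseline `L` before `t0`,
#' minimum exactly `L*(1-D)` at the peak, and late-time plateau
#' `L*(1 - D*(1-R))`.
#'
#' @param t times in seconds (vector).
#' @param L baseline signal level (> 0).
#' @param D fractional drop depth in `[0, 1]`.
#' @param R fractional signal recovery in `[0, 1]` (1 = full recovery).
#' @param t0 bolus arrival time, seconds.
#' @param k sharpness latent (> 0); larger k gives a sharper, earlier peak.
#' @return numeric vector of expected signal.
#' @export
dsc_expectation <- function(t, L, D, R, t0, k) {
  if (L <= 0) stop("perfusion level L must be positive")
  if (D < 0 || D > 1) stop("drop depth D must lie in [0, 1]")
  if (R < 0 || R > 1) stop("recovery fraction R must lie in [0, 1]")
  if (k <= 0) stop("sharpness k must be positive")
  tp <- t0 + 20 / k
  g <- gamma_variate(t, t0, tp, k)
  cstep <- numeric(length(t))
  late <- t > tp
  cstep[late] <- (1 - exp(-(t[late] - tp) / .dsc_tau_recovery)) * (1 - g[late])
  L * (1 - D * g - D * (1 - R) * cstep)
}

#' Simulate one DSC signal-time curve
#'
#' Draws a noisy perfusion curve from the gamma-variate bolus model given one
#' voxel's latent hemodynamic parameters. Noise is i.i.d. Gaussian with SD
#' `noise_sd * L` (noise stated as a fraction of baseline signal).
#'
#' @param latents named list or vector with elements `L`, `D`, `R`, `t0`, `k`.
#' @param n_timepoints number of frames.
#' @param tr repetition time, seconds.
#' @param baseline_frames pre-bolus frame count; `t0` must not precede
#'   `baseline_frames * tr`.
#' @param noise_sd Gaussian noise SD as a fraction of `L`.
#' @return numeric vector of length `n_timepoints`.
#' @export
simulate_dsc_curve <- function(latents, n_timepoints, tr, baseline_frames,
                               noise_sd = 0) {
  latents <- as.list(latents)
  if (latents$t0 < baseline_frames * tr) {
    stop("bolus arrival t0 must not precede the pre-bolus window")
  }
  t <- (seq_len(n_timepoints) - 1) * tr
  mu <- dsc_expectation(t, latents$L, latents$D, latents$R,
                        latents$t0, latents$k)
  if (noise_sd > 0) {
    mu <- mu + stats::rnorm(n_timepoints, 0, noise_sd * latents$L)
  }
  mu
}

## ---- CEST z-spectrum model -------------------------------------------------

## Lorentzian line with unit peak: (G/2)^2 / ((G/2)^2 + (w - d)^2)
lorentzian_line <- function(w, delta, gamma) {
  h <- (gamma / 2)^2
  h / (h + (w - delta)^2)
}

## fixed pool parameters: direct water saturation and a broad symmetric
## MT-like background; the amine pool at +3 ppm carries the acidity signal
.cest_pools <- list(
  water = list(delta = 0,   A = 0.75, gamma = 1.2),
  mt    = list(delta = 0,   A = 0.10, gamma = 30),
  amine = list(delta = 3.0, gamma = 1.0)
)

#' Amine-pool calibration constant
#'
#' The factor converting amine-pool amplitude to the MTR_asym value recovered
#' by the 0.4 ppm window asymmetry at 3 ppm: the mean over the window offsets
#' of the amine Lorentzian minus its mirrored tail. The generator sets the
#' amine amplitude to `true_acidity / cest_w_cal()` so that, noise-free and
#' with zero B0 shift, the recovered MTR_asym equals the true acidity.
#'
#' @param center window center in ppm.
#' @param width full window width in ppm.
#' @param spacing offset sampling interval in ppm.
#' @return scalar calibration constant.
#' @export
cest_w_cal <- function(center = 3.0, width = 0.4, spacing = 0.1) {
  w <- seq(center - width / 2, center + width / 2, by = spacing)
  p <- .cest_pools$amine
  mean(lorentzian_line(w, p$delta, p$gamma) -
         lorentzian_line(-w, p$delta, p$gamma))
}

#' Simulate a CEST z-spectrum for one voxel
#'
#' Generates the saturated signal at each offset from a three-pool Lorentzian
#' model (direct water, broad symmetric MT background, amine at +3 ppm) with
#' all pools shifted by the voxel's B0 offset:
#' `Z(w) = 1 - sum_p A_p * Lor(w; delta_p + b0, Gamma_p)`. The amine amplitude
#' is `true_acidity / cest_w_cal()`. The unsaturated reference is `s0 = 1`
#' before noise; Gaussian noise of SD `noise_sd` (fraction of S0) is added to
#' every saturated sample and to s0.
#'
#' @param true_acidity MTR_asym-scale acidity in `[0, 0.1]`.
#' @param b0 voxel B0 offset in ppm.
#' @param offsets sampled offsets in ppm, strictly increasing.
#' @param noise_sd Gaussian noise SD as a fraction of S0.
#' @return list with `spectrum` (numeric vector over offsets) and `s0`.
#' @export
simulate_zspectrum <- function(true_acidity, b0, offsets, noise_sd = 0) {
  if (is.unsorted(offsets, strictly = TRUE)) {
    stop("offsets must be strictly increasing")
  }
  a_amine <- true_acidity / cest_w_cal()
  amps <- c(.cest_pools$water$A, .cest_pools$mt$A, a_amine)
  if (sum(amps) > 1) {
    stop("pool amplitudes sum above 1 (nonphysical negative signal)")
  }
  z <- 1 -
    .cest_pools$water$A * lorentzian_line(offsets, b0, .cest_pools$water$gamma) -
    .cest_pools$mt$A * lorentzian_line(offsets, b0, .cest_pools$mt$gamma) -
    a_amine * lorentzian_line(offsets, .cest_pools$amine$delta + b0,
                              .cest_pools$amine$gamma)
  s0 <- 1
  if (noise_sd > 0) {
    z <- z + stats::rnorm(length(z), 0, noise_sd)
    s0 <- s0 + stats::rnorm(1, 0, noise_sd)
  }
  list(spectrum = z, s0 = s0)
}

## ---- cohort geometry, latents, acidity link --------------------------------

## per-tissue latent parameter distributions (means, SDs); labels follow the
## BraTS-style convention 1 = NC, 2 = ED, 4 = ET, 0 = normal brain
.tissue_latents <- list(
  normal = list(L = c(100, 10), D = c(0.35, 0.05), R = c(0.85, 0.05)),
  nc     = list(L = c(60, 8),   D = c(0.20, 0.04), R = c(0.90, 0.04)),
  ed     = list(L = c(110, 10), D = c(0.40, 0.05), R = c(0.75, 0.06)),
  et     = list(L = c(160, 15), D = c(0.55, 0.07), R = c(0.60, 0.08))
)

## hemodynamics -> acidity link: monotone increasing in L, D and (1 - R);
## bounded to the fractional MTR_asym scale [0, 0.1]
.link_params <- list(scale = 0.09, w_L = 0.40, w_D = 0.35, w_R = 0.25,
                     L_ref = 200)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Deterministic hemodynamics-to-acidity link
#'
#' The monotone function mapping latent hemodynamics to true acidity used by
#' the phantom generator:
#' `0.09 * clamp01(0.40*clamp01(L/200) + 0.35*D + 0.25*(1-R))`.
#' Higher perfusion level, deeper drop, and poorer recovery all increase
#' acidity, mirroring the reported association of the first three temporal
#' principal components with MTR_asym.
#'
#' @param L,D,R latent vectors (level, drop depth, recovery fraction).
#' @return acidity values on the MTR_asym fraction scale, in `[0, 0.09]`.
#' @export
acidity_link <- function(L, D, R) {
  p <- .link_params
  p$scale * clamp01(p$w_L * clamp01(L / p$L_ref) + p$w_D * D +
                      p$w_R * (1 - R))
}

## concentric-ellipsoid tumor in one hemisphere of an ellipsoidal brain
phantom_geometry <- function(grid_shape, jitter = c(0, 0, 0),
                             radius_jitter = 1) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  ctr <- (grid_shape + 1) / 2
  ax_brain <- 0.45 * grid_shape
  tumor_ctr <- ctr + grid_shape * (c(0.17, 0, 0) + jitter)
  r_nc <- 0.12 * grid_shape * radius_jitter
  r_et <- 0.18 * grid_shape * radius_jitter
  r_ed <- 0.26 * grid_shape * radius_jitter
  ix <- array(rep(seq_len(nx), times = ny * nz), dim = grid_shape)
  iy <- array(rep(rep(seq_len(ny), each = nx), times = nz), dim = grid_shape)
  iz <- array(rep(seq_len(nz), each = nx * ny), dim = grid_shape)
  d2 <- function(c0, ax) {
    ((ix - c0[1]) / ax[1])^2 + ((iy - c0[2]) / ax[2])^2 +
      ((iz - c0[3]) / ax[3])^2
  }
  brain <- d2(ctr, ax_brain) <= 1
  dt_nc <- d2(tumor_ctr, r_nc)
  dt_et <- d2(tumor_ctr, r_et)
  dt_ed <- d2(tumor_ctr, r_ed)
  label <- array(0L, dim = grid_shape)
  label[brain & dt_ed <= 1] <- 2L   # peritumoral edema shell
  label[brain & dt_et <= 1] <- 4L   # enhancing tumor rim
  label[brain & dt_nc <= 1] <- 1L   # necrotic core
  list(mask = brain, label = label, coords = list(ix = ix, iy = iy, iz = iz),
       center = ctr)
}

## signed low-order polynomial B0 field scaled so max |field| = amplitude;
## a global offset dominates so the field keeps one sign across the brain
make_b0_field <- function(grid_shape, amplitude) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  xs <- seq(-1, 1, length.out = nx)
  ys <- seq(-1, 1, length.out = ny)
  zs <- seq(-1, 1, length.out = nz)
  x <- array(rep(xs, times = ny * nz), dim = grid_shape)
  y <- array(rep(rep(ys, each = nx), times = nz), dim = grid_shape)
  z <- array(rep(zs, each = nx * ny), dim = grid_shape)
  a <- stats::rnorm(9)
  q <- a[1] * x + a[2] * y + a[3] * z + a[4] * x * y + a[5] * x * z +
    a[6] * y * z + a[7] * x^2 + a[8] * y^2 + a[9] * z^2
  mq <- max(abs(q))
  if (mq > 0) q <- 0.4 * q / mq
  sgn <- if (stats::runif(1) < 0.5) -1 else 1
  raw <- sgn * (0.6 + q)
  amplitude * raw / max(abs(raw))
}

draw_latents <- function(n, tissue) {
  p <- .tissue_latents[[tissue]]
  list(
    L = pmax(stats::rnorm(n, p$L[1], p$L[2]), 5),
    D = pmin(pmax(stats::rnorm(n, p$D[1], p$D[2]), 0.02), 0.95),
    R = pmin(pmax(stats::rnorm(n, p$R[1], p$R[2]), 0.05), 1)
  )
}

## vectorized noise-free DSC expectation over voxels (rows) x times (cols)
dsc_expectation_matrix <- function(L, D, R, t0, k, t) {
  nv <- length(L); nt <- length(t)
  tp <- t0 + 20 / k
  tm <- matrix(t, nv, nt, byrow = TRUE)
  x <- (tm - t0) / (tp - t0)
  g <- matrix(0, nv, nt)
  up <- tm > t0
  g[up] <- (x[up]^k[row(x)[up]]) * exp(k[row(x)[up]] * (1 - x[up]))
  cstep <- matrix(0, nv, nt)
  late <- tm > tp
  cstep[late] <- (1 - exp(-(tm[late] - tp[row(tm)[late]]) /
                            .dsc_tau_recovery)) * (1 - g[late])
  L * (1 - D * g - D * (1 - R) * cstep)
}

#' Generate a synthetic multi-subject phantom cohort
#'
#' Builds `n_subjects` digital phantoms, each with a concentric-ellipsoid
#' tumor (necrotic core, enhancing rim, edema shell) in one hemisphere of an
#' ellipsoidal brain. Tissue classes receive distinct latent hemodynamic
#' distributions (ET high level and drop, NC low level, ED intermediate);
#' true acidity is [acidity_link()] of the latents plus Gaussian scatter
#' `link_noise_sd`, clamped to `[0, 0.1]`. Each subject gets a DSC time
#' series, a CEST acquisition over [offset_schedule()] with a smooth signed
#' polynomial B0 field, the tumor segmentation, and the full ground truth.
#' The whole cohort is a deterministic function of the configuration.
#'
#' @param config a [phantom_config()].
#' @param out_dir optional directory; if given, each subject is written to
#'   disk via [write_subject()].
#' @return an object of class `phantom_cohort`: list with `config` and
#'   `subjects` (each of class `phantom_subject`).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  offsets <- offset_schedule()
  t <- (seq_len(config$n_timepoints) - 1) * config$tr_seconds
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    jit <- c(stats::runif(1, -0.02, 0.02), stats::runif(1, -0.04, 0.04), 0)
    rjit <- stats::runif(1, 0.9, 1.1)
    geo <- phantom_geometry(config$grid_shape, jitter = jit,
                            radius_jitter = rjit)
    if (!all(c(1L, 2L, 4L) %in% geo$label)) {
      stop("degenerate phantom geometry: a tumor subregion is empty")
    }
    vox <- which(geo$mask)
    nv <- length(vox)
    lab <- geo$label[vox]
    L <- D <- R <- numeric(nv)
    for (tis in list(c("normal", 0L), c("nc", 1L), c("ed", 2L),
                     c("et", 4L))) {
      idx <- which(lab == as.integer(tis[2]))
      if (length(idx)) {
        lt <- draw_latents(length(idx), tis[1])
        L[idx] <- lt$L; D[idx] <- lt$D; R[idx] <- lt$R
      }
    }
    t0 <- config$baseline_frames * config$tr_seconds +
      stats::runif(nv, 2, 6)
    k <- stats::runif(nv, 2, 5)
    acid <- acidity_link(L, D, R)
    if (config$link_noise_sd > 0) {
      acid <- acid + stats::rnorm(nv, 0, config$link_noise_sd)
    }
    acid <- pmin(pmax(acid, 0), 0.1)
    b0 <- make_b0_field(config$grid_shape, config$b0_amplitude_ppm)

    ## DSC 4D volume
    mu <- dsc_expectation_matrix(L, D, R, t0, k, t)
    if (config$noise_sd_dsc > 0) {
      mu <- mu + matrix(stats::rnorm(length(mu), 0, 1), nrow(mu)) *
        (config$noise_sd_dsc * L)
    }
    dsc <- array(0, dim = c(config$grid_shape, config$n_timepoints))
    for (j in seq_len(config$n_timepoints)) {
      vol <- array(0, dim = config$grid_shape)
      vol[vox] <- mu[, j]
      dsc[, , , j] <- vol
    }

    ## CEST 4D volume + S0, three-pool Lorentzian spectra
    wcal <- cest_w_cal()
    a_amine <- acid / wcal
    b0v <- b0[vox]
    z <- matrix(1, nv, length(offsets))
    for (jj in seq_along(offsets)) {
      w <- offsets[jj]
      z[, jj] <- 1 -
        .cest_pools$water$A * lorentzian_line(w, b0v, .cest_pools$water$gamma) -
        .cest_pools$mt$A * lorentzian_line(w, b0v, .cest_pools$mt$gamma) -
        a_amine * lorentzian_line(w, .cest_pools$amine$delta + b0v,
                                  .cest_pools$amine$gamma)
    }
    s0v <- rep(1, nv)
    if (config$noise_sd_cest > 0) {
      z <- z + matrix(stats::rnorm(length(z), 0, config$noise_sd_cest),
                      nrow(z))
      s0v <- s0v + stats::rnorm(nv, 0, config$noise_sd_cest)
    }
    cest <- array(0, dim = c(config$grid_shape, length(offsets)))
    for (jj in seq_along(offsets)) {
      vol <- array(0, dim = config$grid_shape)
      vol[vox] <- z[, jj]
      cest[, , , jj] <- vol
    }
    s0 <- array(0, dim = config$grid_shape)
    s0[vox] <- s0v

    truth <- list(
      L = fill_volume(L, vox, config$grid_shape),
      D = fill_volume(D, vox, config$grid_shape),
      R = fill_volume(R, vox, config$grid_shape),
      t0 = fill_volume(t0, vox, config$grid_shape),
      k = fill_volume(k, vox, config$grid_shape),
      true_acidity = fill_volume(acid, vox, config$grid_shape),
      b0_field = b0,
      label = geo$label
    )
    subjects[[s]] <- structure(list(
      id = sprintf("subject-%02d", s),
      dsc = dsc,
      tr_seconds = config$tr_seconds,
      baseline_frames = config$baseline_frames,
      cest = list(offsets = offsets, volumes = cest, s0 = s0,
                  mask = geo$mask),
      mask = geo$mask,
      seg = geo$label,
      truth = truth,
      link = .link_params
    ), class = "phantom_subject")
  }
  cohort <- structure(list(config = config, subjects = subjects),
                      class = "phantom_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

fill_volume <- function(values, vox, grid_shape) {
  vol <- array(NA_real_, dim = grid_shape)
  vol[vox] <- values
  vol
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("phantom_cohort:", length(x$subjects), "subjects on",
      paste(x$config$grid_shape, collapse = "x"), "grid\n")
  invisible(x)
}
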