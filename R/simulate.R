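# Seeded synthetic-data generators for every input type the analysis
# consumes. Noiseless generator output goes through the same forward-model
# code the fits use, so generators and models cannot drift apart; noise is
# additive Gaussian on the observable (multiplicative for peak volumes),
# and every generator takes an explicit seed and leaves the caller's
# random state untouched.

#' Simulate a ligand titration series
#'
#' Two-state mode produces a fast-exchange reporter shift versus total
#' ligand; three-state mode additionally produces the slow-exchange
#' active-state reporter intensity, both from the exact equilibrium
#' models. Gaussian noise is added on each observable.
#'
#' @param ligand_mM Strictly increasing, non-negative total ligand
#'   concentrations (mM).
#' @param protein_mM Total protein concentration (mM).
#' @param kd_mM Two-state dissociation constant (mM); supply for the
#'   two-state model.
#' @param kd_inactive_mM,kd_active_mM Apparent dissociation constants
#'   (mM); supply both for the three-state model.
#' @param delta_free_ppm,delta_bound_ppm Reporter shifts (ppm).
#' @param intensity_scale Active-reporter intensity at unit population
#'   (three-state only).
#' @param noise_sd Shift noise SD (ppm); default 0.002, a typical
#'   spectral-resolution-scale uncertainty.
#' @param intensity_noise_frac Intensity noise SD as a fraction of the
#'   maximum noiseless intensity (three-state only); default 0.02.
#' @param seed Integer random seed (mandatory for reproducibility).
#' @return A tibble with `ligand_mM`, `protein_mM`, `shift_ppm`,
#'   `shift_sd` and, in three-state mode, `intensity`, `intensity_sd`.
#' @examples
#' sim_titration(kd_mM = 1.7, delta_free_ppm = 18, delta_bound_ppm = 18.5,
#'               ligand_mM = seq(0, 20, length.out = 12), protein_mM = 0.1,
#'               noise_sd = 0.002, seed = 7)
#' @export
sim_titration <- function(ligand_mM, protein_mM, kd_mM = NULL,
                          kd_inactive_mM = NULL, kd_active_mM = NULL,
                          delta_free_ppm, delta_bound_ppm,
                          intensity_scale = 1, noise_sd = 0.002,
                          intensity_noise_frac = 0.02, seed) {
  if (length(ligand_mM) == 0) abort("`ligand_mM` must be non-empty.")
  if (any(ligand_mM < 0) || is.unsorted(ligand_mM, strictly = TRUE)) {
    abort("`ligand_mM` must be non-negative and strictly increasing.")
  }
  check_noise(noise_sd)
  if (!is.null(kd_mM)) {
    shift <- two_state_shift(ligand_mM, protein_mM, kd_mM,
                             delta_free_ppm, delta_bound_ppm)
    with_seed(seed, {
      tibble(
        ligand_mM = ligand_mM, protein_mM = protein_mM,
        shift_ppm = shift + rnorm(length(shift), 0, noise_sd),
        shift_sd = noise_sd
      )
    })
  } else {
    if (is.null(kd_inactive_mM) || is.null(kd_active_mM)) {
      abort("Supply `kd_mM` or both apparent dissociation constants.")
    }
    obs <- three_state_observables(ligand_mM, protein_mM, kd_inactive_mM,
                                   kd_active_mM, delta_free_ppm,
                                   delta_bound_ppm, intensity_scale)
    isd <- intensity_noise_frac * max(obs$intensity)
    with_seed(seed, {
      tibble(
        ligand_mM = ligand_mM, protein_mM = protein_mM,
        shift_ppm = obs$shift_ppm + rnorm(nrow(obs), 0, noise_sd),
        shift_sd = noise_sd,
        intensity = obs$intensity + rnorm(nrow(obs), 0, isd),
        intensity_sd = isd
      )
    })
  }
}

#' Simulate a four-curve ZZ-exchange dataset
#'
#' Auto- and cross-peak intensities from the closed-form longitudinal
#' exchange model (see [zz_intensities()]) plus Gaussian noise scaled to
#' the maximum noiseless intensity.
#'
#' @inheritParams zz_intensities
#' @param R1,R1_A Longitudinal relaxation rate(s) (s^-1); one shared value
#'   by default.
#' @param noise_sd Noise SD as a fraction of the maximum noiseless
#'   intensity; default 0.02.
#' @param seed Integer random seed.
#' @return A tibble with `time_s`, the four intensity columns, and four
#'   matching `_sd` columns.
#' @examples
#' sim_zz_curves(5, 9, R1 = 1.5, times = seq(0, 0.3, length.out = 8),
#'               noise_sd = 0.02, seed = 3)
#' @export
sim_zz_curves <- function(k_IA, k_AI, R1 = 0, R1_A = R1, times,
                          amp_I = NULL, amp_A = NULL, noise_sd = 0.02,
                          seed) {
  if (any(times < 0)) abort("Mixing times must be non-negative.")
  check_noise(noise_sd)
  clean <- zz_intensities(k_IA, k_AI, R1, R1_A, times,
                          amp_I = amp_I, amp_A = amp_A)
  sd_abs <- noise_sd * max(abs(as.matrix(clean[, -1])))
  with_seed(seed, {
    noisy <- clean
    for (col in c("I_II", "I_AA", "I_IA", "I_AI")) {
      noisy[[col]] <- clean[[col]] + rnorm(nrow(clean), 0, sd_abs)
      noisy[[paste0(col, "_sd")]] <- sd_abs
    }
    noisy
  })
}

#' Simulate a titration series of two-site exchange spectra
#'
#' One 1D spectrum per titration point, with populations and exchange
#' rates at each point derived from `(KD, koff)` through the exact binding
#' equilibrium, plus Gaussian noise scaled to the series maximum.
#'
#' @inheritParams sim_titration
#' @param koff Dissociation rate constant (s^-1), > 0.
#' @param delta_free_hz,delta_bound_hz Site offsets (Hz).
#' @param r2_free,r2_bound Transverse relaxation rates (s^-1).
#' @param freq_hz Strictly increasing frequency grid (Hz).
#' @param noise_frac Noise SD as a fraction of the maximum noiseless
#'   intensity; default 0.01.
#' @return Long-format tibble: `ligand_mM`, `frequency_hz`, `intensity`.
#' @export
sim_lineshape_series <- function(ligand_mM, protein_mM, kd_mM, koff,
                                 delta_free_hz, delta_bound_hz,
                                 r2_free = 30, r2_bound = r2_free,
                                 freq_hz, noise_frac = 0.01, seed) {
  if (koff <= 0) abort("`koff` must be positive.")
  if (r2_free <= 0 || r2_bound <= 0) abort("R2 rates must be positive.")
  if (any(diff(freq_hz) <= 0)) {
    abort("`freq_hz` must have positive grid spacing.")
  }
  check_noise(noise_frac)
  clean <- lineshape_series_model(freq_hz, ligand_mM, protein_mM, kd_mM,
                                  koff, delta_free_hz, delta_bound_hz,
                                  r2_free, r2_bound)
  sd_abs <- noise_frac * max(clean$intensity)
  with_seed(seed, {
    mutate(clean,
           intensity = .data$intensity + rnorm(n(), 0, sd_abs))
  })
}

#' Simulate an enzymatic progress curve
#'
#' Product fraction `f(t) = min(1, kcat * E * t / S0)` (all concentrations
#' converted to a consistent unit) sampled on a regular grid, returned as
#' substrate/product signal integrals with additive Gaussian noise.
#'
#' @param kcat_min Turnover number (min^-1).
#' @param enzyme_uM Enzyme concentration (micromolar).
#' @param substrate_mM Initial substrate concentration (millimolar).
#' @param dt_s Sampling interval (s); default 34, one spectrum per
#'   transient block of the real-time assay the generator emulates.
#' @param total_s Total observation time (s).
#' @param noise_sd Noise SD on each integral (fraction units); default
#'   0.01.
#' @param seed Integer random seed.
#' @return A tibble with `time_s`, `gln_integral`, `glu_integral`,
#'   `enzyme_uM`, `substrate_mM`.
#' @examples
#' sim_progress_curve(63, 1, 10, total_s = 1200, noise_sd = 0.01, seed = 2)
#' @export
sim_progress_curve <- function(kcat_min, enzyme_uM, substrate_mM,
                               dt_s = 34, total_s = 1200, noise_sd = 0.01,
                               seed) {
  if (kcat_min < 0) abort("`kcat_min` must be non-negative.")
  if (enzyme_uM <= 0 || substrate_mM <= 0 || dt_s <= 0) {
    abort("Concentrations and the sampling interval must be positive.")
  }
  check_noise(noise_sd)
  t <- seq(0, total_s, by = dt_s)
  f <- pmin(1, (kcat_min / 60) * enzyme_uM * t / (substrate_mM * 1000))
  with_seed(seed, {
    tibble(
      time_s = t,
      gln_integral = (1 - f) + rnorm(length(t), 0, noise_sd),
      glu_integral = f + rnorm(length(t), 0, noise_sd),
      enzyme_uM = enzyme_uM, substrate_mM = substrate_mM
    )
  })
}

#' Simulate per-reporter peak-volume pairs at a given active fraction
#'
#' Each reporter gets a random overall scale (detection efficiency), an
#' inactive volume proportional to `1 - p_active` and an active volume
#' proportional to `p_active`, with multiplicative Gaussian noise on each
#' volume (default; additive available).
#'
#' @param p_active True active-state fraction, in `[0, 1]`.
#' @param n_reporters Number of reporter resonances (default 8).
#' @param noise_sd Noise SD: relative (multiplicative mode, default 0.03)
#'   or absolute (additive mode).
#' @param noise_type `"multiplicative"` or `"additive"`.
#' @param seed Integer random seed.
#' @return A tibble with `reporter`, `volume_inactive`, `volume_active`.
#' @examples
#' sim_peak_volumes(0.78, n_reporters = 8, noise_sd = 0.03, seed = 11)
#' @export
sim_peak_volumes <- function(p_active, n_reporters = 8, noise_sd = 0.03,
                             noise_type = c("multiplicative", "additive"),
                             seed) {
  noise_type <- match.arg(noise_type)
  if (p_active < 0 || p_active > 1) abort("`p_active` must be in [0, 1].")
  if (n_reporters < 1) abort("`n_reporters` must be at least 1.")
  check_noise(noise_sd)
  with_seed(seed, {
    scale <- runif(n_reporters, 0.5, 1.5)
    vi <- scale * (1 - p_active)
    va <- scale * p_active
    if (noise_type == "multiplicative") {
      vi <- vi * (1 + rnorm(n_reporters, 0, noise_sd))
      va <- va * (1 + rnorm(n_reporters, 0, noise_sd))
    } else {
      vi <- vi + rnorm(n_reporters, 0, noise_sd)
      va <- va + rnorm(n_reporters, 0, noise_sd)
    }
    tibble(
      reporter = paste0("r", seq_len(n_reporters)),
      volume_inactive = pmax(vi, 0),
      volume_active = pmax(va, 0)
    )
  })
}
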