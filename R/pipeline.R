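# Orchestration: the end-to-end reproduction run that stitches together
# simulation, fitting, population analysis, the thermodynamic table and
# the rank correlation into one machine-readable report.

#' Default configuration for a reproduction run
#'
#' Study-condition defaults: ground-truth parameters, concentration and
#' time grids, noise levels and replicate counts for every recovery
#' protocol, plus the temperature and the packaged condition table.
#'
#' @param seed Master integer seed; per-replicate sub-seeds are derived
#'   from it deterministically.
#' @return A named list understood by [run_reproduction()].
#' @export
reproduction_config <- function(seed = 1) {
  list(
    seed = seed,
    temperature = 303.15,
    two_state = list(kd_mM = 1.7, delta_free_ppm = 18,
                     delta_bound_ppm = 18.5,
                     ligand_mM = seq(0, 20, length.out = 12),
                     protein_mM = 0.1, noise_sd = 0.002, n_seeds = 20),
    three_state = list(kd_inactive_mM = 1.4, kd_active_mM = 0.2,
                       delta_free_ppm = 18, delta_bound_ppm = 18.5,
                       ligand_mM = seq(0, 20, length.out = 12),
                       protein_mM = 0.1, noise_sd = 0.002,
                       intensity_noise_frac = 0.02, n_seeds = 20),
    zz = list(k_IA = 5, k_AI = 9, R1 = 1.5,
              times = seq(0, 0.3, length.out = 8),
              noise_sd = 0.02, n_seeds = 20),
    lineshape = list(koff = 1600, kd_mM = 1.3, delta_free_hz = -150,
                     delta_bound_hz = 150, r2 = 30,
                     ligand_mM = c(0, 0.65, 1.3, 2.6, 5.2, 13),
                     protein_mM = 0.1,
                     freq_hz = seq(-600, 700, by = 2),
                     noise_frac = 0.01, n_seeds = 10),
    kinetics = list(kcat_min = 63, enzyme_uM = 1, substrate_mM = 10,
                    dt_s = 34, total_s = 1200, noise_sd = 0.01,
                    n_seeds = 20),
    volumes = list(p_active = 0.78, n_reporters = 8, noise_sd = 0.03,
                   n_seeds = 20),
    reference = "ProFAR"
  )
}

#' Run the full reproduction pipeline
#'
#' Executes every recovery protocol of the package on seeded synthetic
#' data (two-state and three-state titration fits, ZZ-exchange rate fits,
#' global lineshape fits, turnover fits, peak-volume populations), builds
#' the thermodynamic linkage table from the packaged condition table, and
#' computes the exact Spearman rank correlation and the fixed-slope
#' linkage fit. Re-running with the same config reproduces every number
#' bit for bit.
#'
#' @param config A list from [reproduction_config()].
#' @param include_lineshape Set `FALSE` to skip the (comparatively slow)
#'   lineshape stage.
#' @return A list of tibbles and named values; element `summary` is a
#'   key/value tibble with every recovered mean.
#' @export
run_reproduction <- function(config = reproduction_config(),
                             include_lineshape = TRUE) {
  cfg <- config
  seeds <- function(n, block) {
    vapply(seq_len(n), function(i) sub_seed(cfg$seed + block * 100L, i),
           numeric(1))
  }

  # two-state KD recovery
  ts <- cfg$two_state
  kd2 <- vapply(seeds(ts$n_seeds, 1L), function(s) {
    d <- sim_titration(ligand_mM = ts$ligand_mM, protein_mM = ts$protein_mM,
                       kd_mM = ts$kd_mM, delta_free_ppm = ts$delta_free_ppm,
                       delta_bound_ppm = ts$delta_bound_ppm,
                       noise_sd = ts$noise_sd, seed = s)
    fit_two_state(d)$estimate$kd_mM
  }, numeric(1))

  # three-state apparent-KD recovery
  th <- cfg$three_state
  kd3 <- vapply(seeds(th$n_seeds, 2L), function(s) {
    d <- sim_titration(ligand_mM = th$ligand_mM, protein_mM = th$protein_mM,
                       kd_inactive_mM = th$kd_inactive_mM,
                       kd_active_mM = th$kd_active_mM,
                       delta_free_ppm = th$delta_free_ppm,
                       delta_bound_ppm = th$delta_bound_ppm,
                       noise_sd = th$noise_sd,
                       intensity_noise_frac = th$intensity_noise_frac,
                       seed = s)
    f <- fit_three_state(d)$estimate
    c(f$kd_inactive_mM, f$kd_active_mM)
  }, numeric(2))

  # ZZ-exchange rate recovery
  zz <- cfg$zz
  zzr <- vapply(seeds(zz$n_seeds, 3L), function(s) {
    d <- sim_zz_curves(zz$k_IA, zz$k_AI, R1 = zz$R1, times = zz$times,
                       noise_sd = zz$noise_sd, seed = s)
    f <- fit_zz(d)$estimate
    c(f$k_IA, f$k_AI)
  }, numeric(2))

  # lineshape koff recovery
  ko <- NULL
  if (isTRUE(include_lineshape)) {
    ls <- cfg$lineshape
    ko <- vapply(seeds(ls$n_seeds, 4L), function(s) {
      d <- sim_lineshape_series(ligand_mM = ls$ligand_mM,
                                protein_mM = ls$protein_mM,
                                kd_mM = ls$kd_mM, koff = ls$koff,
                                delta_free_hz = ls$delta_free_hz,
                                delta_bound_hz = ls$delta_bound_hz,
                                r2_free = ls$r2, freq_hz = ls$freq_hz,
                                noise_frac = ls$noise_frac, seed = s)
      fit_lineshape_titration(d, protein_mM = ls$protein_mM)$estimate$koff
    }, numeric(1))
  }

  # turnover recovery
  ki <- cfg$kinetics
  kc <- vapply(seeds(ki$n_seeds, 5L), function(s) {
    d <- sim_progress_curve(ki$kcat_min, ki$enzyme_uM, ki$substrate_mM,
                            dt_s = ki$dt_s, total_s = ki$total_s,
                            noise_sd = ki$noise_sd, seed = s)
    fit_turnover(d, ki$enzyme_uM, ki$substrate_mM)$estimate$kcat_min
  }, numeric(1))

  # peak-volume population recovery
  vo <- cfg$volumes
  pv <- vapply(seeds(vo$n_seeds, 6L), function(s) {
    d <- sim_peak_volumes(vo$p_active, vo$n_reporters,
                          noise_sd = vo$noise_sd, seed = s)
    population_from_volumes(d)$p_active
  }, numeric(1))

  # thermodynamic table, correlation, linkage fit
  cond <- hisfh_conditions()
  tt <- thermo_table(cond, reference = cfg$reference,
                     temperature = cfg$temperature)
  sp <- spearman_exact(tt$p_active, tt$kcat)
  lk <- fit_lnkcat_vs_ddg(tt, slope = "fixed",
                          temperature = cfg$temperature)

  summary <- tibble(
    quantity = c("kd_two_state_mM", "kd_inactive_mM", "kd_active_mM",
                 "k_IA_per_s", "k_AI_per_s",
                 if (!is.null(ko)) "koff_per_s",
                 "kcat_per_min", "p_active_volumes",
                 "p_active_zz_printed", "spearman_rs",
                 "spearman_p", "linkage_intercept"),
    value = c(mean(kd2), mean(kd3[1, ]), mean(kd3[2, ]),
              mean(zzr[1, ]), mean(zzr[2, ]),
              if (!is.null(ko)) mean(ko),
              mean(kc), mean(pv),
              equilibrium_population(cfg$zz$k_IA, cfg$zz$k_AI),
              sp$rs, sp$p_value, lk$estimate$intercept)
  )

  list(
    summary = summary,
    kd_two_state = kd2,
    kd_three_state = tibble(kd_inactive_mM = kd3[1, ],
                            kd_active_mM = kd3[2, ]),
    zz_rates = tibble(k_IA = zzr[1, ], k_AI = zzr[2, ]),
    koff = ko,
    kcat = kc,
    p_active_volumes = pv,
    thermo = tt,
    spearman = sp,
    linkage = lk,
    config = cfg
  )
}
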