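# Synthetic-data generators: determinism, noiseless = forward model,
# noise calibration, error handling.

test_that("all generators are bit-reproducible under a fixed seed", {
  args_tit <- list(ligand_mM = seq(0, 20, length.out = 8),
                   protein_mM = 0.1, kd_mM = 1.7, delta_free_ppm = 18,
                   delta_bound_ppm = 18.5, noise_sd = 0.002, seed = 17)
  expect_identical(do.call(sim_titration, args_tit),
                   do.call(sim_titration, args_tit))
  expect_identical(
    sim_zz_curves(5, 9, R1 = 1.5, times = seq(0, 0.3, length.out = 6),
                  noise_sd = 0.02, seed = 17),
    sim_zz_curves(5, 9, R1 = 1.5, times = seq(0, 0.3, length.out = 6),
                  noise_sd = 0.02, seed = 17)
  )
  expect_identical(
    sim_progress_curve(63, 1, 10, noise_sd = 0.01, seed = 17),
    sim_progress_curve(63, 1, 10, noise_sd = 0.01, seed = 17)
  )
  expect_identical(
    sim_peak_volumes(0.78, seed = 17),
    sim_peak_volumes(0.78, seed = 17)
  )
  # generators do not disturb the caller's RNG stream
  withr::with_seed(1, {
    r1 <- rnorm(1)
  })
  withr::with_seed(1, {
    invisible(sim_peak_volumes(0.5, seed = 99))
    r2 <- rnorm(1)
  })
  expect_identical(r1, r2)
})

test_that("noiseless titrations equal the forward models exactly", {
  t2 <- sim_titration(ligand_mM = c(0, 1, 5, 20), protein_mM = 0.1,
                      kd_mM = 1.7, delta_free_ppm = 18,
                      delta_bound_ppm = 18.5, noise_sd = 0, seed = 1)
  expect_equal(t2$shift_ppm,
               two_state_shift(c(0, 1, 5, 20), 0.1, 1.7, 18, 18.5))
  expect_equal(t2$shift_ppm[1], 18) # zero-ligand limit
  t3 <- sim_titration(ligand_mM = c(0, 1, 5, 20), protein_mM = 0.1,
                      kd_inactive_mM = 1.4, kd_active_mM = 0.2,
                      delta_free_ppm = 18, delta_bound_ppm = 18.5,
                      noise_sd = 0, intensity_noise_frac = 0, seed = 1)
  expect_equal(t3$intensity[1], 0) # no ligand, no active state
})

test_that("noiseless ZZ curves reproduce the exchange model; cross peaks
           start at zero", {
  times <- seq(0, 0.3, length.out = 6)
  d <- sim_zz_curves(5, 9, R1 = 1.5, times = times, noise_sd = 0, seed = 1)
  m <- zz_intensities(5, 9, 1.5, 1.5, times)
  expect_equal(d$I_II, m$I_II)
  expect_equal(d$I_IA, m$I_IA)
  expect_equal(d$I_IA[1], 0)
  expect_equal(d$I_AI[1], 0)
  # symmetric long-time limit at R1 = 0: all curves meet at half the
  # (equal) initial amplitudes — closed-form eigen-solution check
  long <- sim_zz_curves(4, 4, R1 = 0, times = c(0, 10), amp_I = 1,
                        amp_A = 1, noise_sd = 0, seed = 1)
  expect_equal(unlist(long[2, c("I_II", "I_AA", "I_IA", "I_AI")]),
               rep(0.5, 4), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("noiseless spectrum series equal the lineshape model, with
           kex-independent integrals and pure limits", {
  freq <- seq(-600, 700, by = 2)
  s <- sim_lineshape_series(ligand_mM = c(0, 1.3, 13), protein_mM = 0.1,
                            kd_mM = 1.7, koff = 2000,
                            delta_free_hz = -150, delta_bound_hz = 150,
                            freq_hz = freq, noise_frac = 0, seed = 1)
  # L = 0 is a pure free-state Lorentzian
  s0 <- dplyr::filter(s, ligand_mM == 0)
  pure <- two_site_spectrum(freq, -150, 150, 30, 30, p_bound = 0,
                            kex = 2000)
  expect_equal(s0$intensity, pure$intensity)
  expect_equal(s0$frequency_hz[which.max(s0$intensity)], -150)
  # integral identical across koff at fixed populations
  areas <- vapply(c(500, 5000, 1e6), function(ko) {
    si <- sim_lineshape_series(ligand_mM = c(0, 1.3, 13), protein_mM = 0.1,
                               kd_mM = 1.7, koff = ko,
                               delta_free_hz = -150, delta_bound_hz = 150,
                               freq_hz = seq(-2000, 2000, by = 2),
                               noise_frac = 0, seed = 1)
    s1 <- dplyr::filter(si, ligand_mM == 1.3)
    trapz(s1$frequency_hz, s1$intensity)
  }, numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.005)
  # very fast exchange: single line at the population-weighted shift
  fast <- sim_lineshape_series(ligand_mM = c(0, 0.6, 1.3, 13),
                               protein_mM = 0.1, kd_mM = 1.7, koff = 1e7,
                               delta_free_hz = -150, delta_bound_hz = 150,
                               freq_hz = freq, noise_frac = 0, seed = 1)
  f13 <- dplyr::filter(fast, ligand_mM == 13)
  lf <- free_ligand(13, 0.1, kd_mM = 1.7)
  pb <- lf / (1.7 + lf)
  expect_equal(f13$frequency_hz[which.max(f13$intensity)],
               -150 + pb * 300, tolerance = 3)
})

test_that("noise realizations have the requested spread", {
  big <- sim_progress_curve(10, 1, 10, dt_s = 1, total_s = 2000,
                            noise_sd = 0.05, seed = 23)
  f_true <- pmin(1, (10 / 60) * big$time_s / 1e4)
  resid <- big$glu_integral - f_true
  expect_gt(length(resid), 1000)
  expect_lt(abs(sd(resid) - 0.05) / 0.05, 0.2)
})

test_that("peak-volume generator respects its exact-fraction contract", {
  v_half <- sim_peak_volumes(0.5, n_reporters = 6, noise_sd = 0, seed = 2)
  expect_equal(v_half$volume_inactive, v_half$volume_active)
  v0 <- sim_peak_volumes(0, n_reporters = 6, noise_sd = 0, seed = 2)
  expect_equal(v0$volume_active, rep(0, 6))
})

test_that("generator preconditions are enforced", {
  expect_error(sim_titration(ligand_mM = numeric(0), protein_mM = 0.1,
                             kd_mM = 1, delta_free_ppm = 0,
                             delta_bound_ppm = 1, seed = 1), "non-empty")
  expect_error(sim_titration(ligand_mM = c(2, 1), protein_mM = 0.1,
                             kd_mM = 1, delta_free_ppm = 0,
                             delta_bound_ppm = 1, seed = 1), "increasing")
  expect_error(sim_titration(ligand_mM = 0:3, protein_mM = 0.1,
                             kd_mM = -1, delta_free_ppm = 0,
                             delta_bound_ppm = 1, seed = 1), "positive")
  expect_error(sim_zz_curves(5, 9, times = c(-0.1, 0.1), seed = 1),
               "non-negative")
  expect_error(sim_lineshape_series(ligand_mM = c(0, 1), protein_mM = 0.1,
                                    kd_mM = 1, koff = 1000,
                                    delta_free_hz = 0, delta_bound_hz = 100,
                                    freq_hz = c(0, 0, 1), seed = 1),
               "spacing")
  expect_error(sim_peak_volumes(1.2, seed = 1), "0, 1")
  expect_error(sim_progress_curve(63, 1, 10, noise_sd = -1, seed = 1),
               "non-negative")
})
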