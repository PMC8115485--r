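# Longitudinal two-state exchange (ZZ-exchange): closed-form solution of
# the coupled relaxation/exchange system and joint four-curve fitting.

# Closed-form exp(K t) for K = [[-R1_I - kIA, kAI], [kIA, -R1_A - kAI]].
# Returns the four matrix elements for each t, handling the degenerate
# (equal-eigenvalue) case by its analytic limit.
zz_propagator <- function(k_IA, k_AI, R1_I, R1_A, t) {
  a <- -R1_I - k_IA
  d <- -R1_A - k_AI
  b <- k_AI
  cc <- k_IA
  m <- (a + d) / 2
  disc <- (a - d)^2 + 4 * b * cc # >= 0 for this sign structure
  half <- sqrt(max(disc, 0)) / 2
  em <- exp(m * t)
  if (half * max(t, 1) < 1e-12) {
    ch <- 1 + (half * t)^2 / 2
    shh <- t * (1 + (half * t)^2 / 6) # sinh(half*t)/half as half -> 0
  } else {
    ch <- cosh(half * t)
    shh <- sinh(half * t) / half
  }
  list(
    E11 = em * (ch + (a - d) / 2 * shh),
    E12 = em * b * shh,
    E21 = em * cc * shh,
    E22 = em * (ch - (a - d) / 2 * shh)
  )
}

#' Auto- and cross-peak intensities of a two-state ZZ-exchange experiment
#'
#' Solves the coupled longitudinal magnetization equations
#' `d/dt [M_I, M_A] = K [M_I, M_A]` with
#' `K = [[-R1_I - k_IA, k_AI], [k_IA, -R1_A - k_AI]]` in closed form
#' (2x2 eigen-solution), for magnetization starting on each state in turn.
#' The four returned series are the auto peaks `I_II`, `I_AA` and the
#' exchange (cross) peaks `I_IA` (inactive-to-active transfer) and `I_AI`.
#'
#' @param k_IA,k_AI Forward (inactive-to-active) and backward interconversion
#'   rates (s^-1).
#' @param R1_I,R1_A Longitudinal relaxation rates of the two states (s^-1).
#' @param times Mixing times (s).
#' @param amp_I,amp_A Initial magnetization amplitudes of the two states.
#'   Defaults are the equilibrium populations `k_AI/(k_IA+k_AI)` and
#'   `k_IA/(k_IA+k_AI)`, the physical initial condition when the mixing
#'   period starts from a relaxed equilibrium sample.
#' @return A tibble with columns `time_s`, `I_II`, `I_AA`, `I_IA`, `I_AI`.
#' @examples
#' zz_intensities(5, 9, 1.5, 1.5, seq(0, 0.3, length.out = 8))
#' @export
zz_intensities <- function(k_IA, k_AI, R1_I = 0, R1_A = R1_I, times,
                           amp_I = NULL, amp_A = NULL) {
  if (any(c(k_IA, k_AI, R1_I, R1_A) < 0)) abort("Rates must be non-negative.")
  if (any(times < 0)) abort("Mixing times must be non-negative.")
  if (is.null(amp_I) || is.null(amp_A)) {
    if (k_IA + k_AI > 0) {
      amp_I <- amp_I %||% (k_AI / (k_IA + k_AI))
      amp_A <- amp_A %||% (k_IA / (k_IA + k_AI))
    } else {
      amp_I <- amp_I %||% 0.5
      amp_A <- amp_A %||% 0.5
    }
  }
  rows <- lapply(times, function(t) {
    E <- zz_propagator(k_IA, k_AI, R1_I, R1_A, t)
    tibble(
      time_s = t,
      I_II = amp_I * E$E11,
      I_AA = amp_A * E$E22,
      I_IA = amp_I * E$E21,
      I_AI = amp_A * E$E12
    )
  })
  bind_rows(rows)
}

#' Equilibrium active-state fraction from interconversion rates
#'
#' Detailed balance for a two-state exchange gives the active fraction
#' `k_IA / (k_IA + k_AI)`.
#'
#' @inheritParams zz_intensities
#' @return Fraction of the active state (0-1).
#' @examples
#' equilibrium_population(5, 9) # 0.357 -> 36%
#' @export
equilibrium_population <- function(k_IA, k_AI) {
  if (any(k_IA < 0) || any(k_AI < 0)) abort("Rates must be non-negative.")
  if (any(k_IA + k_AI == 0)) {
    abort("Both rates are zero; the equilibrium fraction is undefined.")
  }
  k_IA / (k_IA + k_AI)
}

#' Fit the two-state ZZ-exchange model to four intensity curves
#'
#' Joint Levenberg-Marquardt least squares over the two auto and two cross
#' curves versus mixing time. Free parameters are the two interconversion
#' rates, the longitudinal relaxation rate (shared between states by
#' default), and the two initial auto-peak amplitudes (absolute intensities
#' are instrument-scaled).
#'
#' @param data A data frame with columns `time_s`, `I_II`, `I_AA`, `I_IA`,
#'   `I_AI`; optional `*_sd` columns are used as weights.
#' @param shared_R1 If `TRUE` (default) a single R1 is fitted for both
#'   states; otherwise `R1_I` and `R1_A` are separate parameters.
#' @return An object of class `allofit_zz` with `tidy()`/`glance()`
#'   methods. Estimates include `k_IA`, `k_AI`, `R1_I`, `R1_A`, `amp_I`,
#'   `amp_A` and the derived equilibrium active fraction `p_active`.
#' @examples
#' d <- sim_zz_curves(5, 9, R1 = 1.5, times = seq(0, 0.3, length.out = 8),
#'                    noise_sd = 0, seed = 1)
#' fit_zz(d)
#' @export
fit_zz <- function(data, shared_R1 = TRUE) {
  check_column(data, c("time_s", "I_II", "I_AA", "I_IA", "I_AI"), "fit_zz")
  if (nrow(data) < 4) abort("At least 4 mixing times are required.")
  t <- data$time_s
  Y <- as.matrix(data[, c("I_II", "I_AA", "I_IA", "I_AI")])

  # exchange-detected guard: cross peaks must rise above the noise floor
  noise <- if (all(c("I_IA_sd", "I_AI_sd") %in% names(data))) {
    mean(c(data$I_IA_sd, data$I_AI_sd))
  } else {
    0.01 * max(abs(Y[, c("I_II", "I_AA")]))
  }
  if (max(abs(Y[, c("I_IA", "I_AI")])) < 3 * noise) {
    abort(paste(
      "fit_zz: cross-peak intensities never exceed 3x the noise level;",
      "no exchange is detected on this mixing-time grid."
    ), class = "allofit_exchange_undetected_error")
  }

  w <- matrix(1, nrow(Y), 4)
  sd_cols <- paste0(c("I_II", "I_AA", "I_IA", "I_AI"), "_sd")
  if (all(sd_cols %in% names(data))) {
    sds <- as.matrix(data[, sd_cols])
    if (all(sds > 0)) w <- 1 / sds
  }

  model_mat <- function(k_IA, k_AI, R1_I, R1_A, aI, aA) {
    E <- zz_propagator(k_IA, k_AI, R1_I, R1_A, t)
    cbind(aI * E$E11, aA * E$E22, aI * E$E21, aA * E$E12)
  }
  resid_fn <- function(par) {
    k_IA <- exp(par[1]); k_AI <- exp(par[2]); R1_I <- exp(par[3])
    if (shared_R1) {
      R1_A <- R1_I; aI <- par[4]; aA <- par[5]
    } else {
      R1_A <- exp(par[4]); aI <- par[5]; aA <- par[6]
    }
    as.vector(w * (Y - model_mat(k_IA, k_AI, R1_I, R1_A, aI, aA)))
  }

  # data-driven starts: cross build-up peaks near t ~ 1/(k_IA + k_AI)
  cross <- rowSums(abs(Y[, c("I_IA", "I_AI")]))
  t_pk <- t[which.max(cross)]
  kex0 <- if (t_pk > 0) 1 / t_pk else 10
  aI0 <- unname(Y[which.min(t), "I_II"])
  aA0 <- unname(Y[which.min(t), "I_AA"])
  ratio <- max(Y[, "I_IA"]) / max(max(Y[, "I_AI"]), 1e-12)
  kIA0 <- kex0 * ratio / (1 + ratio)
  kAI0 <- kex0 / (1 + ratio)
  R10 <- {
    i0 <- which.min(t); i1 <- which.max(t)
    r <- Y[i1, "I_II"] / max(Y[i0, "I_II"], 1e-12)
    if (r > 0 && r < 1 && t[i1] > t[i0]) -log(r) / (t[i1] - t[i0]) else 1
  }

  starts <- list(
    c(log(kIA0), log(kAI0)),
    c(log(kex0 / 2), log(kex0 / 2)),
    c(log(kIA0 / 5), log(kAI0 / 5)),
    c(log(kIA0 * 5), log(kAI0 * 5))
  )
  fits <- lapply(starts, function(s) {
    p0 <- if (shared_R1) c(s, log(max(R10, 1e-3)), aI0, aA0) else
      c(s, log(max(R10, 1e-3)), log(max(R10, 1e-3)), aI0, aA0)
    tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) abort("fit_zz: optimisation failed.")
  best <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]

  par <- best$par
  se <- nls_lm_se(best)
  if (shared_R1) {
    est <- list(k_IA = exp(par[1]), k_AI = exp(par[2]),
                R1_I = exp(par[3]), R1_A = exp(par[3]),
                amp_I = par[4], amp_A = par[5])
    sds <- list(k_IA = exp(par[1]) * se[1], k_AI = exp(par[2]) * se[2],
                R1_I = exp(par[3]) * se[3], R1_A = exp(par[3]) * se[3],
                amp_I = se[4], amp_A = se[5])
    npar <- 5L
  } else {
    est <- list(k_IA = exp(par[1]), k_AI = exp(par[2]),
                R1_I = exp(par[3]), R1_A = exp(par[4]),
                amp_I = par[5], amp_A = par[6])
    sds <- list(k_IA = exp(par[1]) * se[1], k_AI = exp(par[2]) * se[2],
                R1_I = exp(par[3]) * se[3], R1_A = exp(par[4]) * se[4],
                amp_I = se[5], amp_A = se[6])
    npar <- 6L
  }
  p_act <- equilibrium_population(est$k_IA, est$k_AI)

  new_allofit_fit(list(
    estimate = est, sd = sds, p_active = p_act, data = as_tibble(data),
    shared_R1 = shared_R1, deviance = best$deviance,
    df_residual = 4L * nrow(data) - npar, fit = best
  ), "allofit_zz")
}
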