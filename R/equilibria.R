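# Binding equilibria: exact mass balance, two-state fast-exchange shift
# model, three-state (inactive-apo / inactive-ligand / active-ligand)
# population model, and least-squares fits of both.

#' Exact free-ligand concentration from mass balance
#'
#' Solves the ligand mass-balance equation exactly, without the usual
#' ligand-excess approximation, so that fitted dissociation constants remain
#' correct even when the protein concentration is not negligible against KD.
#'
#' For the two-state model (one binding-competent protein state with
#' dissociation constant `kd_mM`) the solution is the positive root of the
#' standard quadratic. For the three-state model the protein partitions into
#' an apo state and two ligand-bound states (inactive-bound and
#' active-bound) with apparent dissociation constants `kd_inactive_mM` and
#' `kd_active_mM`, both defined from the apo state; the balance is then
#' solved by a monotone one-dimensional root find.
#'
#' @param ligand_mM Total ligand concentration (mM), scalar or vector.
#' @param protein_mM Total protein concentration (mM).
#' @param kd_mM Two-state dissociation constant (mM). Supply either this or
#'   the pair of apparent constants.
#' @param kd_inactive_mM,kd_active_mM Apparent dissociation constants (mM)
#'   of the inactive-bound and active-bound states, both relative to the
#'   apo state (three-state model).
#' @return Free ligand concentration(s) in mM.
#' @examples
#' free_ligand(1.7, 0.1, kd_mM = 1.7)
#' free_ligand(2, 0.1, kd_inactive_mM = 1.4, kd_active_mM = 0.2)
#' @export
free_ligand <- function(ligand_mM, protein_mM, kd_mM = NULL,
                        kd_inactive_mM = NULL, kd_active_mM = NULL) {
  if (any(ligand_mM < 0) || protein_mM < 0) {
    abort("Concentrations must be non-negative.")
  }
  if (!is.null(kd_mM)) {
    if (kd_mM <= 0) abort("`kd_mM` must be positive.")
    # L_f^2 + (KD + P - L) L_f - KD L = 0, positive root
    b <- kd_mM + protein_mM - ligand_mM
    lf <- (-b + sqrt(b^2 + 4 * kd_mM * ligand_mM)) / 2
    return(pmax(lf, 0))
  }
  if (is.null(kd_inactive_mM) || is.null(kd_active_mM)) {
    abort("Supply `kd_mM` or both `kd_inactive_mM` and `kd_active_mM`.")
  }
  if (kd_inactive_mM <= 0 || kd_active_mM <= 0) {
    abort("Apparent dissociation constants must be positive.")
  }
  vapply(ligand_mM, function(L) {
    if (L == 0) return(0)
    # bound fraction of protein at free ligand x
    bound <- function(x) {
      w <- x / kd_inactive_mM + x / kd_active_mM
      w / (1 + w)
    }
    g <- function(x) x + protein_mM * bound(x) - L
    uniroot(g, c(0, L), tol = 1e-13 * max(1, L))$root
  }, numeric(1))
}

#' Observed chemical shift under the two-state fast-exchange model
#'
#' Population-weighted average shift of a reporter in fast exchange between
#' the free and ligand-bound protein states, with the bound fraction
#' computed from the exact free-ligand solution.
#'
#' @inheritParams free_ligand
#' @param delta_free_ppm,delta_bound_ppm Shifts of the free and bound
#'   states (ppm).
#' @return Observed shift(s) in ppm.
#' @examples
#' two_state_shift(0:20, 0.1, kd_mM = 1.7,
#'                 delta_free_ppm = 18.0, delta_bound_ppm = 18.5)
#' @export
two_state_shift <- function(ligand_mM, protein_mM, kd_mM,
                            delta_free_ppm, delta_bound_ppm) {
  lf <- free_ligand(ligand_mM, protein_mM, kd_mM = kd_mM)
  p_bound <- lf / (kd_mM + lf)
  delta_free_ppm + p_bound * (delta_bound_ppm - delta_free_ppm)
}

#' Three-state equilibrium populations
#'
#' Populations of the apo inactive state (p1), the ligand-bound inactive
#' state (p2) and the ligand-bound active state (p3) at exact mass balance.
#' Both bound states are parameterised by apparent dissociation constants
#' from state 1, matching the equilibrium scheme used to fit titrations in
#' which ligand binding to the inactive conformation is fast on the NMR
#' timescale while the inactive-to-active transition is slow.
#'
#' @inheritParams free_ligand
#' @return A tibble with columns `ligand_mM`, `ligand_free_mM`, `p1`, `p2`,
#'   `p3`. Populations sum to one.
#' @examples
#' three_state_populations(c(0, 1, 5, 20), 0.1,
#'                         kd_inactive_mM = 1.4, kd_active_mM = 0.2)
#' @export
three_state_populations <- function(ligand_mM, protein_mM,
                                    kd_inactive_mM, kd_active_mM) {
  lf <- free_ligand(ligand_mM, protein_mM,
                    kd_inactive_mM = kd_inactive_mM,
                    kd_active_mM = kd_active_mM)
  w2 <- lf / kd_inactive_mM
  w3 <- lf / kd_active_mM
  z <- 1 + w2 + w3
  tibble(
    ligand_mM = ligand_mM,
    ligand_free_mM = lf,
    p1 = 1 / z,
    p2 = w2 / z,
    p3 = w3 / z
  )
}

# Shift of the fast-exchange reporter within the inactive sub-ensemble
# (states 1 and 2) plus active-reporter intensity, given three-state params.
three_state_observables <- function(ligand_mM, protein_mM, kd_inactive_mM,
                                    kd_active_mM, delta_free_ppm,
                                    delta_bound_ppm, intensity_scale) {
  pops <- three_state_populations(ligand_mM, protein_mM,
                                  kd_inactive_mM, kd_active_mM)
  f12 <- ifelse(pops$p1 + pops$p2 > 0,
                pops$p2 / (pops$p1 + pops$p2), 0)
  mutate(pops,
         shift_ppm = delta_free_ppm + f12 * (delta_bound_ppm - delta_free_ppm),
         intensity = intensity_scale * .data$p3)
}

#' Association rate from dissociation rate and affinity
#'
#' `kon = koff / KD` with the dissociation constant converted from mM to M,
#' so the result is in the conventional M^-1 s^-1.
#'
#' @param koff Dissociation rate constant (s^-1).
#' @param kd_mM Dissociation constant (mM).
#' @return Association rate constant in M^-1 s^-1.
#' @examples
#' kon_from_koff(1600, 1.3) # ~1.2e6
#' @export
kon_from_koff <- function(koff, kd_mM) {
  if (any(koff <= 0) || any(kd_mM <= 0)) {
    abort("`koff` and `kd_mM` must be positive.")
  }
  koff / (kd_mM * 1e-3)
}

# ---- fitting -------------------------------------------------------------

# Data-driven KD starting guesses: concentration at half-maximal response,
# log-spaced multi-start around it.
kd_starts <- function(ligand, response, n = 10) {
  dr <- abs(response - response[which.min(ligand)])
  half <- max(dr) / 2
  above <- which(dr >= half & ligand > 0)
  guess <- if (length(above) > 0) ligand[min(above)] else median(ligand[ligand > 0])
  guess <- max(guess, 1e-3)
  exp(seq(log(guess / 10), log(guess * 10), length.out = n))
}

new_allofit_fit <- function(x, subclass) {
  structure(x, class = c(subclass, "allofit_fit"))
}

#' @export
print.allofit_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Fit the two-state fast-exchange binding model to a titration series
#'
#' Least-squares fit of `KD`, `delta_free` and `delta_bound` to observed
#' reporter shifts versus total ligand concentration, using the exact
#' free-ligand solution, Levenberg-Marquardt optimisation and ten
#' log-spaced multi-starts around a half-saturation KD guess. Parameter
#' uncertainties come from the Jacobian-based covariance; a jackknife
#' (leave-one-point-out) option is available.
#'
#' @param data A data frame with columns `ligand_mM`, `shift_ppm` and
#'   optionally `shift_sd` (per-point SD used as weights) and `protein_mM`.
#' @param protein_mM Total protein concentration (mM); only needed when
#'   `data` has no `protein_mM` column.
#' @param jackknife If `TRUE`, parameter SDs are recomputed by the
#'   jackknife over titration points.
#' @return An object of class `allofit_two_state` with `tidy()`,
#'   `glance()`, `augment()` and `autoplot()` methods. Estimates are in
#'   `$estimate` (named list with `kd_mM`, `delta_free_ppm`,
#'   `delta_bound_ppm`) with SDs in `$sd`.
#' @examples
#' tit <- sim_titration(kd_mM = 1.7, delta_free_ppm = 18, delta_bound_ppm = 18.5,
#'                      ligand_mM = seq(0, 20, length.out = 12),
#'                      protein_mM = 0.1, noise_sd = 0, seed = 1)
#' fit_two_state(tit)
#' @export
fit_two_state <- function(data, protein_mM = NULL, jackknife = FALSE) {
  check_column(data, c("ligand_mM", "shift_ppm"), "fit_two_state")
  if (nrow(data) < 4) abort("At least 4 titration points are required.")
  P <- data$protein_mM[1] %||% protein_mM
  if ("protein_mM" %in% names(data)) P <- data$protein_mM[1]
  if (is.null(P)) abort("Supply `protein_mM` (argument or column).")
  L <- data$ligand_mM
  y <- data$shift_ppm
  w <- if ("shift_sd" %in% names(data) && all(data$shift_sd > 0)) {
    1 / data$shift_sd
  } else {
    rep(1, length(y))
  }

  # identifiability: response must rise above the noise floor
  noise <- if ("shift_sd" %in% names(data)) {
    mean(data$shift_sd)
  } else {
    sd(diff(y)) / sqrt(2)
  }
  if (!is.finite(noise)) noise <- 0
  if (diff(range(y)) < 3 * noise || diff(range(y)) == 0) {
    abort(paste(
      "fit_two_state: shift range is below 3x the noise level;",
      "KD is not identifiable from this series."
    ), class = "allofit_identifiability_error")
  }

  resid_fn <- function(par) {
    mdl <- two_state_shift(L, P, exp(par[1]), par[2], par[3])
    w * (y - mdl)
  }
  fit1 <- function(kd0) {
    start <- c(log(kd0), y[which.min(L)], y[which.max(L)])
    minpack.lm::nls.lm(start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fits <- lapply(kd_starts(L, y), function(k0) {
    tryCatch(fit1(k0), error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) abort("fit_two_state: optimisation failed.")
  best <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]

  par <- best$par
  se <- nls_lm_se(best)
  est <- list(kd_mM = exp(par[1]), delta_free_ppm = par[2],
              delta_bound_ppm = par[3])
  sds <- c(kd_mM = exp(par[1]) * se[1], delta_free_ppm = se[2],
           delta_bound_ppm = se[3])

  if (isTRUE(jackknife)) {
    th <- vapply(seq_along(L), function(i) {
      d <- data[-i, , drop = FALSE]
      f <- fit_two_state(d, protein_mM = P, jackknife = FALSE)
      unlist(f$estimate)
    }, numeric(3))
    nn <- ncol(th)
    sds <- sqrt((nn - 1) / nn * rowSums((th - rowMeans(th))^2))
    names(sds) <- c("kd_mM", "delta_free_ppm", "delta_bound_ppm")
  }

  new_allofit_fit(list(
    estimate = est, sd = as.list(sds), data = as_tibble(data),
    protein_mM = P, deviance = best$deviance,
    df_residual = length(y) - 3L, fit = best
  ), "allofit_two_state")
}

#' Fit the three-state binding/activation model jointly to shift and
#' intensity observables
#'
#' Joint weighted least squares over a fast-exchange reporter shift (which
#' tracks the apo vs ligand-bound balance of the inactive conformation)
#' and a slow-exchange active-state reporter intensity (proportional to
#' the active-state population). Returns both apparent dissociation
#' constants, the shift endpoints and the intensity scale.
#'
#' @param data A data frame with columns `ligand_mM`, `shift_ppm`,
#'   `intensity` and optionally `shift_sd`, `intensity_sd`, `protein_mM`.
#' @inheritParams fit_two_state
#' @return An object of class `allofit_three_state` with the usual
#'   broom-style methods. Estimates: `kd_inactive_mM`, `kd_active_mM`,
#'   `delta_free_ppm`, `delta_bound_ppm`, `intensity_scale`.
#' @export
fit_three_state <- function(data, protein_mM = NULL, jackknife = FALSE) {
  check_column(data, c("ligand_mM", "shift_ppm", "intensity"),
               "fit_three_state")
  if (nrow(data) < 4) abort("At least 4 titration points are required.")
  P <- if ("protein_mM" %in% names(data)) data$protein_mM[1] else protein_mM
  if (is.null(P)) abort("Supply `protein_mM` (argument or column).")
  if (all(data$intensity == 0)) {
    abort(paste(
      "fit_three_state: the intensity observable is identically zero;",
      "the active-state apparent KD is not identifiable."
    ), class = "allofit_identifiability_error")
  }
  L <- data$ligand_mM
  ys <- data$shift_ppm
  yi <- data$intensity
  ws <- if ("shift_sd" %in% names(data) && all(data$shift_sd > 0)) {
    1 / data$shift_sd
  } else {
    rep(1 / max(1e-12, diff(range(ys)) / 50), length(ys))
  }
  wi <- if ("intensity_sd" %in% names(data) && all(data$intensity_sd > 0)) {
    1 / data$intensity_sd
  } else {
    rep(1 / max(1e-12, max(yi) * 0.02), length(yi))
  }

  resid_fn <- function(par) {
    obs <- three_state_observables(L, P, exp(par[1]), exp(par[2]),
                                   par[3], par[4], exp(par[5]))
    c(ws * (ys - obs$shift_ppm), wi * (yi - obs$intensity))
  }
  kd0s <- kd_starts(L, ys)
  fits <- lapply(kd0s, function(k0) {
    start <- c(log(k0), log(k0 / 4), ys[which.min(L)], ys[which.max(L)],
               log(max(yi) * 1.2))
    tryCatch(
      minpack.lm::nls.lm(start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) abort("fit_three_state: optimisation failed.")
  best <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]

  par <- best$par
  se <- nls_lm_se(best)
  est <- list(kd_inactive_mM = exp(par[1]), kd_active_mM = exp(par[2]),
              delta_free_ppm = par[3], delta_bound_ppm = par[4],
              intensity_scale = exp(par[5]))
  sds <- list(kd_inactive_mM = exp(par[1]) * se[1],
              kd_active_mM = exp(par[2]) * se[2],
              delta_free_ppm = se[3], delta_bound_ppm = se[4],
              intensity_scale = exp(par[5]) * se[5])

  if (isTRUE(jackknife)) {
    th <- vapply(seq_len(nrow(data)), function(i) {
      f <- fit_three_state(data[-i, , drop = FALSE], protein_mM = P)
      unlist(f$estimate)
    }, numeric(5))
    nn <- ncol(th)
    jk <- sqrt((nn - 1) / nn * rowSums((th - rowMeans(th))^2))
    sds <- as.list(setNames(jk, names(est)))
  }

  new_allofit_fit(list(
    estimate = est, sd = sds, data = as_tibble(data), protein_mM = P,
    deviance = best$deviance, df_residual = 2L * length(L) - 5L, fit = best
  ), "allofit_three_state")
}

#' Saturating-limit active fraction from apparent dissociation constants
#'
#' In the saturating-ligand limit of the three-state model the apo state
#' vanishes and the active fraction of the bound ensemble tends to
#' `kd_inactive / (kd_inactive + kd_active)`.
#'
#' @inheritParams free_ligand
#' @return Limiting active fraction (0-1).
#' @examples
#' saturation_active_fraction(1.4, 0.2) # 0.875
#' @export
saturation_active_fraction <- function(kd_inactive_mM, kd_active_mM) {
  if (kd_inactive_mM <= 0 || kd_active_mM <= 0) {
    abort("Apparent dissociation constants must be positive.")
  }
  kd_inactive_mM / (kd_inactive_mM + kd_active_mM)
}
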