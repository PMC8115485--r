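# Ensemble-allostery thermodynamics: populations from peak volumes,
# conformational equilibrium constants and free energies, mutational
# destabilisation energies, the ln(kcat) ~ ddG linkage, and the exact
# permutation Spearman test.

#' Active-state population from per-reporter peak-volume pairs
#'
#' For each reporter resonance resolved in both conformations the active
#' fraction is `V_active / (V_active + V_inactive)`; the returned
#' population is the mean over reporters with its standard deviation.
#' Reporters whose two volumes are both zero carry no information and are
#' dropped with a warning.
#'
#' @param data A data frame with columns `volume_inactive` and
#'   `volume_active` (one row per reporter).
#' @return A tibble with `p_active`, `p_sd`, `n_reporters` and a logical
#'   `sd_defined` flag (FALSE when only one usable reporter remains, in
#'   which case `p_sd` is 0).
#' @examples
#' v <- sim_peak_volumes(0.78, n_reporters = 8, noise_sd = 0.03, seed = 1)
#' population_from_volumes(v)
#' @export
population_from_volumes <- function(data) {
  check_column(data, c("volume_inactive", "volume_active"),
               "population_from_volumes")
  if (any(data$volume_inactive < 0) || any(data$volume_active < 0)) {
    abort("Peak volumes must be non-negative.")
  }
  tot <- data$volume_inactive + data$volume_active
  if (all(tot == 0)) abort("All reporters have zero total volume.")
  if (any(tot == 0)) {
    warn(sprintf("Dropping %d reporter(s) with zero total volume.",
                 sum(tot == 0)))
  }
  frac <- data$volume_active[tot > 0] / tot[tot > 0]
  sd_defined <- length(frac) > 1
  tibble(
    p_active = mean(frac),
    p_sd = if (sd_defined) sd(frac) else 0,
    n_reporters = length(frac),
    sd_defined = sd_defined
  )
}

#' Conformational equilibrium constant from the active-state population
#'
#' `K_a = p / (1 - p)`, the ratio of active to inactive populations.
#'
#' @param p Active-state population, strictly inside (0, 1).
#' @return The equilibrium constant.
#' @examples
#' ka_from_population(0.78)
#' @export
ka_from_population <- function(p) {
  if (any(p <= 0) || any(p >= 1)) {
    abort(paste(
      "Population must be strictly inside (0, 1);",
      "at the boundaries the equilibrium constant is 0 or infinite."
    ), class = "allofit_boundary_population_error")
  }
  p / (1 - p)
}

#' Free-energy gap from an equilibrium constant
#'
#' `dG = -RT ln(K_a)` in kJ/mol with R = 8.3145 J mol^-1 K^-1.
#'
#' @param ka Equilibrium constant (> 0).
#' @param temperature Temperature (K), default 303.15.
#' @return Free energy difference in kJ/mol (negative when the active
#'   state is favoured).
#' @examples
#' delta_g(ka_from_population(0.78))
#' @export
delta_g <- function(ka, temperature = 303.15) {
  if (any(ka <= 0)) abort("`ka` must be positive.")
  -rt_kj(temperature) * log(ka)
}

#' Mutational/ligand destabilisation of the active conformation
#'
#' `ddG = dG(p_mut) - dG(p_ref)`: the change in the inactive-active
#' free-energy gap caused by a mutation or by a weaker-activating ligand,
#' relative to a reference condition.
#'
#' @param p_mut,p_ref Active-state populations of the perturbed and
#'   reference conditions, strictly inside (0, 1).
#' @inheritParams delta_g
#' @return ddG in kJ/mol (positive = active state destabilised).
#' @examples
#' ddg_mut(0.36, 0.78) # ~ +4.6 kJ/mol
#' @export
ddg_mut <- function(p_mut, p_ref, temperature = 303.15) {
  delta_g(ka_from_population(p_mut), temperature) -
    delta_g(ka_from_population(p_ref), temperature)
}

#' Predicted turnover from the ensemble linkage
#'
#' Under the ensemble allosteric model with a sparsely populated active
#' state, `kcat_mut = kcat_ref * exp(-ddG / RT)`.
#'
#' @param kcat_ref Reference turnover number (any rate unit; the result is
#'   in the same unit).
#' @param ddg Destabilisation free energy (kJ/mol).
#' @inheritParams delta_g
#' @return Predicted turnover number.
#' @examples
#' predict_kcat(63, ddg_mut(0.52, 0.78)) # ~19 min^-1
#' @export
predict_kcat <- function(kcat_ref, ddg, temperature = 303.15) {
  if (any(kcat_ref <= 0)) abort("`kcat_ref` must be positive.")
  kcat_ref * exp(-ddg / rt_kj(temperature))
}

#' Build a thermodynamic linkage table from condition records
#'
#' Takes one row per condition (ligand and/or mutant) with the measured
#' active-state population and turnover number, and derives the
#' equilibrium constant, free-energy gap, destabilisation energy relative
#' to the reference condition, and the linkage-predicted turnover.
#' Population SDs are propagated to `ddg_sd` by the first-order delta
#' method.
#'
#' @param data A data frame with columns `label`, `p_active`, `kcat` and
#'   optionally `p_sd`, `kcat_sd`.
#' @param reference Label of the reference condition (default
#'   `"ProFAR"`).
#' @inheritParams delta_g
#' @return A tibble with the input columns plus `ka`, `dG_kJmol`,
#'   `ddg_kJmol`, `ddg_sd`, `ln_kcat` and `kcat_predicted`.
#' @examples
#' thermo_table(hisfh_conditions())
#' @export
thermo_table <- function(data, reference = "ProFAR", temperature = 303.15) {
  check_column(data, c("label", "p_active", "kcat"), "thermo_table")
  if (!reference %in% data$label) {
    abort(sprintf("Reference condition '%s' not found.", reference))
  }
  rt <- rt_kj(temperature)
  ref <- data[data$label == reference, ]
  p_ref <- ref$p_active[1]
  p_ref_sd <- if ("p_sd" %in% names(data)) ref$p_sd[1] else NA_real_

  # d(dG)/dp = -RT / (p (1 - p))
  dg_sd <- function(p, psd) rt * psd / (p * (1 - p))

  out <- mutate(as_tibble(data),
    ka = ka_from_population(.data$p_active),
    dG_kJmol = delta_g(.data$ka, temperature),
    ddg_kJmol = .data$dG_kJmol - delta_g(ka_from_population(p_ref),
                                         temperature),
    ln_kcat = log(.data$kcat),
    kcat_predicted = predict_kcat(ref$kcat[1], .data$ddg_kJmol, temperature)
  )
  if ("p_sd" %in% names(data) && !is.na(p_ref_sd)) {
    out <- mutate(out, ddg_sd = sqrt(
      dg_sd(.data$p_active, dplyr::coalesce(.data$p_sd, 0))^2 +
        dg_sd(p_ref, p_ref_sd)^2
    ))
  }
  attr(out, "reference") <- reference
  attr(out, "temperature") <- temperature
  out
}

#' Weighted fit of ln(kcat) against the destabilisation energy
#'
#' The ensemble linkage predicts
#' `ln(kcat_mut) = ln(kcat_ref) - ddG / RT`, a line of slope `-1/RT`.
#' In `slope = "fixed"` mode the slope is pinned at `-1/RT` and only the
#' intercept is estimated (weighted mean of `ln_kcat + ddg/RT`); in
#' `slope = "free"` mode both are fit by (weighted) least squares, which
#' serves as a consistency test of the linkage.
#'
#' @param data A thermo table (see [thermo_table()]) or any data frame
#'   with columns `ddg_kJmol` and `ln_kcat` (or `kcat`); optional
#'   `kcat_sd` provides weights `1/var(ln kcat)`.
#' @param slope `"fixed"` or `"free"`.
#' @inheritParams delta_g
#' @return An object of class `allofit_linkage` with `tidy()`/`glance()`;
#'   estimates `intercept` (and `slope` when free), and the implied
#'   reference `kcat`.
#' @examples
#' fit_lnkcat_vs_ddg(thermo_table(hisfh_conditions()), slope = "fixed")
#' @export
fit_lnkcat_vs_ddg <- function(data, slope = c("fixed", "free"),
                              temperature = 303.15) {
  slope <- match.arg(slope)
  check_column(data, "ddg_kJmol", "fit_lnkcat_vs_ddg")
  if (!"ln_kcat" %in% names(data)) {
    check_column(data, "kcat", "fit_lnkcat_vs_ddg")
    data$ln_kcat <- log(data$kcat)
  }
  d <- data[is.finite(data$ddg_kJmol) & is.finite(data$ln_kcat), ]
  if (nrow(d) < 2 && slope == "free") {
    abort("At least 2 conditions with finite ddG are required.")
  }
  if (nrow(d) < 1) abort("No conditions with finite ddG.")
  rt <- rt_kj(temperature)
  w <- if ("kcat_sd" %in% names(d) && all(!is.na(d$kcat_sd)) &&
           all(d$kcat_sd > 0)) {
    (d$kcat / d$kcat_sd)^2 # var(ln k) ~ (sd_k / k)^2
  } else {
    rep(1, nrow(d))
  }

  if (slope == "fixed") {
    z <- d$ln_kcat + d$ddg_kJmol / rt
    intercept <- sum(w * z) / sum(w)
    int_se <- if (nrow(d) > 1) {
      sqrt(sum(w * (z - intercept)^2) / ((nrow(d) - 1) * sum(w)))
    } else {
      NA_real_
    }
    est <- list(intercept = intercept, slope = -1 / rt)
    sds <- list(intercept = int_se, slope = 0)
    resid <- d$ln_kcat - (intercept - d$ddg_kJmol / rt)
    model <- NULL
  } else {
    if (var(d$ddg_kJmol) == 0) {
      abort("All ddG values are equal; the free slope is rank deficient.",
            class = "allofit_rank_deficiency_error")
    }
    model <- lm(ln_kcat ~ ddg_kJmol, data = d, weights = w)
    cf <- summary(model)$coefficients
    est <- list(intercept = cf[1, 1], slope = cf[2, 1])
    sds <- list(intercept = cf[1, 2], slope = cf[2, 2])
    resid <- stats::residuals(model)
  }

  new_allofit_fit(list(
    estimate = est, sd = sds, slope_mode = slope,
    kcat_ref_implied = exp(est$intercept), temperature = temperature,
    residuals = resid, data = as_tibble(d), model = model,
    deviance = sum(w * resid^2),
    df_residual = nrow(d) - if (slope == "fixed") 1L else 2L
  ), "allofit_linkage")
}

# ---- exact Spearman permutation test ------------------------------------

# all permutations of 1..n as an n! x n matrix (n <= 8 kept small)
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with an exact permutation p-value
#'
#' Computes the Spearman rank correlation (midranks for ties) and its
#' permutation p-value. For `n <= 8` the p-value is exact, from full
#' enumeration of all `n!` rank permutations; for larger samples a normal
#' approximation (`z = rs * sqrt(n - 1)`) is used.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A tibble with `rs`, `p_value`, `n` and `method` ("exact
#'   enumeration" or "normal approximation").
#' @examples
#' spearman_exact(1:7, c(2, 3, 5, 8, 13, 21, 34)) # rs = 1, p = 2/5040
#' @export
spearman_exact <- function(x, y,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("At least 3 observations are required.")
  if (var(x) == 0 || var(y) == 0) {
    abort("Constant input: the rank correlation is undefined.",
          class = "allofit_constant_input_error")
  }
  rx <- rank(x) # midranks for ties
  ry <- rank(y)
  rs_of <- function(perm_ry) {
    cxy <- sum((rx - mean(rx)) * (perm_ry - mean(ry)))
    cxy / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  rs <- rs_of(ry)

  if (n <= 8) {
    P <- perm_matrix(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rs_all <- as.vector((matrix(ryc[P], nrow(P), n) %*% rxc) / denom)
    eps <- 1e-12
    p <- switch(alternative,
      two.sided = mean(abs(rs_all) >= abs(rs) - eps),
      greater = mean(rs_all >= rs - eps),
      less = mean(rs_all <= rs + eps)
    )
    method <- "exact enumeration"
  } else {
    z <- rs * sqrt(n - 1)
    p <- switch(alternative,
      two.sided = 2 * pnorm(-abs(z)),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z)
    )
    method <- "normal approximation"
  }
  tibble(rs = rs, p_value = p, n = n, method = method)
}
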