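# broom-style tidy()/glance()/augment() methods for the fitted objects.

tidy_from_est <- function(x) {
  tibble(
    term = names(x$estimate),
    estimate = unname(unlist(x$estimate)),
    std.error = unname(unlist(x$sd))[seq_along(x$estimate)]
  )
}

#' @export
tidy.allofit_fit <- function(x, ...) tidy_from_est(x)

#' @export
tidy.allofit_zz <- function(x, ...) {
  out <- tidy_from_est(x)
  bind_rows(out, tibble(term = "p_active", estimate = x$p_active,
                        std.error = NA_real_))
}

#' @export
glance.allofit_fit <- function(x, ...) {
  tibble(deviance = x$deviance, df.residual = x$df_residual,
         nobs = x$df_residual + (length(x$estimate)))
}

#' @export
glance.allofit_lineshape <- function(x, ...) {
  tibble(deviance = x$deviance, df.residual = x$df_residual,
         kon = x$kon, koff_is_bound = x$koff_is_bound)
}

#' @export
glance.allofit_turnover <- function(x, ...) {
  tibble(kcat_min = x$estimate$kcat_min, kcat_sd = x$sd$kcat_min,
         n_points = x$n_points, window = x$window)
}

#' @export
augment.allofit_two_state <- function(x, ...) {
  e <- x$estimate
  mutate(x$data,
         .fitted = two_state_shift(.data$ligand_mM, x$protein_mM,
                                   e$kd_mM, e$delta_free_ppm,
                                   e$delta_bound_ppm),
         .resid = .data$shift_ppm - .data$.fitted)
}

#' @export
augment.allofit_three_state <- function(x, ...) {
  e <- x$estimate
  obs <- three_state_observables(x$data$ligand_mM, x$protein_mM,
                                 e$kd_inactive_mM, e$kd_active_mM,
                                 e$delta_free_ppm, e$delta_bound_ppm,
                                 e$intensity_scale)
  mutate(x$data,
         .fitted_shift = obs$shift_ppm,
         .fitted_intensity = obs$intensity,
         .resid_shift = .data$shift_ppm - obs$shift_ppm,
         .resid_intensity = .data$intensity - obs$intensity)
}

#' @export
augment.allofit_zz <- function(x, ...) {
  e <- x$estimate
  m <- zz_intensities(e$k_IA, e$k_AI, e$R1_I, e$R1_A, x$data$time_s,
                      amp_I = e$amp_I, amp_A = e$amp_A)
  out <- x$data
  for (col in c("I_II", "I_AA", "I_IA", "I_AI")) {
    out[[paste0(".fitted_", col)]] <- m[[col]]
  }
  out
}
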