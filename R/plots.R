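# ggplot2 autoplot methods for the fitted objects.

#' @export
autoplot.allofit_two_state <- function(object, n_curve = 200, ...) {
  e <- object$estimate
  grid <- tibble(ligand_mM = seq(min(object$data$ligand_mM),
                                 max(object$data$ligand_mM),
                                 length.out = n_curve))
  grid$shift_ppm <- two_state_shift(grid$ligand_mM, object$protein_mM,
                                    e$kd_mM, e$delta_free_ppm,
                                    e$delta_bound_ppm)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$ligand_mM, .data$shift_ppm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#2166ac") +
    ggplot2::labs(
      x = "ligand (mM)", y = "observed shift (ppm)",
      title = sprintf("Two-state fit: KD = %.2f mM", e$kd_mM)
    )
}

#' @export
autoplot.allofit_three_state <- function(object, n_curve = 200, ...) {
  e <- object$estimate
  grid_l <- seq(min(object$data$ligand_mM), max(object$data$ligand_mM),
                length.out = n_curve)
  obs <- three_state_observables(grid_l, object$protein_mM,
                                 e$kd_inactive_mM, e$kd_active_mM,
                                 e$delta_free_ppm, e$delta_bound_ppm,
                                 e$intensity_scale)
  long_d <- tidyr::pivot_longer(
    select(object$data, "ligand_mM", "shift_ppm", "intensity"),
    -"ligand_mM", names_to = "observable", values_to = "value")
  long_m <- tidyr::pivot_longer(
    select(obs, "ligand_mM", "shift_ppm", "intensity"),
    -"ligand_mM", names_to = "observable", values_to = "value")
  ggplot2::ggplot(long_d, ggplot2::aes(.data$ligand_mM, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = long_m, colour = "#b2182b") +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "ligand (mM)", y = NULL,
                  title = sprintf(
                    "Three-state fit: KD,app = %.2f / %.2f mM",
                    e$kd_inactive_mM, e$kd_active_mM))
}

#' @export
autoplot.allofit_zz <- function(object, n_curve = 200, ...) {
  e <- object$estimate
  tgrid <- seq(0, max(object$data$time_s), length.out = n_curve)
  m <- zz_intensities(e$k_IA, e$k_AI, e$R1_I, e$R1_A, tgrid,
                      amp_I = e$amp_I, amp_A = e$amp_A)
  cols <- c("I_II", "I_AA", "I_IA", "I_AI")
  long_d <- tidyr::pivot_longer(select(object$data, "time_s",
                                       dplyr::all_of(cols)),
                                -"time_s", names_to = "peak",
                                values_to = "intensity")
  long_m <- tidyr::pivot_longer(m, -"time_s", names_to = "peak",
                                values_to = "intensity")
  ggplot2::ggplot(long_d, ggplot2::aes(.data$time_s, .data$intensity,
                                       colour = .data$peak)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = long_m) +
    ggplot2::labs(x = "mixing time (s)", y = "intensity",
                  title = sprintf(
                    "ZZ-exchange fit: k(I>A) = %.1f, k(A>I) = %.1f s-1",
                    e$k_IA, e$k_AI))
}

#' @export
autoplot.allofit_linkage <- function(object, ...) {
  e <- object$estimate
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$ddg_kJmol, .data$ln_kcat)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = e$intercept, slope = e$slope,
                         colour = "#b2182b") +
    ggplot2::labs(x = expression(Delta * Delta * G^mut ~ "(kJ/mol)"),
                  y = expression(ln(k[cat])),
                  title = sprintf("Linkage fit (%s slope)",
                                  object$slope_mode))
}

#' Plot a simulated or measured spectrum series
#'
#' @param data Long-format spectra (`ligand_mM`, `frequency_hz`,
#'   `intensity`).
#' @return A ggplot object, one line per titration point.
#' @export
plot_spectrum_series <- function(data) {
  check_column(data, c("ligand_mM", "frequency_hz", "intensity"),
               "plot_spectrum_series")
  ggplot2::ggplot(data, ggplot2::aes(.data$frequency_hz, .data$intensity,
                                     colour = factor(.data$ligand_mM))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "intensity",
                  colour = "ligand (mM)")
}
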