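#' Measured HisFH condition table
#'
#' Active-conformation populations (mean and SD over eight reporter
#' resonances, determined in the slow-hydrolysis hC84S background) and
#' glutaminase turnover numbers (WT background, min^-1) for the HisFH
#' complex under different activating ligands and HisF point mutations.
#' The reference condition is the WT complex saturated with ProFAR and
#' Gln. The fD98E complex is shifted essentially completely to the active
#' conformation; its population is encoded as 0.99 by convention (see the
#' `note` column), which fixes its rank but makes its ddG a convention,
#' not a measurement.
#'
#' @param file Optional path to an alternative CSV with the same columns
#'   (`label`, `p_active`, `p_sd`, `kcat`, `kcat_sd`, `note`).
#' @return A tibble, one row per condition.
#' @examples
#' hisfh_conditions()
#' @export
hisfh_conditions <- function(file = NULL) {
  path <- file %||% system.file("extdata", "hisfh_conditions.csv",
                                package = "allofit", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    label = readr::col_character(),
                    note = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
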