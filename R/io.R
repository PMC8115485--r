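# Shared table I/O: all datasets travel as headered TSV (decimal point,
# one observable per column); condition tables as CSV.

#' Read or write an analysis table as TSV
#'
#' Thin wrappers around readr with the column conventions used throughout
#' the package: titration series (`ligand_mM`, `shift_ppm`, `shift_sd`,
#' optionally `intensity`, `intensity_sd`, `protein_mM`), ZZ datasets
#' (`time_s`, `I_II`, `I_AA`, `I_IA`, `I_AI` + `_sd`), spectrum series
#' (`ligand_mM`, `frequency_hz`, `intensity`), kinetic traces (`time_s`,
#' `gln_integral`, `glu_integral`), and volume tables (`reporter`,
#' `volume_inactive`, `volume_active`).
#'
#' @param path File path.
#' @param data A data frame to write.
#' @return `read_table_tsv()` returns a tibble; `write_table_tsv()`
#'   returns `data` invisibly.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_table_tsv
#' @export
write_table_tsv <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(data)
}
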