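#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.read_delim_auto <- function(file) {
  first <- readLines(file, n = 1)
  if (grepl("\t", first)) readr::read_tsv(file, show_col_types = FALSE)
  else readr::read_csv(file, show_col_types = FALSE)
}

.require_cols <- function(d, cols, what) {
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols)) {
    abort(paste0(what, " file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  d
}

#' Read a titration table (CSV/TSV)
#'
#' Expects a header with `conc_M` (molar) and `fp` or `response`; an
#' optional `replicate` column is kept.
#'
#' @param file Path.
#' @return A tibble.
#' @export
read_titration <- function(file) {
  d <- .read_delim_auto(file)
  if (!"conc_M" %in% names(d) || !any(c("fp", "response") %in% names(d))) {
    abort("titration file needs columns conc_M and fp (or response)")
  }
  d
}

#' Read a serum-decay table (CSV/TSV): columns `time_min`, `fraction`
#'
#' @param file Path.
#' @return A tibble.
#' @export
read_decay <- function(file) {
  .require_cols(.read_delim_auto(file), c("time_min", "fraction"), "decay")
}

#' Read a chemical-shift table (CSV/TSV): columns `res_index`, `token`,
#' `ha_ppm`
#'
#' @param file Path.
#' @return A tibble.
#' @export
read_shift_table <- function(file) {
  .require_cols(.read_delim_auto(file), c("res_index", "token", "ha_ppm"),
                "shift")
}

#' Read an observed-mass list (CSV/TSV): column `mass_da`
#'
#' @param file Path.
#' @return Numeric vector of masses (Da).
#' @export
read_masses <- function(file) {
  .require_cols(.read_delim_auto(file), "mass_da", "mass")$mass_da
}

#' Write a per-residue profile as TSV
#'
#' @param profile A tibble (e.g. from [sasa()] or [buried_area()]).
#' @param file Path.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, file) {
  readr::write_tsv(profile, file)
  invisible(file)
}

#' Shipped buried-area exposure fixture for the Cul3 helix-2 peptide
#'
#' A per-residue buried-area profile over positions 49-68 reflecting the
#' interface structure of the peptide-receptor complex: interface hot spots
#' at Phe54, Tyr58 and Tyr62 (one helical face), completely solvent-exposed
#' residues at Glu56, Leu57, Asn60 and Ala61, and intermediate burial
#' elsewhere. Used by the staple-design examples and tests.
#'
#' @return A tibble with `res_index` and `buried` (Angstrom^2).
#' @export
cul3_exposure_fixture <- function() {
  tibble(
    res_index = 49:68,
    buried = c(20, 12, 15, 25, 30, 80, 18, 0, 2, 95, 28, 0, 1, 90,
               22, 16, 26, 14, 11, 10)
  )
}
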