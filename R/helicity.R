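#' Convert raw CD ellipticity to mean-residue molar ellipticity
#'
#' \[theta\] = theta_mdeg / (10 * c * l * n_res) in
#' deg cm^2 dmol^-1 residue^-1, with concentration c in molar and path
#' length l in cm.
#'
#' @param spectrum Data frame with `wavelength_nm` (strictly increasing) and
#'   `ellipticity_mdeg`.
#' @param conc_M Peptide concentration (molar).
#' @param path_cm Cuvette path length (cm).
#' @param n_residues Number of residues.
#' @return A tibble with `wavelength_nm` and `mre`.
#' @export
to_mre <- function(spectrum, conc_M, path_cm, n_residues) {
  stopifnot(all(c("wavelength_nm", "ellipticity_mdeg") %in% names(spectrum)))
  if (is.null(conc_M) || is.null(path_cm) || is.null(n_residues) ||
      conc_M <= 0 || path_cm <= 0 || n_residues <= 0) {
    abort("conversion needs positive concentration, path length and residue count")
  }
  if (any(diff(spectrum$wavelength_nm) <= 0)) {
    abort("wavelength grid must be strictly increasing")
  }
  tibble(wavelength_nm = spectrum$wavelength_nm,
         mre = spectrum$ellipticity_mdeg / (10 * conc_M * path_cm * n_residues))
}

# Two-state 222 nm helix-coil basis (deg cm^2 dmol^-1 per residue): coil
# limit and a chain-length-corrected full-helix limit.
.mre_coil_222 <- 640
.mre_helix_222 <- function(n_res) -40000 * (1 - 2.5 / n_res)

#' Approximate helix fraction from the 222 nm band
#'
#' Two-state estimate f_H = (\[theta\]222 - \[theta\]_coil) /
#' (\[theta\]_helix(n) - \[theta\]_coil), clamped to \[0, 1\], using a coil
#' limit of +640 and a chain-length-corrected helix limit of
#' -40000 (1 - 2.5/n). This is an approximate single-wavelength estimator,
#' not a basis-set spectral deconvolution; treat its output as a coarse
#' ranking, not a secondary-structure census.
#'
#' @param mre Output of [to_mre()] (nearest grid point to 222 nm is used).
#' @param n_res Number of residues.
#' @return A list with `fraction`, `mre_222`, `helix_limit`, `coil_limit`,
#'   and `method = "approximate 222 nm two-state"`.
#' @export
helix_fraction_222 <- function(mre, n_res) {
  i <- which.min(abs(mre$wavelength_nm - 222))
  m222 <- mre$mre[i]
  h <- .mre_helix_222(n_res)
  f <- (m222 - .mre_coil_222) / (h - .mre_coil_222)
  list(fraction = min(1, max(0, f)), mre_222 = m222, helix_limit = h,
       coil_limit = .mre_coil_222, method = "approximate 222 nm two-state")
}

# Random-coil H-alpha reference shifts (ppm), Wishart-style literature
# values. A documented stand-in, user-overridable; S5 is mapped to the
# alanine value (alpha-substituted alanine backbone).
.random_coil_ha <- c(
  A = 4.35, C = 4.65, D = 4.76, E = 4.29, F = 4.66, G = 3.97, H = 4.63,
  I = 4.23, K = 4.36, L = 4.38, M = 4.52, N = 4.75, P = 4.44, Q = 4.37,
  R = 4.38, S = 4.50, T = 4.35, V = 4.18, W = 4.70, Y = 4.60, S5 = 4.35
)

#' Random-coil H-alpha reference table
#'
#' @return A tibble with `token` and `ha_ppm`.
#' @export
random_coil_shifts <- function() {
  tibble(token = names(.random_coil_ha), ha_ppm = unname(.random_coil_ha))
}

#' H-alpha secondary chemical-shift profile
#'
#' Delta-delta_i = delta_obs,i - delta_randomcoil(residue type i), with no
#' smoothing. Sustained negative (upfield) runs indicate helix.
#'
#' @param shifts Data frame with `res_index`, `token`, `ha_ppm` (observed,
#'   0-12 ppm).
#' @param reference Reference table (`token`, `ha_ppm`); defaults to
#'   [random_coil_shifts()].
#' @return A tibble with `res_index`, `token`, `ha_ppm`, `csd` (ppm).
#' @export
csd <- function(shifts, reference = random_coil_shifts()) {
  stopifnot(all(c("res_index", "token", "ha_ppm") %in% names(shifts)))
  if (anyDuplicated(shifts$res_index)) abort("residue positions must be unique")
  if (any(shifts$ha_ppm < 0 | shifts$ha_ppm > 12)) {
    abort("observed shifts outside the 0-12 ppm sanity window")
  }
  i <- match(shifts$token, reference$token)
  if (anyNA(i)) {
    abort(paste0("no random-coil reference for residue type(s): ",
                 paste(unique(shifts$token[is.na(i)]), collapse = ", ")))
  }
  tibble(res_index = shifts$res_index, token = shifts$token,
         ha_ppm = shifts$ha_ppm, csd = shifts$ha_ppm - reference$ha_ppm[i])
}

#' Call helical spans from a secondary chemical-shift profile
#'
#' Maximal runs of at least `min_run` consecutive residues with CSD at or
#' below the (negative, upfield) threshold. Runs separated by even a single
#' violating residue are reported separately, never merged.
#'
#' @param profile Output of [csd()].
#' @param threshold Upfield threshold in ppm (must be negative; default
#'   -0.1).
#' @param min_run Minimum run length (default 4).
#' @return A tibble with `start`, `end`, `mean_csd`.
#' @export
call_helix_spans <- function(profile, threshold = -0.1, min_run = 4) {
  stopifnot(threshold < 0, min_run >= 1)
  p <- profile[order(profile$res_index), ]
  below <- p$csd <= threshold
  # breaks in residue numbering also break runs
  grp <- cumsum(c(TRUE, diff(p$res_index) != 1 | diff(below) != 0))
  runs <- split(seq_len(nrow(p)), grp)
  out <- purrr::map_dfr(runs, function(ix) {
    if (!all(below[ix]) || length(ix) < min_run) return(NULL)
    tibble(start = p$res_index[ix[1]], end = p$res_index[ix[length(ix)]],
           mean_csd = mean(p$csd[ix]))
  })
  if (!nrow(out)) {
    return(tibble(start = integer(), end = integer(), mean_csd = numeric()))
  }
  dplyr::arrange(out, .data$start)
}

#' Windowed secondary-structure propensity from CSD
#'
#' Centered moving average of the CSD profile normalized by a full-helix
#' reference shift (so -1 corresponds to fully helical and 0 to coil);
#' edges use truncated windows.
#'
#' @param profile Output of [csd()].
#' @param window Odd window width (default 5).
#' @param helix_ref Full-helix H-alpha secondary shift in ppm (default
#'   -0.39, an average helical upfield shift).
#' @return A tibble with `res_index` and `propensity` (positive = helix-like
#'   after normalization by the negative reference).
#' @export
ssp_profile <- function(profile, window = 5, helix_ref = -0.39) {
  if (window %% 2 != 1) abort("window must be odd")
  p <- profile[order(profile$res_index), ]
  n <- nrow(p)
  if (!n) return(tibble(res_index = integer(), propensity = numeric()))
  half <- (window - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    ix <- max(1, i - half):min(n, i + half)
    mean(p$csd[ix])
  }, numeric(1))
  tibble(res_index = p$res_index, propensity = sm / helix_ref)
}

#' Line plot of a CSD profile with the helix threshold
#'
#' @param profile Output of [csd()].
#' @param threshold Threshold line (default -0.1 ppm).
#' @return A ggplot object.
#' @export
plot_csd_profile <- function(profile, threshold = -0.1) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$res_index, y = .data$csd)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = threshold, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "residue", y = expression(Delta * delta ~ "H" * alpha ~ "(ppm)"))
}
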