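#' Deterministic quasi-uniform sphere lattice
#'
#' Fibonacci lattice of `n` points on the unit sphere. No randomness: SASA
#' values are bit-reproducible for a given point count.
#'
#' @param n Number of points.
#' @return An n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

.assign_radii <- function(s) {
  rad <- vdw_radii()
  r <- rad$radius[match(s$element, rad$element)]
  if (anyNA(r)) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unique(s$element[is.na(r)]), collapse = ", ")))
  }
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places a deterministic Fibonacci lattice on each atom's solvent-expanded
#' sphere (radius + probe) and counts points not occluded by any neighbor's
#' expanded sphere. Per-atom area = exposed fraction x 4 pi (r + probe)^2,
#' aggregated per residue (backbone plus side chain). Hydrogens are excluded
#' by default (united-atom convention).
#'
#' @param s A [structure_model()].
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Lattice points per atom (>= 64; default 960).
#' @param include_h Include hydrogen atoms (default `FALSE`).
#' @return A tibble with per-residue areas (`chain`, `res_index`, `res_name`,
#'   `area`), with attributes `atom_area` (per-atom tibble), `probe`,
#'   `n_points`.
#' @export
sasa <- function(s, probe = 1.4, n_points = 960, include_h = FALSE) {
  stopifnot(inherits(s, "structure_model"), n_points >= 64, probe >= 0)
  d <- s
  if (!include_h) d <- d[d$element != "H", ]
  if (!nrow(d)) {
    prof <- tibble(chain = character(), res_index = integer(),
                   res_name = character(), area = numeric())
    attr(prof, "atom_area") <- tibble()
    return(prof)
  }
  xyz <- as.matrix(d[, c("x", "y", "z")])
  rr <- .assign_radii(d) + probe
  n <- nrow(xyz)
  lattice <- fibonacci_sphere(n_points)
  areas <- numeric(n)
  # neighbor lists via squared-distance cutoff
  for (i in seq_len(n)) {
    pts <- sweep(lattice * rr[i], 2, xyz[i, ], `+`)
    dx <- sweep(xyz, 2, xyz[i, ], `-`)
    d2 <- rowSums(dx^2)
    nbr <- which(d2 < (rr + rr[i])^2 & seq_len(n) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(exposed)) break
      keep <- exposed
      dd <- sweep(pts[keep, , drop = FALSE], 2, xyz[j, ], `-`)
      exposed[keep] <- rowSums(dd^2) > rr[j]^2
    }
    areas[i] <- mean(exposed) * 4 * pi * rr[i]^2
  }
  atom_area <- dplyr::mutate(as_tibble(d), area = areas)
  prof <- atom_area |>
    dplyr::group_by(.data$chain, .data$res_index, .data$res_name) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$res_index)
  attr(prof, "atom_area") <- atom_area
  attr(prof, "probe") <- probe
  attr(prof, "n_points") <- n_points
  prof
}

#' Per-residue buried area upon complex formation
#'
#' For a binder chain docked against one or more receptor chains,
#' buried area per residue = SASA(component alone) - SASA(component in
#' complex), computed with identical probe and lattice so rigid components
#' give non-negative values. Both the binder-side and receptor-side profiles
#' are returned; their totals agree within a few percent (interface
#' symmetry).
#'
#' @param complex A multi-chain [structure_model()].
#' @param binder Chain id of the binder (e.g. the peptide).
#' @param receptor Chain ids of the receptor; default all other chains.
#' @inheritParams sasa
#' @return A tibble of the binder profile (`chain`, `res_index`, `res_name`,
#'   `free_area`, `complex_area`, `buried`), with attribute
#'   `receptor_profile` (same shape) and `components`.
#' @export
buried_area <- function(complex, binder, receptor = NULL, probe = 1.4,
                        n_points = 960) {
  stopifnot(inherits(complex, "structure_model"))
  chains <- unique(complex$chain)
  if (!binder %in% chains) abort(paste0("binder chain '", binder, "' not in structure"))
  if (is.null(receptor)) receptor <- setdiff(chains, binder)
  if (length(intersect(binder, receptor))) abort("binder and receptor chains must be disjoint")
  if (!all(receptor %in% chains)) abort("receptor chain(s) not in structure")

  sub <- function(ch) structure_model(complex[complex$chain %in% ch, ])
  in_complex <- sasa(complex, probe, n_points)
  one_side <- function(ch) {
    alone <- sasa(sub(ch), probe, n_points)
    jc <- in_complex[in_complex$chain %in% ch, ]
    dplyr::left_join(
      dplyr::rename(alone, free_area = "area"),
      dplyr::rename(jc[, c("chain", "res_index", "area")], complex_area = "area"),
      by = c("chain", "res_index")
    ) |>
      dplyr::mutate(buried = .data$free_area - .data$complex_area)
  }
  prof <- one_side(binder)
  attr(prof, "receptor_profile") <- one_side(receptor)
  attr(prof, "components") <- list(binder = binder, receptor = receptor)
  attr(prof, "probe") <- probe
  attr(prof, "n_points") <- n_points
  prof
}

#' Bar chart of a buried-area profile
#'
#' @param profile Output of [buried_area()].
#' @return A ggplot object.
#' @export
plot_buried_area <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$res_index), y = .data$buried)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "residue", y = expression("buried area (" * ring(A)^2 * ")"))
}
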