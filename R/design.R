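#' Classify residue exposure from a buried-area profile
#'
#' Residues with buried area at or below `exposed_max` are `exposed`
#' (candidate staple positions); residues at or above `hotspot_min` times
#' the maximum buried area are `hotspot` (interface anchors that must not be
#' replaced); everything else is `intermediate`.
#'
#' @param profile Data frame with `res_index` and `buried` (Angstrom^2),
#'   e.g. from [buried_area()].
#' @param exposed_max Absolute threshold for "completely solvent-exposed"
#'   (default 5 Angstrom^2).
#' @param hotspot_min Fraction of the maximum buried area defining a hot
#'   spot (default 0.7).
#' @return A tibble `res_index`, `buried`, `class`, with the thresholds as
#'   attributes.
#' @export
classify_exposure <- function(profile, exposed_max = 5, hotspot_min = 0.7) {
  stopifnot(nrow(profile) > 0, exposed_max >= 0, hotspot_min > 0, hotspot_min <= 1)
  b <- profile$buried
  mx <- max(b)
  cls <- rep("intermediate", length(b))
  cls[b >= hotspot_min * mx] <- "hotspot"
  cls[b <= exposed_max] <- "exposed"
  if (mx == 0) {
    warn("all-zero buried-area profile: every residue classified exposed")
    cls[] <- "exposed"
  }
  out <- tibble(res_index = profile$res_index, buried = b, class = cls)
  attr(out, "exposed_max") <- exposed_max
  attr(out, "hotspot_min") <- hotspot_min
  out
}

#' Enumerate and rank i,i+4 staple candidates
#'
#' All (i, i+4) pairs inside the span are candidates. Pairs whose two
#' endpoints are both solvent-exposed and free of hot spots form the top
#' tier (minimal expected perturbation of the binding interface); within a
#' tier, candidates are ordered by summed endpoint buried area (ascending),
#' ties by lower i. Pairs with an endpoint outside the annotated helix are
#' flagged, not removed: stapling an unstructured region is a legitimate —
#' if riskier — design.
#'
#' @param span `c(first, last)` residue range to scan.
#' @param exposure Output of [classify_exposure()].
#' @param helix `c(start, end)` helix annotation.
#' @return A tibble `i`, `j`, `class_i`, `class_j`, `buried_sum`,
#'   `touches_hotspot`, `outside_helix_n`, `outside_helix_c`, `top_tier`,
#'   `rank`.
#' @export
enumerate_staples <- function(span, exposure, helix) {
  stopifnot(length(span) == 2, length(helix) == 2, helix[1] < helix[2])
  if (span[2] - span[1] < 4) {
    return(tibble(i = integer(), j = integer(), class_i = character(),
                  class_j = character(), buried_sum = numeric(),
                  touches_hotspot = logical(), outside_helix_n = logical(),
                  outside_helix_c = logical(), top_tier = logical(),
                  rank = integer()))
  }
  i <- span[1]:(span[2] - 4)
  look <- function(p, col) {
    v <- exposure[[col]][match(p, exposure$res_index)]
    if (col == "class") ifelse(is.na(v), "intermediate", v) else ifelse(is.na(v), 0, v)
  }
  out <- tibble(
    i = i, j = i + 4L,
    class_i = look(i, "class"), class_j = look(i + 4L, "class"),
    buried_sum = look(i, "buried") + look(i + 4L, "buried")
  ) |>
    dplyr::mutate(
      touches_hotspot = .data$class_i == "hotspot" | .data$class_j == "hotspot",
      outside_helix_n = .data$i < helix[1],
      outside_helix_c = .data$j > helix[2],
      top_tier = .data$class_i == "exposed" & .data$class_j == "exposed" &
        !.data$touches_hotspot
    ) |>
    dplyr::arrange(dplyr::desc(.data$top_tier), .data$buried_sum, .data$i) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}

#' Build stapled variants (and hot-spot controls) from ranked candidates
#'
#' For each candidate pair (i, j) this substitutes S5 at both endpoints and
#' closes the staple via [build_variant()]. When `hotspot_control` positions
#' are given, an additional unstapled variant replacing those residues with
#' alanine is emitted as a negative binding control.
#'
#' @param parent A [peptide_construct()].
#' @param candidates Data frame with columns `i`, `j` (e.g. from
#'   [enumerate_staples()]).
#' @param hotspot_control Optional residue positions to mutate to Ala.
#' @return A named list of `peptide_construct` objects.
#' @export
design_variants <- function(parent, candidates, hotspot_control = NULL) {
  out <- list()
  if (!is.null(candidates) && nrow(candidates)) {
    for (r in seq_len(nrow(candidates))) {
      i <- candidates$i[r]; j <- candidates$j[r]
      subs <- stats::setNames(c("S5", "S5"), c(i, j))
      nm <- paste0(parent$name, "_st", i, "_", j)
      out[[nm]] <- build_variant(parent, subs, staple_pair = c(i, j), name = nm)
    }
  }
  if (!is.null(hotspot_control) && length(hotspot_control)) {
    subs <- stats::setNames(rep("A", length(hotspot_control)), hotspot_control)
    nm <- paste0(parent$name, "_ala_control")
    out[[nm]] <- build_variant(parent, subs, name = nm)
  }
  out
}
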