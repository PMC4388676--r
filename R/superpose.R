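#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' matched coordinate sets (SVD of the cross-covariance with a determinant
#' correction, so reflections are never returned).
#'
#' @param mobile,target n x 3 coordinate matrices (or [structure_model()]s,
#'   in which case `selection` names the atoms used, default `"CA"`).
#' @param selection Atom names used when structures are given.
#' @return A list with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   the transform is `x %*% rotation + translation`), `rmsd` (Angstrom) and
#'   `degenerate` (TRUE if the selection is collinear, in which case the
#'   rotation about the degenerate axis is arbitrary).
#' @export
kabsch_superpose <- function(mobile, target, selection = "CA") {
  as_mat <- function(x) {
    if (inherits(x, "structure_model")) coords_matrix(x, atom_names = selection)
    else as.matrix(x)
  }
  A <- as_mat(mobile); B <- as_mat(target)
  if (!all(dim(A) == dim(B))) abort("selections differ in size")
  if (nrow(A) < 3) abort("need at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)  # row-vector convention: x %*% R
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)
  moved <- A0 %*% R
  rmsd <- sqrt(mean(rowSums((moved - B0)^2)))
  list(rotation = R, translation = as.numeric(cb - ca %*% R),
       rmsd = rmsd, degenerate = degenerate)
}

#' Apply a rigid transform to a structure model or coordinate matrix
#'
#' @param x A [structure_model()] or n x 3 matrix.
#' @param fit Result of [kabsch_superpose()].
#' @return Same type as `x`, transformed.
#' @export
apply_transform <- function(x, fit) {
  if (inherits(x, "structure_model")) {
    m <- as.matrix(x[, c("x", "y", "z")]) %*% fit$rotation
    m <- sweep(m, 2, fit$translation, `+`)
    x$x <- m[, 1]; x$y <- m[, 2]; x$z <- m[, 3]
    x
  } else {
    sweep(as.matrix(x) %*% fit$rotation, 2, fit$translation, `+`)
  }
}

#' Helical-wheel face grouping
#'
#' Projects residue positions onto an ideal alpha-helical wheel (100 degrees
#' per residue) and groups those whose angular offset from a reference
#' position stays within a threshold, i.e. residues on the same face of the
#' helix.
#'
#' @param positions Residue numbers within one helical span.
#' @param ref_position Reference residue (angle 0).
#' @param deg_per_residue Helical twist per residue (default 100).
#' @param threshold Same-face half-width in degrees (default 90).
#' @return A tibble with `position`, `angle` (in (-180, 180]) and
#'   `same_face`.
#' @export
helix_face <- function(positions, ref_position, deg_per_residue = 100,
                       threshold = 90) {
  if (!length(positions)) {
    return(tibble(position = integer(), angle = numeric(), same_face = logical()))
  }
  ang <- ((positions - ref_position) * deg_per_residue) %% 360
  ang <- ifelse(ang > 180, ang - 360, ang)
  tibble(position = positions, angle = ang, same_face = abs(ang) <= threshold)
}
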