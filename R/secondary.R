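.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedrals
#'
#' @param s A [structure_model()] with backbone N, CA, C atoms.
#' @return A tibble with `chain`, `res_index`, `phi`, `psi` (degrees; `NA`
#'   at chain termini or where backbone atoms are missing).
#' @export
phi_psi <- function(s) {
  bb <- s[s$name %in% c("N", "CA", "C"), ]
  purrr::map_dfr(split(bb, bb$chain), function(ch) {
    res <- sort(unique(ch$res_index))
    get <- function(ri, nm) {
      row <- ch[ch$res_index == ri & ch$name == nm, ]
      if (nrow(row) != 1) return(NULL)
      c(row$x, row$y, row$z)
    }
    purrr::map_dfr(res, function(ri) {
      N <- get(ri, "N"); CA <- get(ri, "CA"); CC <- get(ri, "C")
      Cm <- get(ri - 1, "C"); Np <- get(ri + 1, "N")
      phi <- if (!is.null(Cm) && !is.null(N) && !is.null(CA) && !is.null(CC))
        .dihedral(Cm, N, CA, CC) else NA_real_
      psi <- if (!is.null(N) && !is.null(CA) && !is.null(CC) && !is.null(Np))
        .dihedral(N, CA, CC, Np) else NA_real_
      tibble(chain = ch$chain[1], res_index = ri, phi = phi, psi = psi)
    })
  })
}

# Dihedral windows for helix classification. The alpha window follows the
# conventional basin; the 3-10 variant window sits above it in psi.
.ss_windows <- list(
  alpha = list(phi = c(-100, -30), psi = c(-67, -7), min_run = 4L),
  three10 = list(phi = c(-100, -30), psi = c(-7, 33), min_run = 3L)
)

.classify_frame <- function(pp) {
  in_win <- function(v, w) !is.na(v) & v >= w[1] & v <= w[2]
  a <- in_win(pp$phi, .ss_windows$alpha$phi) & in_win(pp$psi, .ss_windows$alpha$psi)
  g <- in_win(pp$phi, .ss_windows$three10$phi) & in_win(pp$psi, .ss_windows$three10$psi)
  cls <- rep("coil", nrow(pp))
  run_ok <- function(flag, min_run) {
    r <- rle(flag)
    rep(r$values & r$lengths >= min_run, r$lengths)
  }
  helix_run <- run_ok(a, .ss_windows$alpha$min_run)
  g_run <- run_ok(g & !helix_run, .ss_windows$three10$min_run)
  cls[g & g_run] <- "3-10"
  cls[helix_run] <- "helix"
  # helical-basin residues outside a qualifying run: local turn/bend
  cls[(a | g) & cls == "coil"] <- "turn"
  cls[is.na(pp$phi) & is.na(pp$psi)] <- "unassigned"
  cls
}

#' Secondary-structure assignment from backbone dihedrals
#'
#' Classifies each residue as `helix` (alpha basin phi in \[-100, -30\], psi
#' in \[-67, -7\], in a run of >= 4), `3-10` (psi in (-7, 33\], run >= 3),
#' `turn` (helical-basin dihedrals outside a qualifying run), `coil`, or
#' `unassigned` (missing backbone). Terminal residues lack one dihedral and
#' are classified on the one available.
#'
#' @param x A [structure_model()] with backbone atoms, or a [trajectory()]
#'   whose `topology` carries the backbone atom names.
#' @return For a structure: a tibble `chain`, `res_index`, `class`. For a
#'   trajectory: a list with `timeline` (tibble `frame`, `res_index`,
#'   `class`) and `helicity` (per-residue helix fraction over frames).
#' @export
ss_assign <- function(x) {
  if (inherits(x, "structure_model")) {
    pp <- phi_psi(x)
    # terminal residues: classify on the available dihedral alone
    pp2 <- pp
    pp2$phi[is.na(pp$phi) & !is.na(pp$psi)] <- -65
    pp2$psi[is.na(pp$psi) & !is.na(pp$phi)] <- -40
    cls <- .classify_frame(pp2)
    cls[is.na(pp$phi) & is.na(pp$psi)] <- "unassigned"
    return(tibble(chain = pp$chain, res_index = pp$res_index, class = cls))
  }
  if (!inherits(x, "trajectory") || is.null(x$topology)) {
    abort("ss_assign needs a structure_model or a trajectory with topology")
  }
  top <- x$topology
  timeline <- purrr::map_dfr(seq_len(n_frames(x)), function(i) {
    s <- top
    s$x <- x$coords[i, , 1]; s$y <- x$coords[i, , 2]; s$z <- x$coords[i, , 3]
    cls <- ss_assign(structure_model(s))
    tibble(frame = i, res_index = cls$res_index, class = cls$class)
  })
  helicity <- timeline |>
    dplyr::group_by(.data$res_index) |>
    dplyr::summarise(helicity = mean(.data$class == "helix"), .groups = "drop")
  list(timeline = timeline, helicity = helicity)
}

.resolve_atom <- function(top, sel) {
  i <- which(top$chain == sel[[1]] & top$res_index == as.integer(sel[[2]]) &
               top$name == sel[[3]])
  if (length(i) != 1) return(NA_integer_)
  i
}

#' Fraction of frames in which an interaction is present
#'
#' Hydrogen bonds are scored on the donor-acceptor heavy-atom distance
#' (<= `hbond_dist`), plus the D-H...A angle (>= `hbond_angle`) when a
#' hydrogen atom is given; aromatic contacts on the ring-centroid distance
#' (<= `aromatic_dist`). Criteria referencing atoms absent from the topology
#' are skipped with a warning.
#'
#' @param traj A [trajectory()] whose `topology` identifies atoms by
#'   `(chain, res_index, name)`.
#' @param criteria A list of criteria; each is a list with `id`, `type`
#'   (`"hbond"` or `"aromatic"`), and for hbond `donor`, `acceptor`
#'   (each `c(chain, res_index, name)`), optional `hydrogen`; for aromatic
#'   `ring1`, `ring2` (lists of atom selectors).
#' @param hbond_dist,hbond_angle,aromatic_dist Geometric cutoffs (Angstrom,
#'   degrees).
#' @return A tibble with `id`, `type`, `persistence` (fraction of frames).
#' @export
contact_persistence <- function(traj, criteria, hbond_dist = 3.5,
                                hbond_angle = 120, aromatic_dist = 7.0) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$topology)) abort("trajectory has no topology")
  top <- traj$topology
  nf <- n_frames(traj)
  purrr::map_dfr(criteria, function(cr) {
    present <- logical(nf)
    if (cr$type == "hbond") {
      di <- .resolve_atom(top, cr$donor); ai <- .resolve_atom(top, cr$acceptor)
      hi <- if (!is.null(cr$hydrogen)) .resolve_atom(top, cr$hydrogen) else NA_integer_
      if (is.na(di) || is.na(ai) || (!is.null(cr$hydrogen) && is.na(hi))) {
        warn(paste0("criterion '", cr$id, "' references absent atoms; skipped"))
        return(tibble(id = cr$id, type = cr$type, persistence = NA_real_))
      }
      for (f in seq_len(nf)) {
        D <- traj$coords[f, di, ]; A <- traj$coords[f, ai, ]
        ok <- sqrt(sum((D - A)^2)) <= hbond_dist
        if (ok && !is.na(hi)) {
          H <- traj$coords[f, hi, ]
          v1 <- D - H; v2 <- A - H
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
          ok <- ang >= hbond_angle
        }
        present[f] <- ok
      }
    } else if (cr$type == "aromatic") {
      i1 <- vapply(cr$ring1, .resolve_atom, integer(1), top = top)
      i2 <- vapply(cr$ring2, .resolve_atom, integer(1), top = top)
      if (anyNA(i1) || anyNA(i2)) {
        warn(paste0("criterion '", cr$id, "' references absent atoms; skipped"))
        return(tibble(id = cr$id, type = cr$type, persistence = NA_real_))
      }
      for (f in seq_len(nf)) {
        c1 <- colMeans(matrix(traj$coords[f, i1, ], ncol = 3))
        c2 <- colMeans(matrix(traj$coords[f, i2, ], ncol = 3))
        present[f] <- sqrt(sum((c1 - c2)^2)) <= aromatic_dist
      }
    } else {
      abort(paste0("unknown criterion type '", cr$type, "'"))
    }
    tibble(id = cr$id, type = cr$type, persistence = mean(present))
  })
}
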