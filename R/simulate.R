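## Seeded generators for every input the pipeline consumes. Each takes an
## explicit seed (no hidden RNG state survives) and records its ground-truth
## parameters so downstream recovery is testable.

.nerf_place <- function(A, B, C, r, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ta <- -torsion_deg * pi / 180
  d <- r * c(-cos(th), sin(th) * cos(ta), sin(th) * sin(ta))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  C + cbind(bc, m2, n) %*% d
}

#' Build an ideal helical peptide model
#'
#' Constructs backbone N, CA, C (plus CB for non-glycine residues) from
#' standard bond geometry and per-residue phi/psi torsions. The default
#' (-57, -47) gives a canonical alpha helix: ~1.5 Angstrom rise and ~100
#' degrees of twist per residue, consecutive C-alpha separation ~3.8
#' Angstrom. `phi`/`psi` may be vectors (recycled) to build frayed termini
#' or extended segments.
#'
#' @param tokens Residue tokens (length >= 1).
#' @param start First residue number (default 1).
#' @param phi,psi Backbone torsions in degrees (scalar or per-residue).
#' @param chain Chain id (default `"A"`).
#' @return A [structure_model()].
#' @export
make_helix <- function(tokens, start = 1, phi = -57, psi = -47, chain = "A") {
  n <- length(tokens)
  stopifnot(n >= 1)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329
  a_CNCa <- 121.7; a_NCaC <- 111.2; a_CaCN <- 116.2
  rows <- list()
  add <- function(res_i, nm, el, xyz) {
    rows[[length(rows) + 1]] <<- tibble(
      serial = length(rows) + 1L, name = nm, element = el, chain = chain,
      res_index = start + res_i - 1L,
      res_name = tokens[res_i], x = xyz[1], y = xyz[2], z = xyz[3])
  }
  N <- c(0, 0, 0)
  CA <- c(b_NCa, 0, 0)
  th <- (180 - a_NCaC) * pi / 180
  C <- CA + b_CaC * c(cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      Nprev <- N; CAprev <- CA; Cprev <- C
      N <- .nerf_place(Nprev, CAprev, Cprev, b_CN, a_CaCN, psi[i - 1])
      CA <- .nerf_place(CAprev, Cprev, N, b_NCa, a_CNCa, 180)  # omega trans
      C <- .nerf_place(Cprev, N, CA, b_CaC, a_NCaC, phi[i])
    }
    add(i, "N", "N", N)
    add(i, "CA", "C", CA)
    add(i, "C", "C", C)
    if (tokens[i] != "G") {
      CB <- .nerf_place(C, N, CA, 1.53, 110.5, 122.5)
      add(i, "CB", "C", CB)
    }
  }
  structure_model(dplyr::bind_rows(rows))
}

#' Synthetic helix-in-groove complex with known contact face
#'
#' Packs pseudo-atom receptor clusters against the side chains (CB, or CA
#' for glycine) of the designated contact residues only, so the ground-truth
#' interface is exactly the designated face. Each contact residue receives a
#' small deterministic cap of carbon pseudo-atoms at van der Waals contact
#' distance.
#'
#' @param helix A [structure_model()] from [make_helix()].
#' @param contact_positions Residue numbers forming the contact face (may be
#'   empty: the receptor is then placed 100 Angstrom away, burying nothing).
#' @param receptor_chain Chain id for the pseudo-receptor (default `"R"`).
#' @param contact_dist Distance from the side-chain anchor to the cap center
#'   (default 4.5 Angstrom, non-bonded carbon-carbon packing).
#' @return A two-chain [structure_model()] with attribute `truth` listing
#'   the contact positions.
#' @export
make_groove_complex <- function(helix, contact_positions,
                                receptor_chain = "R", contact_dist = 4.5) {
  stopifnot(inherits(helix, "structure_model"))
  ca <- helix[helix$name == "CA", ]
  axis_fit <- stats::prcomp(as.matrix(ca[, c("x", "y", "z")]))
  center <- colMeans(as.matrix(ca[, c("x", "y", "z")]))
  rows <- list()
  serial0 <- max(helix$serial)
  k <- 0L
  for (p in contact_positions) {
    anchor_row <- helix[helix$res_index == p & helix$name == "CB", ]
    if (!nrow(anchor_row)) anchor_row <- helix[helix$res_index == p & helix$name == "CA", ]
    if (!nrow(anchor_row)) abort(paste0("no residue ", p, " in helix"))
    anchor <- c(anchor_row$x[1], anchor_row$y[1], anchor_row$z[1])
    # outward direction: away from the helix axis through this residue
    t_proj <- sum((anchor - center) * axis_fit$rotation[, 1])
    on_axis <- center + t_proj * axis_fit$rotation[, 1]
    u <- anchor - on_axis; u <- u / sqrt(sum(u^2))
    # orthonormal frame for the cap
    v <- axis_fit$rotation[, 2]; v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    cap_center <- anchor + contact_dist * u
    offsets <- rbind(c(0, 0), c(1.6, 0), c(-1.6, 0), c(0, 1.6), c(0, -1.6),
                     c(1.1, 1.1), c(-1.1, -1.1))
    for (o in seq_len(nrow(offsets))) {
      pos <- cap_center + offsets[o, 1] * v + offsets[o, 2] * w + 0.8 * u * (o > 1)
      k <- k + 1L
      rows[[k]] <- tibble(
        serial = serial0 + k, name = paste0("P", o), element = "C",
        chain = receptor_chain, res_index = 1000L + match(p, contact_positions),
        res_name = "PSD", x = pos[1], y = pos[2], z = pos[3])
    }
  }
  if (!length(rows)) {
    far <- center + 100 * axis_fit$rotation[, 1]
    rows[[1]] <- tibble(serial = serial0 + 1L, name = "P1", element = "C",
                        chain = receptor_chain, res_index = 1000L,
                        res_name = "PSD", x = far[1], y = far[2], z = far[3])
  }
  out <- structure_model(dplyr::bind_rows(list(as_tibble(helix)), rows))
  attr(out, "truth") <- list(contact_positions = contact_positions,
                             receptor_chain = receptor_chain)
  out
}

#' Generate orthonormal displacement modes
#'
#' @param n_atoms Number of atoms (mode dimension 3N).
#' @param k Number of modes.
#' @param seed RNG seed.
#' @return A 3N x k matrix with orthonormal columns.
#' @export
random_modes <- function(n_atoms, k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(3 * n_atoms * k), ncol = k)))
}

#' Simulate a trajectory with a prescribed low-rank covariance
#'
#' frame_t = mean + sum_k sqrt(lambda_k) z_tk v_k + eps, with z and eps
#' standard normal (seeded) and eps isotropic with per-coordinate sd
#' `iso_sd`. The population covariance is therefore
#' sum_k lambda_k v_k v_k' + iso_sd^2 I, so essential-dynamics analysis has
#' an exact ground truth.
#'
#' @param mean_coords n x 3 matrix (or [structure_model()]; CA atoms used).
#' @param modes 3N x k matrix of orthonormal mode vectors.
#' @param lambdas Mode variances (Angstrom^2, length k).
#' @param iso_sd Isotropic noise sd per coordinate (Angstrom).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param dt Frame spacing in ns (default 1).
#' @return A [trajectory()] with attribute `truth` (modes, lambdas, iso_sd).
#' @export
simulate_trajectory <- function(mean_coords, modes = NULL, lambdas = numeric(),
                                iso_sd = 0, n_frames = 100, seed = 1, dt = 1) {
  if (inherits(mean_coords, "structure_model")) {
    mean_coords <- coords_matrix(mean_coords, atom_names = "CA")
  }
  mean_coords <- as.matrix(mean_coords)
  N <- nrow(mean_coords)
  if (n_frames < 2) abort("degenerate trajectory: need at least 2 frames")
  mu <- as.numeric(t(mean_coords))  # (x1, y1, z1, x2, ...)
  k <- length(lambdas)
  if (k > 0) {
    modes <- as.matrix(modes)
    stopifnot(nrow(modes) == 3 * N, ncol(modes) >= k)
    modes <- modes[, seq_len(k), drop = FALSE]
  }
  set.seed(seed)
  Z <- if (k > 0) matrix(stats::rnorm(n_frames * k), n_frames, k) else NULL
  E <- matrix(stats::rnorm(n_frames * 3 * N, sd = iso_sd), n_frames, 3 * N)
  X <- matrix(rep(mu, each = n_frames), n_frames, 3 * N)
  if (k > 0) X <- X + Z %*% (t(modes) * sqrt(lambdas))
  if (iso_sd > 0) X <- X + E
  coords <- array(0, c(n_frames, N, 3))
  for (a in seq_len(N)) coords[, a, ] <- X[, (3 * a - 2):(3 * a)]
  traj <- trajectory(coords, times = (seq_len(n_frames) - 1) * dt)
  attr(traj, "truth") <- list(modes = modes, lambdas = lambdas, iso_sd = iso_sd,
                              seed = seed)
  traj
}

# Preset grids mirroring the study's assay conditions. The FP titration
# spans the tested receptor range of the binding experiment (0.1 nM - 20 uM,
# log-spaced), which brackets sub-micromolar dissociation constants.
.fp_grid_M <- exp(seq(log(0.1e-9), log(20e-6), length.out = 6))
.elisa_grid_M <- c(0.4, 0.75, 1.5, 3.8, 7.6, 15.6) * 1e-6
.decay_grid_min <- c(0, 60, 120, 180, 360, 900)

#' Simulate a fluorescence-polarization titration
#'
#' One-site hyperbola FP = fp0 + bmax * R / (kd + R) with additive Gaussian
#' noise. The default grid is six log-spaced receptor concentrations between
#' 0.1 nM and 20 uM, the tested range of the binding experiment.
#'
#' @param kd Dissociation constant (molar).
#' @param bmax Maximum polarization gain (mP).
#' @param fp0 Baseline polarization (mP).
#' @param grid Receptor concentrations (molar).
#' @param noise_sd Gaussian noise sd (mP).
#' @param replicates Replicate count.
#' @param seed RNG seed.
#' @return A tibble `conc_M`, `fp`, `replicate` with attribute `truth`.
#' @export
simulate_fp <- function(kd = 305e-9, bmax = 100, fp0 = 50,
                        grid = .fp_grid_M, noise_sd = 3, replicates = 1,
                        seed = 1) {
  set.seed(seed)
  out <- purrr::map_dfr(seq_len(replicates), function(r) {
    mu <- fp0 + bmax * grid / (kd + grid)
    tibble(conc_M = grid, fp = mu + stats::rnorm(length(grid), sd = noise_sd),
           replicate = r)
  })
  attr(out, "truth") <- list(kd = kd, bmax = bmax, fp0 = fp0,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate an ELISA binding series
#'
#' Hyperbolic response plateau * R / (k_half + R) plus noise on the plate's
#' concentration grid (0.4-15.6 uM).
#'
#' @param plateau Saturating response (AU).
#' @param k_half Half-saturation concentration (molar).
#' @param grid Concentrations (molar).
#' @param noise_sd Gaussian noise sd (AU).
#' @param seed RNG seed.
#' @return A tibble `conc_M`, `response` with attribute `truth`.
#' @export
simulate_elisa <- function(plateau = 1, k_half = 1e-6, grid = .elisa_grid_M,
                           noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  mu <- plateau * grid / (k_half + grid)
  out <- tibble(conc_M = grid,
                response = mu + stats::rnorm(length(grid), sd = noise_sd))
  attr(out, "truth") <- list(plateau = plateau, k_half = k_half,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a first-order serum-decay series
#'
#' Intact fraction exp(-t ln2 / t_half) plus noise on the sampling grid
#' (default 0, 60, 120, 180, 360, 900 min), clamped to the valid fraction
#' range.
#'
#' @param t_half Half-life (min).
#' @param grid Timepoints (min).
#' @param noise_sd Gaussian noise sd on the fraction.
#' @param seed RNG seed.
#' @return A tibble `time_min`, `fraction` with attribute `truth`.
#' @export
simulate_decay <- function(t_half = 420, grid = .decay_grid_min,
                           noise_sd = 0.03, seed = 1) {
  set.seed(seed)
  mu <- exp(-log(2) * grid / t_half)
  f <- mu + stats::rnorm(length(grid), sd = noise_sd)
  out <- tibble(time_min = grid, fraction = pmin(pmax(f, 0), 1.05))
  attr(out, "truth") <- list(t_half = t_half, noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate an H-alpha shift table with a helical block
#'
#' Observed shifts are random-coil reference values plus a uniform upfield
#' (negative) offset inside the helix span, plus noise.
#'
#' @param tokens Residue tokens.
#' @param start First residue number.
#' @param helix_span `c(start, end)` of the helical block.
#' @param amplitude Upfield offset inside the span (ppm, negative; default
#'   -0.35).
#' @param noise_sd Gaussian noise sd (ppm).
#' @param seed RNG seed.
#' @return A tibble `res_index`, `token`, `ha_ppm` with attribute `truth`.
#' @export
simulate_shifts <- function(tokens, start = 1, helix_span = NULL,
                            amplitude = -0.35, noise_sd = 0, seed = 1) {
  set.seed(seed)
  res_index <- seq.int(start, length.out = length(tokens))
  rc <- random_coil_shifts()
  base <- rc$ha_ppm[match(tokens, rc$token)]
  if (anyNA(base)) abort("unknown residue token in sequence")
  offset <- rep(0, length(tokens))
  if (!is.null(helix_span)) {
    offset[res_index >= helix_span[1] & res_index <= helix_span[2]] <- amplitude
  }
  out <- tibble(res_index = res_index, token = tokens,
                ha_ppm = base + offset + stats::rnorm(length(tokens), sd = noise_sd))
  attr(out, "truth") <- list(helix_span = helix_span, amplitude = amplitude,
                             noise_sd = noise_sd, seed = seed)
  out
}
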