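#' Construct a trajectory
#'
#' Time-ordered coordinate frames for a fixed atom selection (C-alpha atoms
#' by default throughout the package).
#'
#' @param coords A frames x atoms x 3 array, or a list of n x 3 matrices.
#' @param times Frame times in ns (strictly increasing). Defaults to
#'   `0:(n_frames-1)`.
#' @param topology Optional [structure_model()] for the selection.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, times = NULL, topology = NULL) {
  if (is.list(coords)) {
    n_atoms <- nrow(coords[[1]])
    if (!all(vapply(coords, nrow, 1L) == n_atoms)) {
      abort("all frames must have the same atom count")
    }
    arr <- array(0, c(length(coords), n_atoms, 3))
    for (i in seq_along(coords)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  n <- dim(coords)[1]
  if (is.null(times)) times <- seq_len(n) - 1
  if (length(times) != n || (n > 1 && any(diff(times) <= 0))) {
    abort("times must be strictly increasing, one per frame")
  }
  structure(list(coords = coords, times = as.numeric(times),
                 topology = topology),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<trajectory> ", d[1], " frames x ", d[2], " atoms; t = ",
      min(x$times), "-", max(x$times), " ns\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_atoms <- function(traj) dim(traj$coords)[2]

#' Read a multi-model PDB as a C-alpha trajectory
#'
#' @param source PDB path or lines (MODEL/ENDMDL separated frames).
#' @param dt Time step between frames in ns (default 1).
#' @param atom_names Atom selection (default `"CA"`).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(source, dt = 1, atom_names = "CA") {
  file <- .as_pdb_file(source)
  pdb <- tryCatch(bio3d::read.pdb(file, multi = TRUE, verbose = FALSE),
                  error = function(e) abort(paste0("PDB parse failed: ", conditionMessage(e))))
  sel <- which(trimws(pdb$atom$elety) %in% atom_names)
  if (!length(sel)) abort("no atoms match the selection")
  idx <- as.vector(t(outer(sel - 1, 1:3, function(a, k) 3 * a + k)))
  xyz <- pdb$xyz[, idx, drop = FALSE]
  frames <- lapply(seq_len(nrow(xyz)),
                   function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  trajectory(frames, times = (seq_along(frames) - 1) * dt)
}

.window_frames <- function(traj, window) {
  if (is.null(window)) return(seq_len(n_frames(traj)))
  stopifnot(length(window) == 2, window[1] < window[2])
  which(traj$times >= window[1] & traj$times <= window[2])
}

#' Superpose every frame onto a reference
#'
#' Least-squares (Kabsch) superposition of each frame onto the reference
#' coordinates; idempotent once aligned.
#'
#' @param traj A [trajectory()].
#' @param reference n x 3 matrix or frame index (default first frame).
#' @return An aligned [trajectory()].
#' @export
align_trajectory <- function(traj, reference = 1) {
  ref <- if (is.matrix(reference)) reference else traj$coords[reference, , ]
  if (nrow(ref) != n_atoms(traj)) abort("reference selection size mismatch")
  if (n_atoms(traj) == 0) abort("empty atom selection")
  out <- traj
  for (i in seq_len(n_frames(traj))) {
    fit <- kabsch_superpose(traj$coords[i, , ], ref)
    out$coords[i, , ] <- apply_transform(traj$coords[i, , ], fit)
  }
  out
}

#' Per-frame RMSD and gyration radius
#'
#' @param traj An aligned [trajectory()].
#' @param reference n x 3 matrix or frame index (default first frame).
#' @param masses Optional per-atom masses (default unit).
#' @return A tibble with `frame`, `time_ns`, `rmsd`, `rg` (Angstrom).
#' @export
observables <- function(traj, reference = 1, masses = NULL) {
  ref <- if (is.matrix(reference)) reference else traj$coords[reference, , ]
  if (is.null(masses)) masses <- rep(1, n_atoms(traj))
  w <- masses / sum(masses)
  purrr::map_dfr(seq_len(n_frames(traj)), function(i) {
    X <- traj$coords[i, , ]
    com <- colSums(X * w)
    tibble(frame = i, time_ns = traj$times[i],
           rmsd = sqrt(mean(rowSums((X - ref)^2))),
           rg = sqrt(sum(w * rowSums(sweep(X, 2, com)^2))))
  })
}

#' Per-atom root mean square fluctuation
#'
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2) over an equilibrated window.
#'
#' @param traj An aligned [trajectory()].
#' @param window `c(t_start, t_end)` in ns, or `NULL` for all frames.
#' @return A tibble with `atom` and `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, window = NULL) {
  idx <- .window_frames(traj, window)
  if (!length(idx)) abort("window contains no frames")
  X <- traj$coords[idx, , , drop = FALSE]
  mu <- apply(X, c(2, 3), mean)
  dev <- sweep(X, c(2, 3), mu)
  tibble(atom = seq_len(n_atoms(traj)),
         rmsf = sqrt(apply(dev^2, 2, sum) / length(idx)))
}

#' Essential-dynamics subspace of a C-alpha trajectory
#'
#' Eigendecomposition of the 3N x 3N covariance of the concatenated
#' coordinates about the window mean; the top-k eigenvectors (unit vectors in
#' 3N-space) and eigenvalues (Angstrom^2, descending) define the essential
#' subspace.
#'
#' @param traj An aligned [trajectory()].
#' @param window `c(t_start, t_end)` ns or `NULL`.
#' @param k Number of modes kept (default 10).
#' @return An object of class `essential_subspace`: `vectors` (3N x k),
#'   `values` (length k), `all_values`, `n_atoms`, `n_frames_used`, `window`.
#' @export
essential_subspace <- function(traj, window = NULL, k = 10) {
  idx <- .window_frames(traj, window)
  if (length(idx) < 2) abort("need at least 2 frames")
  N <- n_atoms(traj)
  if (length(idx) < 3 * N) {
    warn("fewer frames than 3N: covariance is rank-deficient")
  }
  # column layout (x1, y1, z1, x2, ...): one 3N-vector per frame
  X <- do.call(cbind, lapply(seq_len(N), function(a) {
    matrix(traj$coords[idx, a, , drop = FALSE], nrow = length(idx))
  }))
  C <- stats::cov(X) * (length(idx) - 1) / length(idx)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- min(k, ncol(e$vectors))
  structure(list(vectors = e$vectors[, seq_len(k), drop = FALSE],
                 values = vals[seq_len(k)], all_values = vals,
                 n_atoms = N, n_frames_used = length(idx), window = window),
            class = "essential_subspace")
}

#' @export
print.essential_subspace <- function(x, ...) {
  cat("<essential_subspace> k = ", length(x$values), ", N = ", x$n_atoms,
      " atoms, ", x$n_frames_used, " frames\n", sep = "")
  cat("  top eigenvalues (A^2): ",
      paste(signif(utils::head(x$values, 5), 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Root mean square inner product of two essential subspaces
#'
#' RMSIP = sqrt( (1/k) sum_i sum_j (eta_i^a . eta_j^b)^2 ) over the first k
#' eigenvectors of each subspace. Bounded in \[0, 1\]; 1 for identical
#' spans, ~sqrt(k/d) for random k-subspaces of a d-dimensional space.
#' Invariant to sign flips and to any rotation of either basis within its
#' own span, so degenerate (tied-eigenvalue) spectra are handled safely.
#'
#' @param a,b `essential_subspace` objects (or plain 3N x k matrices with
#'   orthonormal columns) over the same 3N dimension.
#' @param k Number of eigenvectors compared (default 10).
#' @return A list with `value`, `k`, `dim`.
#' @export
rmsip <- function(a, b, k = 10) {
  va <- if (inherits(a, "essential_subspace")) a$vectors else as.matrix(a)
  vb <- if (inherits(b, "essential_subspace")) b$vectors else as.matrix(b)
  if (nrow(va) != nrow(vb)) abort("subspace dimensions differ")
  if (ncol(va) < k || ncol(vb) < k) abort("both subspaces need at least k vectors")
  va <- va[, seq_len(k), drop = FALSE]
  vb <- vb[, seq_len(k), drop = FALSE]
  value <- sqrt(sum((t(va) %*% vb)^2) / k)
  list(value = value, k = k, dim = nrow(va))
}

#' Convergence RMSIP between two halves of an equilibrated window
#'
#' Splits the window at its midpoint, extracts the essential subspace of
#' each half, and returns their RMSIP — the convergence statistic used to
#' judge whether a simulation has sampled a stable essential space.
#'
#' @inheritParams essential_subspace
#' @return A list with `value`, `k`, `halves` (frame counts).
#' @export
split_halves_rmsip <- function(traj, window = NULL, k = 10) {
  idx <- .window_frames(traj, window)
  if (length(idx) < 4) abort("window too short: need at least 4 frames")
  half <- floor(length(idx) / 2)
  t1 <- traj$times[idx[c(1, half)]]
  t2 <- traj$times[idx[c(half + 1, length(idx))]]
  e1 <- essential_subspace(traj, window = t1, k = k)
  e2 <- essential_subspace(traj, window = t2, k = k)
  if (max(e1$all_values) <= 0 || max(e2$all_values) <= 0) {
    abort("degenerate window: zero covariance in at least one half")
  }
  r <- rmsip(e1, e2, k = k)
  list(value = r$value, k = k,
       halves = c(e1$n_frames_used, e2$n_frames_used))
}
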