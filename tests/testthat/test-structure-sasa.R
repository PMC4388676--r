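one_atom <- function(x = 0, y = 0, z = 0, el = "C") {
  structure_model(data.frame(serial = 1, name = paste0(el, "1"), element = el,
                             chain = "A", res_index = 1, res_name = "X",
                             x = x, y = y, z = z))
}

test_that("PDB round trip preserves atoms and coordinates to format precision", {
  minimal <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
  s <- read_pdb(minimal)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$x, s$y, s$z), c(1, 2, 3))

  hx <- make_cul3_helix()
  s2 <- read_pdb(write_pdb(hx))
  expect_equal(nrow(s2), nrow(hx))
  expect_equal(s2$name, hx$name)
  expect_equal(as.matrix(s2[, c("x", "y", "z")]),
               as.matrix(hx[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("malformed coordinates and duplicate atoms are rejected informatively", {
  bad <- c("ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
           "ATOM      2  CA  ALA A   2       xx.xxx   2.000   3.000  1.00  0.00           C")
  expect_error(read_pdb(bad), "line 2")
  dup <- data.frame(serial = 1:2, name = "CA", element = "C", chain = "A",
                    res_index = 5, res_name = "ALA", x = 0:1, y = 0, z = 0)
  expect_error(structure_model(dup), "chain A, residue 5, atom CA")
})

test_that("missing element columns are inferred from atom names with a warning", {
  lines <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00"
  expect_warning(s <- read_pdb(lines), "inferred")
  expect_equal(s$element, "C")
})

test_that("SASA of an isolated sphere matches the closed form", {
  p <- sasa(one_atom())
  expect_equal(p$area, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
  # zero atoms
  empty <- one_atom(el = "H")  # united-atom: H excluded
  expect_equal(nrow(sasa(empty)), 0L)
})

test_that("two overlapping spheres match the analytic spherical-cap formula", {
  R <- 1.7 + 1.4
  for (d in c(2.0, 4.0, 5.5)) {
    s <- structure_model(data.frame(
      serial = 1:2, name = c("C1", "C2"), element = "C", chain = "A",
      res_index = 1:2, res_name = "X", x = c(0, d), y = 0, z = 0))
    analytic <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
    areas <- attr(sasa(s, n_points = 960), "atom_area")$area
    expect_equal(areas[1], analytic, tolerance = 0.02)
    expect_equal(areas[2], analytic, tolerance = 0.02)
  }
})

test_that("a fully engulfed atom has near-zero accessible area", {
  shell <- fibonacci_sphere(60) * 2.2
  atoms <- data.frame(
    serial = 1:61, name = paste0("C", 1:61), element = "C", chain = "A",
    res_index = c(1L, rep(2L, 60)), res_name = "X",
    x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]))
  a <- attr(sasa(structure_model(atoms)), "atom_area")$area
  expect_lt(a[1], 1e-6)
})

test_that("SASA converges with lattice density on the helix fixture", {
  hx <- make_cul3_helix()
  a1 <- sum(sasa(hx, n_points = 960)$area)
  a2 <- sum(sasa(hx, n_points = 3840)$area)
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("total SASA decreases as a second molecule approaches below contact", {
  hx <- make_cul3_helix()
  tot_at <- function(cd) {
    sum(sasa(make_groove_complex(hx, c(54, 58, 62), contact_dist = cd))$area)
  }
  areas <- vapply(c(20, 12, 6, 4), tot_at, numeric(1))
  expect_true(all(diff(areas) <= 1e-6))
  expect_lt(areas[4], areas[1])
})

test_that("buried area is zero for a far-translated binder and localizes to the contact face", {
  hx <- make_cul3_helix()
  far <- make_groove_complex(hx, integer())   # receptor 100 A away
  ba0 <- buried_area(far, binder = "A")
  expect_true(all(abs(ba0$buried) < 1e-9))

  cx <- make_groove_complex(hx, c(54, 58, 62))
  ba <- buried_area(cx, binder = "A")
  expect_true(all(ba$buried >= -1e-6))
  face_share <- sum(ba$buried[ba$res_index %in% c(54, 58, 62)]) / sum(ba$buried)
  expect_gt(face_share, 0.8)
  # top-3 buried residues are the designated face
  top3 <- ba$res_index[order(ba$buried, decreasing = TRUE)][1:3]
  expect_setequal(top3, c(54, 58, 62))
  # interface symmetry within 5%
  rp <- attr(ba, "receptor_profile")
  expect_true(all(rp$buried >= -1e-6))
  expect_lt(abs(sum(ba$buried) - sum(rp$buried)) / sum(ba$buried), 0.05)
  expect_error(buried_area(cx, binder = "Z"), "not in structure")
})

test_that("kabsch superposition is exact, proper, and matches the numeric oracle", {
  hx <- coords_matrix(make_cul3_helix())
  expect_equal(kabsch_superpose(hx, hx)$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation(3)
  moved <- sweep(hx %*% R, 2, c(5, -2, 7), `+`)
  fit <- kabsch_superpose(moved, hx)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # 4-point symmetric toy, one coordinate perturbed by 1 A: value frozen from
  # the numeric rigid-fit oracle
  A <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, -1, 0), c(-1, 1, 0))
  B <- A; B[1, 3] <- 1
  k_rmsd <- kabsch_superpose(A, B)$rmsd
  expect_equal(k_rmsd, 0.2572541, tolerance = 1e-6)
  expect_equal(k_rmsd, oracle_rmsd(A, B), tolerance = 1e-6)
  expect_error(kabsch_superpose(hx[1:4, ], hx[1:5, ]), "size")
  col <- cbind(1:5, 0, 0)
  expect_true(kabsch_superpose(col, col)$degenerate)
})

test_that("kabsch rmsd is invariant under proper rigid motion of both inputs", {
  set.seed(9)
  A <- matrix(rnorm(36), 12)
  B <- A + matrix(rnorm(36, sd = 0.3), 12)
  base <- kabsch_superpose(A, B)$rmsd
  for (s in 1:3) {
    R <- random_rotation(s)
    t <- c(s, -s, 2 * s)
    r2 <- kabsch_superpose(sweep(A %*% R, 2, t, `+`),
                           sweep(B %*% R, 2, t, `+`))$rmsd
    expect_lt(abs(r2 - base), 1e-9)
  }
})

test_that("kabsch agrees with the independent bio3d superposition", {
  set.seed(4)
  A <- matrix(rnorm(30), 10)
  B <- A + matrix(rnorm(30, sd = 0.5), 10)
  ours <- kabsch_superpose(A, B)
  xyz_a <- as.numeric(t(A)); xyz_b <- as.numeric(t(B))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_b, mobile = xyz_a))
  bio3d_rmsd <- sqrt(mean(colSums(matrix((fitted - xyz_b)^2, nrow = 3))))
  expect_equal(ours$rmsd, bio3d_rmsd, tolerance = 1e-6)
})

test_that("helix face grouping follows the 100-degree wheel", {
  hf <- helix_face(c(54, 58, 62), ref_position = 54)
  expect_equal(hf$angle, c(0, 40, 80))
  expect_true(all(hf$same_face))
  hf2 <- helix_face(c(54, 56), ref_position = 54)
  expect_equal(hf2$angle[2], -160)
  expect_false(hf2$same_face[2])
  expect_equal(nrow(helix_face(integer(), 54)), 0L)
})
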