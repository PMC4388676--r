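test_that("alignment removes rigid motion and is idempotent", {
  mu <- coords_matrix(make_cul3_helix())
  frames <- lapply(1:5, function(i) {
    sweep(mu %*% random_rotation(i), 2, c(i, -i, 2 * i), `+`)
  })
  tr <- trajectory(frames)
  al <- align_trajectory(tr, reference = mu)
  for (i in 1:5) expect_lt(max(abs(al$coords[i, , ] - mu)), 1e-6)
  al2 <- align_trajectory(al, reference = mu)
  expect_lt(max(abs(al2$coords - al$coords)), 1e-9)
  expect_error(align_trajectory(tr, reference = mu[1:3, ]), "mismatch")
})

test_that("per-frame observables match closed forms", {
  mu <- coords_matrix(make_cul3_helix())
  tr <- trajectory(list(mu, mu + 1))
  obs <- observables(tr, reference = 1)
  expect_equal(obs$rmsd[1], 0)
  expect_equal(obs$rmsd[2], sqrt(3), tolerance = 1e-12)
  # two unit-mass atoms 2 A apart: Rg = 1
  pair <- trajectory(list(rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(observables(pair)$rg, 1)
  # all atoms coincident: Rg = 0
  pt <- trajectory(list(matrix(5, 4, 3)))
  expect_equal(observables(pt)$rg, 0)
})

test_that("RMSF matches closed forms for static, isotropic and low-rank motion", {
  mu <- coords_matrix(make_cul3_helix())
  static <- trajectory(list(mu, mu, mu))
  expect_true(all(rmsf(static)$rmsf == 0))

  sigma <- 0.3
  iso <- simulate_trajectory(mu, iso_sd = sigma, n_frames = 5000, seed = 21)
  expect_equal(mean(rmsf(iso)$rmsf), sigma * sqrt(3), tolerance = 0.03)

  V <- random_modes(nrow(mu), 3, seed = 7)
  lam <- c(9, 4, 1)
  lr <- simulate_trajectory(mu, V, lam, iso_sd = 0.1, n_frames = 5000, seed = 11)
  pred <- sqrt(vapply(seq_len(nrow(mu)), function(a) {
    sum(lam * colSums(matrix(V[(3 * a - 2):(3 * a), ], 3)^2))
  }, numeric(1)) + 3 * 0.1^2)
  expect_true(all(abs(rmsf(lr)$rmsf - pred) / pred < 0.05))
  expect_error(rmsf(lr, window = c(10000, 10001)), "no frames")
})

test_that("essential subspace recovers planar toy and generator ground truth", {
  # 2-atom toy moving along x only
  frames <- lapply(seq(-1, 1, length.out = 9), function(s) {
    rbind(c(s, 0, 0), c(5, 0, 0))
  })
  es <- suppressWarnings(essential_subspace(trajectory(frames), k = 6))
  expect_equal(sum(es$all_values > 1e-12), 1L)
  expect_equal(abs(es$vectors[1, 1]), 1, tolerance = 1e-9)

  mu <- coords_matrix(make_cul3_helix())
  V <- random_modes(nrow(mu), 3, seed = 7)
  lam <- c(9, 4, 1)
  tr <- simulate_trajectory(mu, V, lam, iso_sd = 0.1, n_frames = 5000, seed = 11)
  es2 <- essential_subspace(tr, k = 10)
  expect_true(all(abs(es2$values[1:3] - lam) / lam < 0.10))
  expect_gt(rmsip(es2$vectors[, 1:3], V, k = 3)$value, 0.95)
  # orthonormality and ordering
  G <- t(es2$vectors) %*% es2$vectors
  expect_lt(max(abs(G - diag(10))), 1e-8)
  expect_true(all(diff(es2$values) <= 1e-12))
  expect_true(all(es2$all_values >= 0))
  # full spectrum sums to the covariance trace = total positional variance
  X <- do.call(cbind, lapply(seq_len(nrow(mu)), function(a) {
    matrix(tr$coords[, a, ], nrow = 5000)
  }))
  trace_cov <- sum(apply(X, 2, function(col) mean((col - mean(col))^2)))
  expect_equal(sum(es2$all_values), trace_cov, tolerance = 1e-8)

  zero <- trajectory(list(mu, mu))
  expect_true(all(suppressWarnings(essential_subspace(zero, k = 3))$all_values == 0))
})

test_that("rmsip is 1 on itself, 0 on complements, symmetric and bounded", {
  d <- 30
  set.seed(77)
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  a <- Q[, 1:10]; b <- Q[, 11:20]
  expect_equal(rmsip(a, a, k = 10)$value, 1, tolerance = 1e-12)
  expect_equal(rmsip(a, b, k = 10)$value, 0, tolerance = 1e-12)
  for (s in 1:25) {
    set.seed(s)
    u <- qr.Q(qr(matrix(rnorm(d * 10), d)))
    v <- qr.Q(qr(matrix(rnorm(d * 10), d)))
    r1 <- rmsip(u, v, k = 10)$value
    expect_gte(r1, 0); expect_lte(r1, 1 + 1e-12)
    expect_equal(r1, rmsip(v, u, k = 10)$value, tolerance = 1e-12)
  }
  expect_error(rmsip(a, Q[1:20, 1:10], k = 10), "dimensions differ")
})

test_that("rmsip is invariant to rotations and sign flips within a span", {
  set.seed(12)
  d <- 30
  u <- qr.Q(qr(matrix(rnorm(d * 10), d)))
  v <- qr.Q(qr(matrix(rnorm(d * 10), d)))
  base <- rmsip(u, v, k = 10)$value
  W <- qr.Q(qr(matrix(rnorm(100), 10)))   # rotation within the span
  expect_equal(rmsip(u %*% W, v, k = 10)$value, base, tolerance = 1e-9)
  flips <- diag(sample(c(-1, 1), 10, replace = TRUE))
  expect_equal(rmsip(u %*% flips, v, k = 10)$value, base, tolerance = 1e-12)
})

test_that("split-halves rmsip is high for a stationary process and errors on degenerate input", {
  mu <- coords_matrix(make_cul3_helix())
  V <- random_modes(nrow(mu), 10, seed = 3)
  lam <- seq(10, 1, length.out = 10)
  tr <- simulate_trajectory(mu, V, lam, iso_sd = 0.05, n_frames = 4000, seed = 5)
  expect_gt(split_halves_rmsip(tr, k = 10)$value, 0.9)

  # halves driven by disjoint mode sets: near the random-overlap baseline
  V20 <- random_modes(nrow(mu), 20, seed = 8)
  t1 <- simulate_trajectory(mu, V20[, 1:10], lam, n_frames = 300, seed = 1)
  t2 <- simulate_trajectory(mu, V20[, 11:20], lam, n_frames = 300, seed = 2)
  joint <- trajectory(array(c(aperm(t1$coords, c(1, 2, 3)),
                              aperm(t2$coords, c(1, 2, 3))),
                            c(600, nrow(mu), 3)))
  lo <- split_halves_rmsip(joint, k = 10)$value
  expect_lt(lo, sqrt(10 / 30) + 0.15)

  rep1 <- trajectory(list(mu, mu, mu, mu))
  expect_error(suppressWarnings(split_halves_rmsip(rep1, k = 2)), "degenerate")
  expect_error(split_halves_rmsip(trajectory(list(mu, mu)), k = 2), "too short")
})

test_that("secondary structure assignment follows the dihedral windows", {
  ideal <- make_helix(rep("A", 12), phi = -57, psi = -47)
  expect_true(all(ss_assign(ideal)$class == "helix"))
  ext <- make_helix(rep("A", 12), phi = -120, psi = 120)
  expect_false(any(ss_assign(ext)$class %in% c("helix", "3-10")))

  # frayed helix trajectory: high helicity inside the span, low outside
  inspan <- 49:68 >= 54 & 49:68 <= 66
  fr <- make_helix(cul3_tokens, start = 49,
                   phi = ifelse(inspan, -57, -120),
                   psi = ifelse(inspan, -47, 120))
  bb <- fr[fr$name %in% c("N", "CA", "C"), ]
  base <- as.matrix(bb[, c("x", "y", "z")])
  set.seed(31)
  frames <- lapply(1:30, function(i) base + matrix(rnorm(length(base), sd = 0.05),
                                                   nrow(base)))
  tr <- trajectory(frames, topology = structure_model(bb))
  out <- ss_assign(tr)
  hel <- out$helicity
  expect_gt(mean(hel$helicity[hel$res_index %in% 54:66]), 0.8)
  expect_lt(mean(hel$helicity[!hel$res_index %in% 54:66]), 0.2)
})

test_that("contact persistence counts the constructed fraction of frames", {
  top <- structure_model(data.frame(
    serial = 1:4, name = c("N", "O", "H", "C1"), element = c("N", "O", "H", "C"),
    chain = "A", res_index = c(1, 2, 1, 3), res_name = "X",
    x = c(0, 3, 1, 0), y = 0, z = 0))
  near <- rbind(c(0, 0, 0), c(3, 0, 0), c(1, 0, 0), c(10, 0, 0))
  far <- rbind(c(0, 0, 0), c(9, 0, 0), c(1, 0, 0), c(10, 0, 0))
  crit <- list(
    list(id = "hb", type = "hbond", donor = list("A", 1, "N"),
         acceptor = list("A", 2, "O"), hydrogen = list("A", 1, "H")),
    list(id = "never", type = "hbond", donor = list("A", 3, "C1"),
         acceptor = list("A", 2, "O"))
  )
  always <- trajectory(list(near, near, near, near), topology = top)
  expect_equal(contact_persistence(always, crit)$persistence, c(1, 0))
  half <- trajectory(list(near, far, near, far), topology = top)
  expect_equal(contact_persistence(half, crit[1])$persistence, 0.5)
  missing_crit <- list(list(id = "gone", type = "hbond",
                            donor = list("A", 9, "N"), acceptor = list("A", 2, "O")))
  expect_warning(out <- contact_persistence(always, missing_crit), "absent")
  expect_true(is.na(out$persistence))
})
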