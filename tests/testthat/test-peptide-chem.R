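test_that("residue table masses derive from compositions and tokens are unique", {
  tab <- residue_table()
  expect_false(anyDuplicated(tab$token) > 0)
  expect_equal(tab$mono_mass, formula_mass(tab$composition, "mono"), tolerance = 1e-9)
  expect_equal(tab$avg_mass, formula_mass(tab$composition, "avg"), tolerance = 1e-9)
  # independent oracle values (composition summation, external mass library)
  expect_equal(tab$mono_mass[tab$token == "G"], 57.02146, tolerance = 1e-4)
  expect_equal(tab$mono_mass[tab$token == "W"], 186.07931, tolerance = 1e-4)
  expect_equal(tab$mono_mass[tab$token == "S5"], 139.09971, tolerance = 1e-4)
  expect_true(all(tab$avg_mass >= tab$mono_mass - 1e-6))
})

test_that("terminal modification deltas match the coupling chemistry", {
  tm <- terminal_mods()
  get <- function(n) tm$delta_mono[tm$name == n]
  expect_equal(get("free"), 0)
  expect_equal(get("acetyl"), 42.01056, tolerance = 1e-4)
  expect_equal(get("amide"), -0.98402, tolerance = 1e-4)
  expect_equal(get("biotinyl_Acp"), 339.16166, tolerance = 1e-4)
  expect_equal(get("FITC"), 389.03579, tolerance = 1e-4)
  # terminus restrictions
  expect_error(peptide_construct("x", c("G"), 1, n_mod = "amide"), "C-terminus")
  expect_error(peptide_construct("x", c("G"), 1, c_mod = "acetyl"), "N-terminus")
})

test_that("build_variant produces the characterized variants and rejects bad staples", {
  peps <- cul3_peptides()
  seq_of <- function(p) paste(p$residues$token, collapse = "")
  expect_equal(seq_of(peps$LA), "NSGLSFEES5YRNS5YTMVLHK")
  expect_equal(peps$LA$staple, c(57L, 61L))
  expect_equal(seq_of(peps$EN), "NSGLSFES5LYRS5AYTMVLHK")
  expect_equal(seq_of(peps$AA), "NSGLSFEELARNAATMVLHK")
  expect_null(peps$AA$staple)
  # identity: no substitutions leaves the sequence unchanged
  copy <- build_variant(peps$wt)
  expect_equal(copy$residues, peps$wt$residues)
  expect_equal(seq_of(peps$wt), "NSGLSFEELYRNAYTMVLHK")  # parent unchanged
  # invalid spacing and absent positions
  expect_error(build_variant(peps$wt, c("57" = "S5", "60" = "S5"), c(57, 60)),
               "i \\+ 4")
  expect_error(build_variant(peps$wt, c("12" = "A")), "not in parent")
  expect_error(build_variant(peps$wt, c("57" = "A", "61" = "A"), c(57, 61)), "S5")
})

test_that("peptide_mass reproduces composition-summation oracle values", {
  gly <- peptide_construct("g", "G", 1)
  expect_equal(peptide_mass(gly), 75.03203, tolerance = 1e-4)
  frag1 <- peptide_construct("f1", strsplit("NAYTMVLHK", "")[[1]], 60,
                             c_mod = "amide")
  expect_equal(peptide_mass(frag1), 1074.5644, tolerance = 1e-3)
  frag2 <- peptide_construct("f2", strsplit("NSGLSFEELYR", "")[[1]], 49,
                             n_mod = "acetyl")
  expect_equal(peptide_mass(frag2), 1355.6357, tolerance = 1e-3)
  expect_error(peptide_construct("bad", c("G", "Z9"), 1), "Z9")
})

test_that("closed staple mass equals open staple mass minus ethylene", {
  peps <- cul3_peptides()
  open <- peps$LA
  open$staple_closed <- FALSE
  for (kind in c("mono", "avg")) {
    expect_equal(peptide_mass(peps$LA, kind),
                 peptide_mass(open, kind) - formula_mass("C2H4", kind),
                 tolerance = 1e-9)
    expect_gte(peptide_mass(peps$LA, "avg"), peptide_mass(peps$LA, "mono"))
  }
})

test_that("fragment enumeration matches the brute-force span count law", {
  wt <- cul3_peptides()$wt
  expect_equal(nrow(enumerate_fragments(wt)), 1L)
  expect_equal(enumerate_fragments(wt)$sequence, "NSGLSFEELYRNAYTMVLHK")
  for (cuts in list(c(58L), c(58L, 59L), c(52L, 58L, 63L), c(50L, 55L, 60L, 65L))) {
    fr <- enumerate_fragments(wt, cuts)
    k <- length(cuts)
    expect_equal(nrow(fr), k * (k + 3) / 2 + 1)
    expect_equal(nrow(fr), length(brute_spans(49L, 68L, cuts)))
  }
})

test_that("fragments inherit terminal modifications only at parent termini", {
  fr <- enumerate_fragments(cul3_peptides()$wt, c(58, 59))
  row <- function(s, e) fr[fr$start == s & fr$end == e, ]
  expect_equal(row(49, 58)$n_mod, "acetyl")
  expect_equal(row(49, 58)$c_mod, "free")
  expect_equal(row(60, 68)$n_mod, "free")
  expect_equal(row(60, 68)$c_mod, "amide")
  expect_equal(row(59, 59)$n_mod, "free")
})

test_that("closed-staple fragments never contain exactly one staple endpoint", {
  la <- cul3_peptides()$LA
  for (cuts in list(c(58L, 59L), c(55L, 58L, 60L), c(50L, 59L, 62L, 65L))) {
    fr <- enumerate_fragments(la, cuts)
    has_i <- fr$start <= 57 & 57 <= fr$end
    has_j <- fr$start <= 61 & 61 <= fr$end
    expect_true(all(has_i == has_j))
  }
})

test_that("masses are additive over any full partition of an unstapled peptide", {
  wt <- cul3_peptides()$wt
  water <- formula_mass("H2O", "mono")
  for (cuts in list(c(58L), c(52L, 58L, 63L))) {
    fr <- enumerate_fragments(wt, cuts)
    # full partition: consecutive spans covering 49..68
    parts <- fr[fr$start == 49 & fr$end == cuts[1], ]
    bounds <- c(49L, cuts + 1L)
    ends <- c(cuts, 68L)
    part_mass <- sum(purrr::map2_dbl(bounds, ends, function(s, e) {
      fr$mono_mass[fr$start == s & fr$end == e]
    }))
    expect_equal(peptide_mass(wt), part_mass - length(cuts) * water,
                 tolerance = 1e-6)
  }
})

test_that("assign_masses reproduces the proteolysis assignment and handles edge cases", {
  fr <- enumerate_fragments(cul3_peptides()$wt, c(58, 59))
  asg <- assign_masses(c(1075, 1355, 1199), fr, tol = 1.0)
  expect_true(all(asg$assigned))
  expect_equal(asg$sequence, c("NAYTMVLHK", "NSGLSFEELYR", "NSGLSFEELY"))
  expect_equal(asg$n_mod, c("free", "acetyl", "acetyl"))
  expect_equal(asg$c_mod, c("amide", "free", "free"))
  expect_equal(nrow(assign_masses(numeric(), fr)), 0L)
  expect_false(assign_masses(5000, fr, tol = 1.0)$assigned)
  expect_false(assign_masses(1075, fr[0, ], tol = 1.0)$assigned)
})

test_that("half-life fit is exact on noiseless data and flags non-decay", {
  d <- simulate_decay(t_half = 420, noise_sd = 0, seed = 1)
  fit <- fit_half_life(d)
  expect_equal(fit$t_half, 420, tolerance = 1e-6)
  expect_equal(fit$k, log(2) / 420, tolerance = 1e-6)
  expect_false(fit$no_decay)
  expect_equal(glance(fit)$t_half, fit$t_half)
  expect_equal(tidy(fit)$estimate[1], fit$k)

  flat <- data.frame(time_min = c(0, 60, 120, 180, 360, 900), fraction = 1)
  expect_true(fit_half_life(flat)$no_decay)
  expect_identical(fit_half_life(flat)$t_half, Inf)

  grow <- data.frame(time_min = c(0, 60, 120, 180, 360),
                     fraction = c(0.2, 0.3, 0.5, 0.8, 1.0))
  expect_error(fit_half_life(grow), "not positive")
})

test_that("half-life recovery is unbiased at low noise over seeded replicates", {
  ks <- vapply(1:1000, function(i) {
    fit_half_life(simulate_decay(t_half = 420, noise_sd = 0.01, seed = 5000 + i))$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - log(2) / 420) / (log(2) / 420), 0.02)
})
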