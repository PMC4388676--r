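---
title: "Designing and characterizing hydrocarbon-stapled helical peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and characterizing hydrocarbon-stapled helical peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staplekit)
```

## The problem

Protein-protein interfaces mediated by a single helix can be attacked with a
peptide that mimics that helix, but short peptides excised from their protein
context usually lose helicity. An all-hydrocarbon staple — two
alpha,alpha-disubstituted alkenyl residues at positions i and i+4, closed by
ring-closing metathesis — can restore it. The worked system in this package
is the Cullin3 helix 2 (residues 49-68, `NSGLSFEELYRNAYTMVLHK`), which binds
the BTB domain of substrate adaptors such as KCTD11; the package covers the
computational side of a design campaign on such a system end to end:

1. locate the interface hot spots of the bound helix (per-residue buried
   surface area);
2. choose i,i+4 staple positions among solvent-exposed residues that spare
   those hot spots;
3. verify trajectory quality for the simulations behind step 1 (RMSD, RMSF,
   essential-dynamics convergence via RMSIP);
4. handle the chemistry bookkeeping: masses of constructs with the
   non-standard S5 residue, terminal modifications, proteolytic fragments,
   LC-MS assignment, serum half-lives;
5. fit binding (fluorescence polarization, ELISA ranking, competition) and
   helicity readouts (CD mean-residue ellipticity, H-alpha secondary
   chemical shifts).

Every input has a seeded synthetic generator with recorded ground truth, so
the whole pipeline is testable without simulation output or instrument
files.

## Buried area and staple-site selection

`sasa()` implements Shrake-Rupley solvent accessibility with a deterministic
Fibonacci lattice (default 960 points per atom, probe 1.4 Å) — no random
number generator, so areas are bit-reproducible and the lattice density is
an explicit convergence dial (the test suite checks 960 vs 3840 points agree
within 1% on a 20-residue helix, and 960 points against the analytic
two-sphere formula within 2%). Radii come from a Bondi-style element table
(`vdw_radii()`); hydrogens are excluded by default (united-atom convention).
`buried_area()` computes, per binder residue, SASA(binder alone) minus
SASA(binder in complex) with the same lattice on both sides, and returns the
receptor-side profile too; for rigid components the profile is non-negative
and the two sides agree to within a few percent.

`classify_exposure()` turns a buried-area profile into three classes:
*exposed* (buried area at most `exposed_max`, default 5 Å² — effectively
"not part of the interface"), *hotspot* (at least `hotspot_min` = 0.7 of the
profile maximum), and *intermediate*. Design narratives in this field use
qualitative classes (a residue is "completely solvent-exposed", or carries
one of the "largest buried areas"); the two thresholds are this package's
quantitative rendering of those classes and are recorded in the output
attributes. `enumerate_staples()` ranks all i,i+4 pairs: pairs whose
endpoints are both exposed and that touch no hot spot form the top tier,
ordered by summed endpoint burial (ascending, ties to the lower position).
Pairs reaching outside the annotated helix are *flagged, not removed* —
stapling a frayed helix cap to force local structure is a legitimate design
(the Cul3 SL variant is exactly that), so the tool must be able to emit
it. On the shipped Cul3 exposure fixture (`cul3_exposure_fixture()`, hot spots 54/58/62,
exposed 56/57/60/61, helix 54-66) the top tier is exactly (56, 60) and
(57, 61), and (53, 57) is emitted with an outside-helix flag.

One open point: Arg59 is buried but not aromatic. We treat any non-exposed
endpoint as down-ranking (second tier) rather than excluding it — the
design logic penalizes, but does not forbid, stapling over buried non-hot-spot
residues.

```{r}
exposure <- classify_exposure(cul3_exposure_fixture())
enumerate_staples(c(49, 68), exposure, helix = c(54, 66)) |> head(4)
```

## Trajectory analysis and RMSIP

`essential_subspace()` diagonalizes the 3N x 3N covariance of C-alpha
coordinates about the window mean (C-alpha only, unit masses — the usual
convention for essential-dynamics analyses). The convergence statistic is the root
mean square inner product between the first k = 10 eigenvectors of the two
halves of the equilibrated window:

$$\mathrm{RMSIP} = \sqrt{\frac{1}{k} \sum_{i=1}^{k} \sum_{j=1}^{k}
\left(\eta_i^a \cdot \eta_j^b\right)^2}$$

Displayed forms of this statistic occasionally omit the explicit square
root; we implement the square-rooted form, which is the standard
definition, is bounded in [0, 1], and equals 1 for identical subspaces.
RMSIP is invariant to sign flips and to any rotation of a basis within its own span, so degenerate
(tied-eigenvalue) spectra are safe; this is tested explicitly. For random
k-dimensional subspaces of a d-dimensional space the expected value is
approximately sqrt(k/d) (0.577 for 10 of 30), which the test suite verifies
by Monte Carlo — useful as the "no convergence" baseline when judging
values in the 0.6-0.7 range that well-converged cluster-scale simulations
typically report. Reproducing any particular simulation's RMSIP is out of
scope: that requires the original trajectory.

Windows are supplied explicitly (`window = c(t_start, t_end)` in ns); there
is no automatic equilibration detection. Secondary structure along a
trajectory (`ss_assign()`) uses phi/psi windows rather than hydrogen-bond
assignment because C-alpha/backbone-only trajectories lack the atoms DSSP
needs: alpha-helix is phi in [-100, -30] and psi in [-67, -7] sustained over
at least 4 residues; the 3-10 variant window sits above it in psi (psi in
(-7, 33], run of 3); helical-basin residues outside a qualifying run count
as turn/bend. `contact_persistence()` scores hydrogen bonds on
donor-acceptor distance <= 3.5 Å (plus a 120 degree D-H...A angle when a
hydrogen is present; both are standard defaults, exposed as arguments) and
aromatic clustering on ring-centroid distance <= 7 Å.

## Peptide chemistry

All masses derive from one elemental-composition table (`formula_mass()`):
residue masses, water, terminal modifications, and the staple. The stapling
residue S5 ((S)-2-(4'-pentenyl)alanine) is the condensed residue C8H13NO;
closing the bridge by ring-closing metathesis releases one ethylene
(-28.0313 Da monoisotopic). Terminal chemistry: acetyl +42.0106, C-terminal
amide -0.9840, N-(+)-biotinyl-6-aminocaproyl +339.1617 (amide coupling,
minus water), FITC +389.0358 (isothiocyanate plus amine gives a thiourea,
no atom loss). The FITC and biotinyl deltas follow from the
conventional coupling chemistry of those reagents (thiourea formation and
amide condensation respectively); where a protocol leaves the linkage
unstated, these are the documented assumptions.

`enumerate_fragments()` models *partial* digestion: cleavage sites mean
"cut after this residue", and every contiguous span delimited by the ends
and any subset of cuts is emitted — which is why overlapping fragments
(49-58 and 49-59) coexist in a serum digest. Fragments inherit a terminal
modification only when they retain that terminus of the parent; for a
closed staple, spans holding exactly one of the two bridged positions are
impossible (the hydrocarbon tether holds them together) and are excluded.
For k usable cuts on an unstapled peptide the span count is k(k+3)/2 + 1.
`assign_masses()` matches observed LC-MS masses to fragments within a
tolerance (default 1 Da, ion-trap ESI accuracy; comparisons use
monoisotopic masses), ties broken toward the longer span then the lower
start. `fit_half_life()` fits exp(-k t) to the intact fraction with a
log-linear initialization and Levenberg-Marquardt refinement; a series
indistinguishable from 1.0 returns an infinite-half-life flag, and
systematically increasing series are rejected as non-decay data.

## Binding assays

The one-site fluorescence-polarization model is

$$FP - FP_0 = \frac{B_{max} \, [R]}{K_D + [R]}$$

with the receptor concentration in monomer units and the *added*
concentration treated as free. That free-ligand assumption is formally
violated when the probe concentration (2 uM in the emulated assay) exceeds
a sub-micromolar K_D; we keep the plain hyperbola as the default for
comparability with routine practice and provide the quadratic depletion
model behind `depletion = TRUE`. K_D is initialized on
a 40-point log grid (linear least squares in B_max and FP_0 at each trial
K_D) and refined with `minpack.lm`; fits that do not significantly improve
on a flat response (F-test at 0.05) return a no-binding flag instead of an
arbitrary K_D. Standard errors come from the fit covariance and the 95%
interval is Wald-type; reported errors on literature dissociation constants
of this kind are the standard error of triplicates, and `tidy()` exposes
both the SE and the interval so either convention can be quoted.
Unweighted least squares is the default, matching common practice with
standard fitting packages; inverse-variance weights can be applied by the
caller.

ELISA series are control-subtracted (`normalize_elisa()`, floored at zero)
and ranked by trapezoidal area under the curve with the plateau reported as
the mean of the two highest concentrations — a deliberately qualitative
ranking, matching how such panels are read. `fit_competition()` is a
four-parameter logistic used only as a displacement control.

## Helicity readouts

`to_mre()` converts raw ellipticity to mean-residue molar ellipticity,
theta / (10 c l n). `helix_fraction_222()` is a two-state single-wavelength
estimate with coil limit +640 and chain-length-corrected helix limit
-40000 (1 - 2.5/n) deg cm² dmol⁻¹: it is labelled *approximate* in its
output and is not a spectral deconvolution — ratios produced by basis-set
deconvolution programs are not comparable to it and are not reproduced
here. `csd()` subtracts a shipped Wishart-style random-coil H-alpha table
(`random_coil_shifts()`), a documented stand-in compiled from literature
consensus values and user-overridable; S5 is mapped to the alanine value. `call_helix_spans()` reports maximal runs
of at least 4 residues at or below a negative threshold (default -0.1 ppm,
CSI-style; a convention, exposed as configuration rather than fixed), never
merging runs across a violating residue. `ssp_profile()` is a windowed, normalized CSD profile — a
transparent stand-in for secondary-structure-propensity software, not a
reimplementation of it.

## Synthetic data: what it does and does not emulate

The generators produce exactly the study's input shapes with known truth:

- `make_helix()` builds ideal backbone geometry from standard bond lengths
  and angles with per-residue phi/psi (so frayed termini are just vectors of
  torsions); `make_groove_complex()` packs deterministic carbon pseudo-atom
  caps at 4.5 Å (non-bonded C-C packing) against the side chains of a
  designated contact face — the ground-truth interface is the face, by
  construction.
- `simulate_trajectory()` draws frames from mean + sum_k sqrt(lambda_k)
  z_k v_k + isotropic noise, i.e. an exactly low-rank-plus-diagonal
  covariance, giving closed forms for RMSF and the essential spectrum.
- `simulate_fp()` / `simulate_elisa()` / `simulate_decay()` /
  `simulate_shifts()` add Gaussian noise to the respective model curves on
  preset grids matching the assays (FP: six log-spaced points over the
  tested 0.1 nM - 20 uM receptor range; ELISA: 0.4-15.6 uM; decay: 0, 60,
  120, 180, 360, 900 min; shifts: a uniform -0.35 ppm block over the
  helical span).

What they deliberately do not emulate: force-field energetics, correlated
(non-Gaussian, time-autocorrelated) MD fluctuations, real side-chain
packing in the groove, isotope envelopes and charge states in MS, probe
depletion and plate effects in FP/ELISA, and residue-specific shift
dispersion. Passing the recovery tests therefore demonstrates that the
estimators are correct under their stated models at realistic noise, not
that the models capture every feature of real data.

## Numerical choices and problem sizes

- SASA lattice 960 points/atom (tests also run 3840); probe 1.4 Å.
- Kabsch superposition via SVD with determinant correction; collinear
  selections return a `degenerate` flag rather than an arbitrary rotation.
- Eigendecomposition by `eigen(symmetric = TRUE)`; eigenvalues clipped at
  zero; population (1/n) covariance normalization.
- Monte-Carlo suite sizes used by the tests: 1000 FP replicates at 3 mP
  noise, 500 decay replicates at 0.03 noise (plus 1000 at 0.01 for the bias
  bound), 1000 random-subspace RMSIP draws, 5000-frame trajectories for
  eigenvalue recovery. These sizes give stable statistics in about a minute
  of total test time.
- All generator seeds are explicit arguments; identical spec + seed is
  bit-identical output.

## Limitations

- The 222 nm helix estimator is coarse; use it for ranking, not
  quantitation.
- The FP model ignores probe depletion by default (see above).
- Proteolysis is user-specified cut sites; there is no enzyme-specificity
  prediction.
- Buried-area thresholds (5 Å², 0.7) are calibrated to the shipped fixture
  scale; profiles computed with very different probe/density settings may
  need different thresholds.
- The random-coil shift table and the SSP-style profile are documented
  stand-ins, chosen for transparency over fidelity to any specific
  published tool.
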