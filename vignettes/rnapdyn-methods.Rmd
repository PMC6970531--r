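---
title: "Methods: measuring RNAP domain motions, clamp heterogeneity, and initiation flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring RNAP domain motions, clamp heterogeneity, and initiation flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnapdyn)
```

This vignette is the package's own account of its models, numerical
choices, and limitations. Bacterial RNA polymerase (RNAP) is a
crab-claw-shaped machine whose mobile modules — the clamp (β′ pincer
plus σ70 region 2), the β′shelf/jaw, the βlobe with its Si1 insertion,
the Si3 insertion in the trigger loop, and the bridge helix spanning the
cleft — move as near-rigid bodies. Secondary-channel regulators such as
TraR act purely allosterically: they change which conformations the
enzyme samples, and thereby change transcription output in a
promoter-dependent way. The package quantifies those three things:
discrete rigid-body motions between models, the continuous width of a
conformational distribution, and the kinetic consequences on a model
promoter.

## 1. Rigid-body geometry

### Superposition and RMSD

`superpose()` solves the orthogonal Procrustes problem in closed form:
with paired, centered coordinate sets A and B and covariance
H = Bᵀ·A (weighted if requested), the SVD H = U·D·Vᵀ gives
R = V·diag(1, 1, det(V·Uᵀ))·Uᵀ. The determinant correction guarantees a
proper rotation is always returned; when the smallest singular value is
near zero (planar or collinear points) a conditioning warning is raised
instead of silently reflecting. The test suite cross-checks the reported
RMSD against an independent quaternion (absolute-orientation)
implementation on 10,000 random clouds to 1e-9.

Atom pairing (`pair_common_atoms()`) matches on (chain, author residue
number, insertion code, atom name) — models of the same protein are
assumed to share author numbering, and no sequence alignment is
attempted. `rmsd_between()` composes pairing, optional
exclusion (e.g. "all Cα except the Si3 insertion β′ 948–1126"), and
superposition.

### Domain rotations

`domain_rotation()` uses the standard two-stage convention: align the
two models on a structural core, then fit the residual rigid transform
carrying the domain of one model onto the (core-aligned) domain of the
other, and decompose it as a screw motion. The angle is
arccos((tr R − 1)/2); the axis comes from the antisymmetric part of R,
switching above 135° to the exact symmetric-part identity
(R + Rᵀ)/2 = cos θ·I + (1 − cos θ)·a·aᵀ, whose accuracy does not degrade
as sin θ → 0. Below 0.1° the axis is numerically undefined and flagged
unreliable. The pivot is reported as the point on the axis nearest the
domain centroid. Round-tripping rotation → (axis, angle) → rotation
reproduces the matrix to 1e-6 for angles in (0.1°, 179.9°).

On noise-free synthetic two-domain constructs the recovery is exact to
1e-6 for all angles the package was designed around (1°, 4.5°, 18°,
121° — clamp-scale, shelf, lobe, and Si3-flip magnitudes). With 0.2 Å
isotropic coordinate noise on one model and 150-atom domains, the Monte
Carlo mean absolute recovery error over 100 seeds is below 0.3° (single
seeds occasionally reach ~0.33°; the package quotes and tests the mean,
since the per-seed extreme depends on cluster size and lever arm, which
are free parameters of the construct).

### Helix kinks

`kink_angle()` fits an axis to the Cα of the upstream and the downstream
flank of the kink residue (12 residues each by default, at least 6
required) and reports the angle between the axes, oriented N→C. The
axis estimator is the second-difference construction: for points on a
regular helix, p(i) − 2p(i+1) + p(i+2) is exactly perpendicular to the
helix axis, so the axis is the smallest-variance eigenvector of those
vectors' covariance. A centered principal-component fit of the raw
coordinates was considered and rejected: on a 12-residue window (3.33
helical turns) the centroid lies off the helix axis and the principal
axis tilts by a systematic ~4°, which would swamp a ±1° recovery target;
the second-difference axis is exact on ideal helices regardless of
fractional turns. Kink values still depend on the flank window on real,
irregular helices, so the window is configurable and reported kinks
should be quoted with that setting.

### Distances and interface area

`min_distance()` is the exact minimum over all cross pairs (verified
against a brute-force double loop). `interface_area()` uses the
one-sided buried-area convention (SASA(a) + SASA(b) − SASA(a∪b))/2 with
Shrake–Rupley sampling: 960 golden-spiral points per atom, probe 1.4 Å,
standard van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80, Mg 1.73,
Zn 1.39 Å, default 1.70 Å for unlisted elements). Against the
closed-form two-overlapping-spheres solution the sampled value agrees to
2%; cross-implementation agreement on proteins is method-dependent and
should be treated as ±10%.

## 2. Clamp heterogeneity from multibody eigenvalues

Multibody refinement of a cryo-EM dataset yields one amplitude
("eigenvalue") per particle per principal component of relative body
motion. The package treats each component's amplitudes as a 1-D sample
and asks how wide the underlying conformational distribution is, in
degrees.

The analysis chain and its assumptions:

* **Gaussian fit** (`fit_gaussian()`): either moments ("mle": sample
  mean; *population* standard deviation, dividing by n, because the fit
  describes the observed ensemble rather than estimating a
  superpopulation — the n−1 convention is available via `sd_type`), or a
  least-squares Gaussian fit to the normalized histogram (60 equal-width
  bins spanning μ ± 4σ; bin width is a package choice). Both report the
  same goodness measure (SSR against the normalized histogram) so the
  methods can be compared; on 10⁵ Gaussian draws they agree in σ within
  1%.
* **Equal-count terciles** (`equal_count_bins()`): a stable sort (ties
  keep input order) splits particles into low/mid/high bins whose counts
  never differ by more than one; remainders go low, then mid. 370,965
  particles — the dataset size the clamp analysis was matched at —
  split into exactly 123,655 per bin.
* **Calibration** (`calibrate_rotation()`): the rotation θ_bin between
  the low-bin and high-bin mean conformations is measured *externally*
  (reconstruct per bin, fit models, run `domain_rotation()`); dividing
  by the eigenvalue gap between the outer-bin means gives degrees per
  eigenvalue unit. The linearity of rotation in eigenvalue is an
  assumption inherited from the upstream procedure (the middle bin sits
  half-way between the outer two); it is not checked by the package.
* **98% range** (`estimate_range98()`): θ₉₈ = (°/unit)·2·z·σ with
  z = Φ⁻¹(0.99) = 2.326348 by default (1% excluded per tail;
  configurable).

For Gaussian data these definitions fix the dimensionless ratio
θ₉₈/θ_bin: the outer-tercile means sit 2·3·φ(Φ⁻¹(2/3))·σ ≈ 2.1816σ
apart, so θ₉₈/θ_bin = 4.6527/2.1816 = 2.1327, independent of μ, σ, and
the calibration scale. The suite verifies this at n = 10⁶ within 0.02,
plus shift/scale equivariance of the whole chain. No absolute θ₉₈
values are asserted anywhere — only this ratio and orderings (a
restricted ensemble reports a smaller range than a free one at equal
calibration), because absolute ranges depend on the upstream
reconstruction protocol.

## 3. Initiation flux on a free-energy landscape

Open-complex formation is multi-step: R+P ⇌ RP1 ⇌ RP2 ⇌ RPo, followed
by the irreversible escape into RNA synthesis (RP_ITC). The package
represents a promoter as wells G_i and barriers B_i in units of kBT and
maps them to rates k = A·exp(−(B − G)) with a single prefactor A
(default 1). Consequences, all by construction: detailed balance
k_f/k_r = exp(ΔG) per transition; lowering a barrier by δ multiplies
both of its rates by e^(−δ) leaving its equilibrium fixed; stabilizing
a well shifts only the adjacent equilibria. Absolute time is *not*
interpretable — the landscapes are qualitative — so the package only
ever quotes ratios and fold changes.

The steady state closes the cycle by letting the irreversible output
step regenerate free promoter (the minimal topology admitting a
nonzero steady flux). `steady_state_flux()` solves K·p = 0, Σp = 1
exactly (4×4 linear solve); `ode_steady_state()` integrates the master
equation with lsoda (rtol 1e-12) until max|dp/dt| < 1e-12 as an
independent oracle — the two agree to 1e-8 relative on 1,000 random
schemes, and as k_cat → 0 the occupancies recover the Boltzmann weights
of the landscape to 1e-8.

### Presets and scenarios

The exact rate constants of TraR-regulated promoters are not published
as a usable table, so the shipped presets are **package-defined
archetypes** encoding the two well-established promoter classes, chosen
once on qualitative constraints and frozen:

| preset | wells (kBT) | barriers | final barrier |
|---|---|---|---|
| inhibited_hypothetical | 0, −0.5, −1, −2 | 2, 1.5, 2.5 | 8 |
| activated_hypothetical | 0, −0.5, −1, −8 | 2, 1.5, 6 | −5 |

The inhibited archetype forms RPo fast (all pre-RPo barriers low) but
holds it shallowly — RPo stays in equilibrium with earlier
intermediates and the slow step is escape into synthesis (half-lives of
seconds to minutes motivate the high final barrier). The activated
archetype is the mirror image: the RP2→RPo crossing is rate-limiting
and RPo is very deep (half-lives of hours). The inhibited RP2⇌RPo
barrier is set at 2.5 kBT — the smallest value that keeps every shipped
perturbation above the flanking wells — rather than lower.

Two scenarios apply fixed perturbations, never touching the initial
binding step (consistent with kinetic evidence that these factors leave
the first step alone):

* `traR_scenario()`: −1.5 kBT on the RP1⇌RP2 barrier, −1.0 kBT on the
  RP2 well, −2.5 kBT on the RP2⇌RPo barrier. On the inhibited preset
  this *lowers* flux 0.73× (stabilizing RP2 drains the Boltzmann weight
  of RPo, which is what the output rate sees), while on the activated
  preset the same perturbation *raises* flux 6.1× (the barrier lowering
  wins where the RP2→RPo crossing was rate-limiting). One perturbation,
  two opposite outcomes, decided entirely by the basal landscape.
  An optional `f_dissoc` ∈ (0, 1] scales the output rate in the
  factor-bound scheme (the factor must dissociate before synthesis);
  default 1, i.e. the pure landscape perturbation.
* `sigma11_deletion_scenario()`: region 1.1 of σ70 occupies the DNA
  channel and is ejected late on the path to RPo, so its deletion is
  modeled as lowering only the RP2⇌RPo barrier, by −3.5 kBT by default
  (e^3.5 ≈ 33, the scale of the measured basal-activity increase at an
  activated promoter). On the inhibited preset the fold change is 1.002
  (that transition is nowhere near rate-limiting); on the activated
  preset it is ~21.

Fold changes are invariant to the prefactor and to whether flux is read
per promoter or per unit time, which is why they are the only numbers
the scenarios assert.

## Synthetic data: what it does and does not emulate

The generators produce: ideal Cα helices (rise 1.5 Å, twist 100°,
radius 2.3 Å) with optional known kinks; two-chain rigid clusters
(Gaussian clouds, σ = 8 Å, domain centered 30 Å from the core) with a
known rotation applied about the domain centroid and optional isotropic
Gaussian coordinate noise on the moved copy only; exactly Gaussian
eigenvalue ensembles with a recorded linear eigenvalue→degree map; and
the two preset landscapes. Every generator takes an explicit seed
(default 0), restores the caller's RNG state, and returns its ground
truth alongside the data.

What passing tests on these constructs shows: the estimators are
correct and numerically stable on their stated models. What it does not
show: robustness to real-data pathologies — non-rigid deformation
within a "rigid" domain, irregular helices, heavy-tailed or skewed
eigenvalue distributions (deliberately not simulated), misassigned
author numbering between models, or nonlinearity of the
eigenvalue→rotation map. Measurements on real deposited models should
therefore be reported with the package's stated tolerances (±2° on
domain rotations measured through reconstructions, ±3° on kinks due to
the window dependence, ±10% on interface areas).

## Numerical choices and degenerate inputs

* Alt-locs resolve to highest occupancy, ties to first occurrence;
  insertion codes are kept as distinct residues.
* Selections are normalized (sorted, merged, inclusive author-numbered
  ranges); empty selection results are legal and flagged, but geometry
  operations refuse fewer than 3 pairs.
* The βlobe boundaries are not a published range; the built-in
  `blobe_si1` default (β 151–453) is a package choice, flagged in its
  documentation, and rotations measured with it are approximate.
* Zero-rotation transforms (< 0.1°) report an unreliable axis rather
  than a fabricated one; degenerate (zero-variance) eigenvalue series
  and all-zero rate schemes are errors, not silent results.
* Angles are degrees in all public interfaces; the CLI rounds to 0.1°
  in its human-readable field and keeps full precision in
  `angle_deg_exact`.

## Problem sizes in the shipped checks

The test suite runs entirely on synthetic data at sizes chosen to make
the property checks sharp but quick: 10,000 random clouds for the
superposition oracle, 10⁶ particles for the Gaussian ratio law, 1,000
random schemes for the flux oracle, 100 noise seeds for rotation
recovery. `scripts/acceptance.R` recomputes the headline quantities at
the same or moderately reduced sizes in a few seconds.

## Known limitations

* No sequence alignment: pairing requires consistent author numbering.
* No map handling, no flexible fitting, no multibody refinement itself
  — the package starts where those tools end.
* The kinetic model is unicyclic and deterministic (no stochastic
  simulation, no NTP mass-action extension); presets are archetypes,
  not fits, and cannot be claimed to reproduce any particular measured
  promoter's numbers.
* An optional accession downloader was deliberately left out of the
  library surface; all library code is offline.
```{r session}
sessionInfo()
```
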