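# rnapdyn

Quantitative analysis of conformational regulation of bacterial RNA
polymerase (RNAP), for structural biologists studying how
secondary-channel factors such as TraR (an F-plasmid homolog of
ppGpp/DksA) reshape the enzyme to activate some promoters and inhibit
others.

The package covers three layers of that analysis:

1. **Rigid-body geometry between conformational states.** Optimal
   superposition of atomic models (Kabsch, closed-form SVD with a
   reflection guard), Cα RMSD with include/exclude selections,
   "core-then-domain" rigid-body rotation measurement with full screw
   decomposition (angle θ, unit axis **n**, screw translation, pivot),
   helix kink angles from flank-axis fits, minimum interatomic distances,
   and buried interface area (Shrake–Rupley ΔSASA/2). Models are read
   from PDB or mmCIF; RNAP module boundaries (clamp, β′shelf, Si3, Si1,
   bridge helix) ship as a built-in selection table in author numbering.

2. **Continuous conformational heterogeneity.** Cryo-EM multibody
   refinement assigns each particle an eigenvalue per principal component
   of body motion — a proxy for a continuous coordinate such as clamp
   opening. The package fits Gaussians N(μ, σ²) to eigenvalue histograms,
   splits particles into equal-count terciles, calibrates eigenvalue
   units to degrees from the rotation θ_bin measured between the
   outer-tercile mean conformations, and extrapolates the rotation range
   covering 98% of particles: θ₉₈ = (θ_bin/Δε)·2·z₀.₉₉·σ with
   z₀.₉₉ = 2.3263. For Gaussian data θ₉₈/θ_bin → 2.1327, a ratio the test
   suite verifies at n = 10⁶.

3. **Initiation kinetics on a free-energy landscape.** A four-step
   scheme R+P ⇌ RP1 ⇌ RP2 ⇌ RPo → RP_ITC, with wells G_i and barriers
   B_i in kBT, mapped to rates k = A·exp(−(B−G)) (detailed balance by
   construction) and solved exactly for steady-state occupancies and
   transcription flux J = k_cat·p(RPo), with an independent
   master-equation integrator as oracle. Shipped perturbation scenarios —
   TraR (lower the RP1⇌RP2 barrier, stabilize RP2, lower the RP2⇌RPo
   barrier) and σ70 region 1.1 deletion (lower the RP2⇌RPo barrier
   only) — applied to preset "inhibited" and "activated" promoter
   landscapes reproduce differential regulation from one shared
   perturbation.

Synthetic generators with recorded ground truth (ideal/kinked helices,
two-domain models with known rotations, Gaussian eigenvalue ensembles,
preset landscapes) make every layer testable end-to-end without any
external data.

## Worked example

```r
library(rnapdyn)

## 1. measure a known 18-degree domain rotation between two models
td <- make_two_domain_model(core_n = 60, domain_n = 60, angle = 18,
                            axis = c(1, -2, 0.7), seed = 1)
domain_rotation(td$reference, td$moved,
                core_sel = parse_selection("A:1-60"),
                domain_sel = parse_selection("B:1-60"))
#> <axis_angle> 18.000 deg about (0.4268, -0.8536, 0.2988)
#>   screw translation 0.000 Angstrom; pivot (29.32, 0.64, 0.87)

## 2. clamp heterogeneity: tercile binning and the 98% rotation range
sim <- simulate_eigenvalues(370965, mu = 0, sigma = 1,
                            degrees_per_unit = 1.2376, seed = 1)
bins <- equal_count_bins(sim$series)
bins
#> <bin_assignment> low 123655 / mid 123655 / high 123655
gap <- mean(sim$series$values[bins$labels == "high"]) -
  mean(sim$series$values[bins$labels == "low"])
cal <- calibrate_rotation(1.2376 * gap, sim$series, bins)
estimate_range98(fit_gaussian(sim$series), cal,
                 component_label = "opening/closing")
#> <range_estimate> opening/closing: theta_bin 2.702 deg, theta_98 5.762 deg (z 2.3263)

## 3. one TraR perturbation, two opposite regulatory outcomes
traR_scenario(preset_landscapes()$activated_hypothetical)$fold_change
#> [1] 6.08   (activation)
traR_scenario(preset_landscapes()$inhibited_hypothetical)$fold_change
#> [1] 0.73   (inhibition)
```

The rotation comes back at exactly the applied 18° with the applied unit
axis; the 370,965 simulated particles split into three bins of 123,655;
θ₉₈/θ_bin ≈ 2.13 as the Gaussian model predicts; and the same composite
TraR perturbation raises flux 6-fold on the activated-promoter landscape
while cutting it to 0.73× on the inhibited one.

A command-line wrapper is installed under `exec/rnapdyn`
(subcommands `rmsd`, `domain-rotation`, `kink`, `distance`, `interface`,
`clamp-range`, `flux`, `simulate`), each emitting a JSON summary with an
embedded run manifest.

## Scope

Upstream cryo-EM image processing (motion correction, classification,
refinement, multibody refinement itself) and atomic model
building/refinement are out of scope: the package starts from deposited
coordinate models and per-particle eigenvalue tables. The kinetic
presets are package-defined archetypes, not fitted rate constants; only
ratios and fold changes are meaningful (see the methods vignette).
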