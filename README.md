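# glycomd

Analysis of protein–glycan molecular-dynamics trajectories in R:

* **Pose analysis** — receptor-fitted ligand RMSD series, pairwise
  2D-RMSD matrices, average-linkage pose clustering with populations
  and medoids, representative-frame extraction (Kabsch superposition,
  proper rotations only).
* **Glycan conformation** — glycosidic linkage detection with phi/psi
  torsion series (sialic-acid-specific definitions), per-linkage-class
  strain-energy scoring with mirror handling for alpha-L sugars, and
  Cremer–Pople ring puckering (4C1/1C4 chairs).
* **Interactions** — hydrogen-bond occupancy (distance + angle
  criteria, frame-weighted pooling over runs), water-density voxel
  maps with OpenDX export, and Ca²⁺–water–sulfate bridge detection.
* **Energetics** — single-trajectory MM-GBSA interaction energies:
  Coulomb (configurable internal dielectric), Lennard-Jones, GB-OBC
  polar solvation, Shrake–Rupley SASA nonpolar term; exact per-group
  decomposition; alanine truncation and residue removal for
  computational mutagenesis.
* **Entropy** — quasiharmonic entropy from the mass-weighted Cartesian
  covariance with 1/t infinite-sampling extrapolation, and
  Karplus–Kushick torsional entropy (bound vs free).
* **Reporting** — binding free-energy assembly
  `dG_binding = dG_MM/GBSA + (-TdS)` with quadrature SDs, integer
  percent contributions, run-level statistics and two-sample t tests.
* **Synthetic data** — generators with closed-form ground truth
  (harmonic baths, Gaussian torsion ensembles, a toy receptor–glycan
  complex with planted poses, hydrogen bonds and water bridges), so
  every stage is testable without external trajectories.

## Worked example

Generate two replicate runs of the synthetic bound complex and drive
the full pipeline:

```r
library(glycomd)

runs <- lapply(1:2, function(r)
  gen_toy_complex("stable", n_frames = 200, seed = r, run_id = r))

pr <- run_pipeline(runs,
                   analysis_config(n_snapshots = 20, entropy_windows = 5),
                   outdir = "demo", label = "toy complex")
print(pr)
#> pipeline for toy complex -- status 0
#>   poses    ok
#>   torsions ok
#>   hbonds   ok
#>   energy   ok
#>   entropy  ok
#>   report   ok

list.files("demo")
#>  [1] "config.json"          "energy_pergroup.csv"  "energy.csv"
#>  [4] "entropy.csv"          "hbonds.csv"           "pose_populations.csv"
#>  [7] "poses.csv"            "report.csv"           "representative.pdb"
#> [10] "rmsd_series.csv"      "summary.json"         "torsions.csv"
```

The MM-GBSA components of the toy complex show the classic
cancellation between electrostatic attraction and GB desolvation of a
charged ligand:

```r
mm <- mmgbsa_interaction(lapply(runs, `[[`, "trajectory"),
                         runs[[1]]$params, n_snapshots = 20)
round(mm$mean, 2)
#>  E_elec   E_vdW   dG_GB dG_SASA   total
#>  -55.78    5.05   52.62   -1.85    0.03
```

Pose clustering recovers planted dwell fractions exactly:

```r
multi <- gen_toy_complex("multi-pose", n_frames = 300, seed = 7,
                         dwell_fractions = c(0.5, 0.3, 0.2))
m <- pairwise_rmsd_matrix(multi$trajectory, "ring_atoms",
                          fit_selection = "receptor")
cluster_poses(m, cutoff = 1.5)$populations
#> [1] 0.5 0.3 0.2
```

Binding reports assemble from energy and entropy blocks, with integer
percent contributions when the overall total is meaningful:

```r
print(assemble_binding(-25.4, entropy_estimate(19.2, 2.3),
                       label = "complex A"))
#> complex A
#>   dG_MM/GBSA : -25.4 kcal/mol
#>   -TdS       : 21.5 kcal/mol
#>   dG_binding : -3.9 kcal/mol

percent_contributions(data.frame(group = c("Fuc", "Neu5Ac"),
                                 energy = c(-13.2, -3.6)),
                      total = -25.4)$percent
#> [1] "52%" "14%"
```

Complex-vs-complex comparisons accept raw per-run values or summary
statistics:

```r
print(compare_complexes(list(mean = -24.8, sd = 1.0, n = 3),
                        list(mean = -25.4, sd = 0.7, n = 3),
                        labels = c("sulfated", "parent")))
#> sulfated vs parent: ddG = 0.6 kcal/mol
#>   pooled t = 0.8514, df = 4, two-tailed P = 0.4425
```

A ligand that leaves the binding site trips an instability gate: the
energy, entropy and report stages are withheld with the message
`unstable ligand -- energies not reported`, while pose and
hydrogen-bond analyses still complete and the pipeline exits with
status 0 (instability is a finding, not a failure).

## Documentation

See the methods vignette (`vignettes/glycomd-methods.Rmd`) for a tour
of every module on synthetic data with planted ground truth, and the
help pages of `run_pipeline()`, `mmgbsa_interaction()`,
`quasiharmonic_entropy()`, `torsional_entropy_kk()`,
`cluster_poses()` and `gen_toy_complex()` for details.

## Testing

```r
testthat::test_dir("tests/testthat")
```

The suite validates each estimator against closed-form oracles (Born
ion GB energy, harmonic-bath quasiharmonic entropy, Gaussian-torsion
Karplus–Kushick entropy, exact 1/t extrapolation) and each detector
against the generators' planted truths. `scripts/acceptance.R` writes
the headline quantities to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```
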