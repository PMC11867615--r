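# protacdyn

Structural-dynamics analysis of PROTAC-induced protein degradation
machinery, in R.

PROTACs (PROteolysis TArgeting Chimeras) are heterobifunctional degraders:
one warhead binds an E3 ligase (here Cereblon, CRBN), the other a target
protein (here the first bromodomain of BRD4), and a linker joins them.
Forming the ternary CRBN–PROTAC–BRD4 complex is necessary but not
sufficient for degradation — the full CRL4A machinery (DDB1, CUL4A, Rbx1,
NEDD8, E2, ubiquitin) must arrange a surface lysine of the target into the
E2/ubiquitin catalytic pocket. `protacdyn` implements the modelling and
trajectory-analysis toolchain for studying that arrangement:

* **Assembly** — Kabsch superposition of ternary models onto ligase
  scaffolds via the shared CRBN, inter-chain clash screening, scaffold
  classification by the CRBN-to-E2 interface gap (ring-forming cluster A
  &lt; 10 Å, ring-open cluster B ≥ 10 Å, clashing cluster C discarded), and a
  retention filter keeping assemblies whose minimum Lys(NZ)–Gly75(O)
  distance is ≤ 16 Å.
* **Ubiquitination competence** — per-frame flags requiring
  d(Lys NZ, Gly C) &lt; 10 Å **and** d(Asp O, Gly O) &lt; 6 Å, with the
  fraction of competent frames as the summary statistic.
* **Circular dihedral statistics** — resultant-vector circular means,
  shortest-arc deviations `atan2(sin(x−x̄), cos(x−x̄))`, wrap-safe Pearson
  correlation of angle series, dihedral Gibbs entropy
  `T·S = −R·T·Σ pᵢ ln pᵢ` over 10° bins, and time-lagged correlation
  between a pseudo-dihedral and a reactive-pair distance.
* **Force networks** — residue-pair nonbonded forces (Lennard-Jones +
  Coulomb, 10 Å cutoff, pN units), elimination of pairs within ±10 pN,
  and strongest-coupling shortest paths (edge weight `1/|force|`).
* **Backbone PCA** — iterative-mean alignment, covariance
  eigendecomposition, per-mode variance fractions and projections.
* **Synthetic data** — toy multi-chain complexes with labelled reactive
  atoms at exact requested distances, trajectories with planted orthonormal
  collective modes, coupled angle/distance series with a planted lag, and
  force matrices with a planted strong path, so every estimator is tested
  against known ground truth.

## Worked example

```r
library(protacdyn)

# a toy machinery complex: 12 surface lysines, K99 NZ planted 8 A from
# ubiquitin's Gly75 C, the E2 Asp carboxylate 5 A from Gly75 O
sys <- make_toy_complex()
min_lys_gly_distance(sys, gly_atom = "O")
#> $residue
#> [1] 99
#> $distance
#> [1] 7.730592

# coupled series with a planted 65-sample lag, recovered by the estimator
ser <- simulate_coupled_series(synthetic_spec(seed = 3))
lagged_correlation(ser$angle, ser$distance, max_lag = 200)
#> lag_correlation: peak r = 0.904 at lag 65 frames (3.25 ns)

# dihedral Gibbs entropy of the torsion walk (kcal/mol at 300 K);
# the uniform-distribution ceiling over 36 bins is RT ln 36 = 2.136
dihedral_entropy(ser$angle)
#> [1] 1.884772

# planted 4:1 two-mode trajectory: PCA recovers fractions (0.8, 0.2)
traj <- simulate_trajectory(sys, synthetic_spec(seed = 2, n_frames = 200,
                            mode_amplitudes = c(2, 1), noise_sd = 0))
pca_trajectory(traj, selection = seq_len(nrow(sys$atoms)))
#> pca_result: 200 modes over 93 atoms
#>   leading variance fractions: 0.800 0.200 0.000 0.000 0.000
```

The minimum-distance call reports the argmin lysine (K99) and its NZ to
Gly75-O distance; the lag-correlation peak at 65 frames with r ≈ 0.9 is the
planted coupling read back by the estimator; the PCA fractions reproduce
the planted 4:1 variance ratio.

The end-to-end demo (`run_pipeline(pipeline_config(seed = 1))`) assembles
toy ternary conformations over nine scaffolds, applies the retention
filter, and runs the competence, series, force-network and PCA stages,
writing stage CSVs plus a deterministic JSON manifest.

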