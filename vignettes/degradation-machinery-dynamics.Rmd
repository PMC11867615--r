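---
title: "Modelling and quantifying PROTAC degradation-machinery dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying PROTAC degradation-machinery dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protacdyn)
```

## The scientific problem

A PROTAC recruits an E3 ligase (CRBN) and a target protein (BRD4's first
bromodomain) into a ternary complex, but degradation requires more: within
the assembled CRL4A machinery (DDB1/CUL4A/Rbx1/NEDD8/E2/ubiquitin), a
surface lysine of the target must reach the E2/ubiquitin catalytic pocket
so that its side-chain ε-amine can attack the C-terminal glycine (Gly75) of
ubiquitin, with an E2 aspartate positioned to support the charge transfer.
Ternary complexes with nearly identical static contacts can therefore
degrade with very different potency: what differs is the *dynamics* the
linker imparts to the whole machine. `protacdyn` implements the modelling
and analysis chain for this question — machinery assembly with geometric
retention filters, and trajectory observables that quantify whether and
when the catalytic geometry is reached.

## Assembly model and its thresholds

Ternary conformations are mounted onto ligase scaffolds by least-squares
rigid superposition (Kabsch, SVD with determinant correction so a
reflection is never returned) of the shared CRBN Cα set; the transform is
applied to the whole ternary and the scaffold's CRBN copy is kept. Three
geometric rules, all surfaced as configuration with these defaults, filter
the combinatorial space:

* **Clash screening**: inter-chain heavy-atom pairs closer than 2.0 Å.
  No numeric criterion is standard for bead-level models; 2.0 Å is below
  any physical heavy-atom contact distance, so anything under it is a true
  overlap. A cell-list grid keeps the scan linear in atom count.
* **Scaffold classification**: a total-least-squares plane is fitted
  through the E2 interface atoms and the minimum signed CRBN probe
  distance to it is the *gap*; the sign is positive away from the E2 body
  centroid. Gap &lt; 10 Å with no clash is ring-forming cluster A, ≥ 10 Å is
  ring-open cluster B, negative gap or clashes is cluster C (discarded).
  The plane construction is our choice — the classification names a plane
  but not how to fit it; total least squares is the symmetric option.
* **Retention**: an assembly is kept when some surface-lysine NZ lies
  within 16 Å of ubiquitin's Gly75 backbone **O** and there is no clash.
  The boundary is inclusive (≤ 16), reading the permissive "less than or
  close to" phrasing. Note the deliberate asymmetry: retention measures to
  the Gly **O**, the competence criterion below to the Gly **C**; both
  atoms are explicit configuration fields. Which lysine nitrogen: the
  side-chain NZ, since ubiquitination chemistry targets the ε-amine, and
  the candidate-lysine list is an input (default: all lysines with NZ
  atoms).

## Ubiquitination competence

A trajectory frame is *competent* when, for at least one candidate lysine,
d(Lys NZ, Gly75 C) &lt; 10 Å and min over the Asp carboxylate oxygens of
d(Asp O, Gly75 O) &lt; 6 Å. Both inequalities are strict, as stated.
Flags over multiple candidate lysines are OR-ed — any lysine reaching the
pocket suffices. The summary statistic is the fraction of competent
frames; an optional start frame restricts the averaging window (default:
the full series, since no equilibration convention is universal).

## Circular statistics

Torsion series live on a circle, so naive means and Pearson correlations
fail at ±180°. The package uses resultant-vector circular means
(`atan2(Σ sin, Σ cos)`), shortest-arc deviations
`atan2(sin(x−x̄), cos(x−x̄))`, and Pearson correlation of those deviations;
away from the wrap this reduces exactly to linear Pearson (tested to
1e-12). The torsion itself follows the IUPAC sign convention
(`atan2((n₁×n₂)·b̂₂, n₁·n₂)`, range [−180, 180), trans ↦ −180). One
property worth stating because it is often mis-remembered: the torsion is
*invariant* under reversal of the four-point order, and negated under
mirror reflection — both are tested.

**Dihedral Gibbs entropy** is the plug-in estimate −Σ pᵢ ln pᵢ over
uniform bins of [−180, 180), reported as T·S = R·T·(−Σ pᵢ ln pᵢ) in
kcal/mol at T = 300 K (the simulation temperature this analysis is
designed for). Reporting in kcal/mol dimensionally requires the
temperature factor; since mislabelled conventions exist, the raw entropy
in nats is attached as an attribute. Defaults: 36 bins of 10°, which at
8000 samples gives ≥ 200 expected counts per bin and a stable plug-in
estimate; no small-sample bias correction is applied, matching a direct
Gibbs-formula reading. Bin count is a parameter.

**Time-lagged correlation** scans lags 0..max_lag, correlating the angle's
circular deviations at time t with the distance at t+ℓ; positive lags only
by default, encoding the causal reading that linker rotation *leads* the
lysine–glycine approach (a flag enables symmetric lags). Lags whose
overlap window has degenerate variance are recorded as `NA` and excluded
from the peak. Reported peaks convert to ns via the sampling interval.

## Force networks

Residue-pair forces sum the scalar radial nonbonded forces −dU/dr with
U = 4ε[(σ/r)¹² − (σ/r)⁶] + 332.0637·qᵢqⱼ/r, truncated at 10 Å, converted
to pN (1 kcal/(mol·Å) = 69.4786 pN); attraction is negative, following
force-distribution-analysis convention. Plain cutoff Coulomb is used —
lattice-sum electrostatics belongs to full MD engines and is out of scope
here; this is a documented fidelity limit of the toy energy model, not an
approximation of one. For trajectories the matrix is time-averaged after
discarding the first 10% of frames as equilibration (configurable), the
per-frame matrices being available for inspection. Pairs within ±10 pN
are eliminated; surviving edges carry weight 1/|force| so that
shortest paths trace the strongest mechanical coupling routes, with ties
broken lexicographically for deterministic output. The interaction-energy
split ΔE = E_complex − E_part1 − E_part2 over the same model reduces to
the inter-partition pair-energy sum, since internal terms cancel.

## Backbone PCA

Frames are aligned by Kabsch superposition onto an iteratively refined
mean reference (convergence when the mean shifts &lt; 1e-6 Å RMS), then the
covariance of the flattened selected coordinates is eigendecomposed via
SVD. The covariance uses the unbiased F−1 denominator (variance fractions
are denominator-invariant). The default atom selection is the peptide
backbone N/Cα/C without the carbonyl O — "backbone" conventions differ, so
the set is configurable. Mode signs are fixed (largest-magnitude component
positive) for reproducible output.

## What the synthetic generators emulate — and what they do not

The generators plant known ground truth so that every estimator is tested
by recovery, without any structure downloads:

* `make_toy_complex` builds bead-level chains with the reactive atoms
  explicit (Lys NZ, Gly75 C/O, Asp OD1/OD2) at exactly the requested
  distances, 12 surface lysines by default, plus CRBN/PROTAC chains.
* `simulate_coupled_series` drives circular deviations with a wrapped
  AR(1) (Ornstein–Uhlenbeck) process — correlation time 20 samples,
  stationary spread 60°/√concentration, wrapped around a random centre so
  the ±180° discontinuity is exercised — and couples the distance to the
  lagged deviation through a fixed monotone map
  (10 Å + coupling·6 Å·dev/180 + Gaussian noise, 0.5 Å default). A
  wrapped-normal step process is used rather than exact von Mises
  sampling: only the circular-wrap behaviour matters to the estimators.
  The defaults (8000 samples at 50 ps, planted lag 65 samples) mirror the
  sampling regime of 400-ns production runs recorded every 50 ps.
* `simulate_trajectory` superimposes orthonormal random displacement
  fields with integer-cycle sinusoids (exactly orthogonal in time, so
  amplitudes 2:1 give variance fractions exactly 0.8/0.2), optional
  rigid-body jitter to exercise alignment, and isotropic noise.
* `make_force_matrix` plants a strong attractive path over sub-threshold
  background (background resampled into the open (−10, 10) pN band).

None of this is physical dynamics: there is no force field integration, no
solvent, no thermostat. Passing recovery tests shows the *estimators* are
correct and the *procedure* is faithfully implemented; it does not certify
behaviour on real MD output, where sampling noise, autocorrelation
structure and anharmonicity are richer.

## Numerical choices and degenerate inputs

Superposition requires ≥ 3 non-collinear paired atoms and errors
otherwise; collinearity is detected via the second singular value. Circular
means error on a vanishing resultant (mass exactly antipodal). Entropy
defines 0·ln 0 = 0 and guards the x = 180 bin edge. PDB output enforces
the 4-digit residue and 8.3 coordinate fields; insertion codes are
rejected rather than guessed, and only the first altloc is kept. The PDB
round trip preserves coordinates to the 1e-3 Å print precision.

## Problem sizes

The test suite and the acceptance script run on deliberately modest sizes
chosen once: series of 8000 samples (the sampling regime the analysis
targets), trajectories of 200–400 frames over ~100-atom toy complexes for
PCA, 20-replicate seed sweeps for lag-recovery statistics, and
5–15-residue systems for exhaustive-oracle force comparisons. These sizes
make every independent oracle (quadruple loops, exhaustive path
enumeration, O(n²) clash scans) affordable while leaving the estimators'
statistical behaviour visible.

## Known limitations

Bead-level toys cannot probe solvent-accessibility of lysines ("surface"
status is an input, not computed); cutoff Coulomb underestimates
long-range electrostatic coupling; the plug-in entropy is biased low for
short series (warned below one sample per bin on average); and the
lag-correlation estimator assumes one dominant coupling direction — for
bidirectional coupling, enable symmetric lags and interpret both signs.
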