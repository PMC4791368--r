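---
title: "Group-level analysis of weighted brain connectomes with cohortnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level analysis of weighted brain connectomes with cohortnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortnet)
```

## What the package computes

`cohortnet` implements a complete group-level connectome analysis for a
three-group resting-state fMRI + diffusion imaging study design: patients
with auditory verbal hallucinations (AVH, n = 35), patients without
(nAVH, n = 41), and healthy controls (HC, n = 50), with 90 AAL-style
cortical/subcortical regions as network nodes. Two arms share a common
weighted-graph core:

* **Functional arm.** Per subject, an ROI x volume signal matrix (180
  volumes, TR = 2 s) is conditioned (discard first 10 volumes, framewise
  displacement and spike detection at FD > 0.5 mm, joint regression of 6
  motion parameters, their first differences, global/white-matter/CSF
  signals and spike indicators, ideal band-pass 0.01–0.08 Hz), all
  pairwise Pearson correlations and their two-tailed p-values (t
  distribution, df = n − 2) are computed, and edges are retained where
  r > 0 and p clears a significance scheme (P < 0.05 Bonferroni over
  4005 pairs by default; P < 0.001 uncorrected and P < 0.01 Bonferroni
  as sensitivity schemes). The retained correlation is the edge weight.
* **Structural arm.** Per subject, a symmetric integer fiber-count (FN)
  matrix is thresholded at ≥ 3 fibers; the count is the edge weight.

On every weighted graph the package computes the clustering coefficient
Cp (geometric-mean/Onnela weighted variant), characteristic path length
Lp, global efficiency Eg and local efficiency Eloc, plus density, mean
connectivity strength and largest-component size. Weights are
max-normalized internally (ŵ = w / max w) and shortest-path lengths are
1/ŵ, making every metric invariant to a global rescaling of the weights.
Raw metrics are scaled against the means of matched random networks —
degree-preserving double-edge-swap rewirings in which weights travel with
their edges — giving γ = Cp/⟨Cp_null⟩, λ = Lp/⟨Lp_null⟩, small-worldness
σ = γ/λ, and normalized efficiencies. Group differences are tested with
permutation one-way ANOVA (F statistic, labels permuted, add-one
p-value) and pairwise mean-difference permutation tests; metric-symptom
association uses Spearman correlation against AHRS total scores in the
AVH group.

## Numerical and procedural conventions

Several choices are conventions rather than forced by the problem; each
is fixed, documented, and covered by tests:

* **FD formula.** The scalar Power-style index: sum of absolute
  volume-to-volume translation changes plus 50 mm times the sum of
  absolute rotation changes; the first volume is defined as 0 and is
  excluded from mean-FD QC summaries. "Exceeds 0.5 mm" is a strict
  inequality.
* **Motion derivatives** are backward differences with a leading zero,
  preserving series length.
* **Band-pass** is an ideal rectangular mask on the discrete Fourier
  spectrum; the 0 Hz component is always removed. A mask makes the
  passband contract exactly testable (an in-band tone passes within 1%,
  an out-of-band tone is suppressed below 1%); it is not a rolled-off
  filter.
* **Correlation df.** p-values use nominal df = n − 2 on the
  post-discard volume count. Band-pass filtering reduces the effective
  df well below this (about 2 × bandwidth × duration ≈ 48 at the default
  band), so nominal-df thresholds are anti-conservative on filtered
  data; this matches common practice for significance-thresholded
  networks and is deliberately not "corrected" here.
* **Spike and covariate regression** are a single joint least-squares
  fit (one design matrix with 15 continuous columns plus one-hot spike
  columns); exactly collinear columns are pruned by QR pivoting with a
  warning.
* **Disconnected graphs.** Lp averages finite distances within the
  largest connected component; efficiencies use the 1/∞ = 0 convention;
  Cp averages over all 90 nodes with isolates contributing 0.
* **Null ensemble.** 10 attempted swaps per edge per null network
  (standard burn-in); swaps creating self-loops or multi-edges are
  rejected; rigid graphs (no valid swap) are returned unchanged with a
  warning. Because the weight multiset is preserved, each null graph's
  max-normalization constant equals the real graph's.
* **Permutation p-values** use the add-one convention,
  p = (1 + #{T_perm ≥ T_obs}) / (1 + n_perm), so p ∈ (0, 1] always, and
  the minimum attainable p is 1/(n_perm + 1). Post-hoc pairwise tests
  are reported at α = 0.05 without multiplicity correction, matching an
  exploratory analysis stance.
* **Degenerate statistics** (zero within-group variance, constant
  correlation inputs) are reported as flagged degenerate results, never
  silently dropped.

## The synthetic cohort generator

No subject-level imaging data are distributable, so the package includes
a first-class generator that emulates the *structure* of such a study
with controllable, named group effects — every downstream stage is
exercised on it.

**Functional signals.** Each subject's ROI x volume matrix is drawn from
a zero-mean multivariate normal with a modular correlation structure:
within-module correlation `rho_within` (group-specific), between-module
correlation derived from a shared module-factor hierarchy, and 45
homotopic pairs at `rho_homotopic`, identical across groups. Three
design features deserve explanation:

1. **Homotopic anchor pairs.** In real functional connectomes the
   strongest correlations (homotopic left-right homologue pairs) are
   largely preserved in patients. Under max-normalization this matters
   mechanically: if a group manipulation lowered the network's maximum
   weight, all its normalized weights would *rise* and path lengths
   would *shrink*, inverting the intended effect. Fixed strong homotopic
   pairs (default 0.90) pin the top of every subject's weight
   distribution so that reduced within-module coupling translates into
   genuinely longer normalized paths, as in the empirical phenomenon
   being modeled.
2. **Hierarchical between-module coupling.** ROI signals are modeled as
   loading on module factors that are themselves correlated, so a
   subject's between-module correlation scales proportionally with their
   within-module level (`rho_between` is attained exactly at the HC
   baseline `rho_within`). A patient group's single named knob — reduced
   `rho_within` — therefore weakens both local and long-range coupling
   coherently, which is what global dysconnectivity means; with a fixed,
   group-independent between-module correlation, path-based metrics are
   nearly blind to the manipulation.
3. **Subject heterogeneity.** Each subject's connectivity level is
   jittered (`rho_subject_sd`, default 0.025, identical for all groups).
   Without it the between-subject variance would be pure finite-sample
   noise and "a standardized effect of about 1 SD" would not be a
   meaningful design target.

**Defaults as study conditions.** The defaults are calibrated once, by
Monte-Carlo, so that the *least sensitive* planted functional contrast
(characteristic path length) is close to a 1 SD standardized effect:
`rho_within` 0.50 (HC) vs 0.42 (both patient groups), `rho_between`
0.20, `rho_homotopic` 0.90. Clustering and local efficiency are
mechanically more sensitive to the same knob (≈ 2–2.7 SD). The
structural arm plants its effect through `shortcut_density` — the
probability that a between-module pair carries a strong long-range
connection — 0.05 in HC/nAVH vs 0.02 in AVH, which lengthens AVH
structural paths by ≈ 1–2 SD while leaving nAVH indistinguishable from
controls. Fiber counts are negative-binomial (mean 25 within modules,
0.5 between, dispersion 3), reflecting the overdispersion of real
tract-count matrices.

**Motion and nuisance channels.** Motion traces are low-amplitude random
walks (mean FD ≈ 0.07–0.1 mm, comparable to a well-behaved cohort) with
1 mm translation steps injected at spike volumes, so FD crosses the
0.5 mm threshold exactly at the injected volumes. Spikes are
translations only, which keeps the check independent of the rotation
radius convention. Global/WM/CSF signals are fabricated smooth AR(1)
series. AHRS total scores are truncated-normal with mean 23.9 and SD
8.4, present only for AVH subjects.

**What the generator does not emulate.** No voxel-level images, scanner
artifacts, physiological noise spectra, spatial autocorrelation,
tractography geometry, or realistic hub topology. Passing tests on this
cohort demonstrate that the pipeline recovers planted effects of the
stated kind and size under clean distributional assumptions — not that
it would detect effects in any particular real dataset.

## Validation design and problem sizes

The test suite validates each stage against independent routes:

* graph metrics against exhaustive brute-force path enumeration and
  triple-loop clustering on 500 random graphs of ≤ 7 nodes (agreement to
  1e-12), plus closed-form anchors (complete graphs, stars, paths);
* every null-ensemble member against exact preservation of node count,
  edge count, degree sequence and weight multiset;
* normalization sanity: dense random 90-node graphs self-normalize to
  γ, λ ≈ 1 within 3 ensemble SDs; ring lattices with 10% shortcuts give
  γ > 1 and σ > 1 in 10/10 seeds (n_null = 200);
* permutation ANOVA type-I error on 1000 null cohorts of 35/41/50
  (n_perm = 500) inside [0.035, 0.065] at α = 0.05, with a KS uniformity
  check on the p-distribution;
* parameter recovery over 50 replicate cohorts (n_perm = 1000): the
  functional pattern — decreased Cp, Eg, Eloc and increased Lp in both
  patient groups, no AVH-nAVH difference — and the structural pattern —
  increased Lp in AVH only.

These replicate counts and ensemble sizes were chosen as the smallest
runs that make the Monte-Carlo bands tight relative to the thresholds
being checked; `scripts/acceptance.R` uses n_null = 100 and
n_perm = 2000 on the full 126-subject design for the same reason.

## Known limitations

* The exchangeable-block correlation model has no spatial embedding; a
  parcellation-aware covariance would change absolute metric levels.
* Lp's largest-component convention makes it sensitive to component
  merges in very sparse regimes; at the default design the thresholded
  networks are fully connected, so this does not bite.
* Nominal-df correlation p-values after band-pass filtering are
  anti-conservative (see above); the thresholds should be read as edge
  selection rules, not calibrated hypothesis tests.
* The permutation post-hoc tests are per-metric at α = 0.05 with no
  correction across metrics, appropriate only for exploratory use.
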