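# cohortnet

Group-level graph-theoretical analysis of weighted brain connectomes,
with a built-in synthetic-cohort generator so the entire pipeline can be
run, tested, and calibrated without access to imaging data.

## The problem

Resting-state fMRI and diffusion tractography each yield, per subject, a
90-node weighted network over an AAL-style parcellation: functional
edges are significance-thresholded positive Pearson correlations between
regional time series; structural edges are fiber counts thresholded at a
minimum of 3 streamlines. Psychiatric connectomics asks whether the
global topology of these networks — segregation, integration, small-world
organization, efficiency — differs between patient subgroups, for example
between schizophrenia patients with and without auditory verbal
hallucinations (AVH / nAVH) and healthy controls (HC).

`cohortnet` is for researchers who want that analysis as a tested,
reproducible pipeline: ROI time series and motion parameters in, metric
tables and permutation statistics out.

## The metrics

For a weighted undirected graph with max-normalized weights
ŵ = w / max(w) and shortest-path lengths d computed over edge lengths
1/ŵ:

- clustering coefficient (Onnela variant):
  C_i = [k_i (k_i − 1)]⁻¹ Σ_{j≠h} (ŵ_ij ŵ_ih ŵ_jh)^{1/3},
  Cp = mean_i C_i
- characteristic path length: Lp = mean of d_ij over ordered pairs in
  the largest connected component
- global efficiency: Eg = [N(N−1)]⁻¹ Σ_{i≠j} 1/d_ij (1/∞ = 0)
- local efficiency: Eloc = mean over nodes of Eg applied to each node's
  neighbor-induced subgraph

Each metric is scaled against the mean of 1000 matched random networks
(degree-preserving double-edge swaps, weights riding with their edges):
γ = Cp/⟨Cp_null⟩, λ = Lp/⟨Lp_null⟩, small-worldness σ = γ/λ, and
normalized efficiencies. Group inference is by permutation one-way ANOVA
(10000 permutations by default, add-one p-values) with pairwise
mean-difference permutation tests, and Spearman correlation of metrics
with symptom severity (AHRS) in the AVH group.

## Worked example

Simulate a small three-group cohort and run the functional arm
end-to-end (preprocessing, correlation networks at P < 0.05 Bonferroni,
raw + null-normalized metrics, permutation group tests):

```r
library(cohortnet)
spec <- cohort_spec(group_sizes = c(AVH = 6L, nAVH = 6L, HC = 8L), seed = 42L)
cohort <- generate_functional_cohort(spec)
cohort
#> <cohort> 20 subjects (AVH: 6, HC: 8, nAVH: 6)

cfg <- run_config(n_null = 50L, n_perm = 2000L, seed = 7L,
                  schemes = list(threshold_scheme(0.05, "bonferroni")))
res <- run_functional_arm(cohort, cfg)
res$metrics[1:3, c("subject_id", "group", "cp", "lp", "eg",
                   "gamma", "lambda", "sigma")]
#>    subject_id  group        cp       lp        eg    gamma   lambda    sigma
#> 1:    sub-001    AVH 0.3389577 5.195223 0.2333399 4.146907 1.422053 2.916142
#> 2:    sub-002    AVH 0.2990666 3.750240 0.3077226 1.688885 1.212472 1.392927
#> 3:    sub-003    AVH 0.2830631 3.918674 0.2936170 1.769883 1.196072 1.479745

res$tests[res$tests$metric %in% c("cp", "lp"),
          c("metric", "f_obs", "p_perm", "p_avh_hc", "p_navh_hc", "p_avh_navh")]
#>    metric    f_obs      p_perm    p_avh_hc   p_navh_hc p_avh_navh
#> 1:     cp 6.013349 0.009995002 0.102448776 0.006996502  0.1479260
#> 2:     lp 5.929174 0.012493753 0.002498751 0.008495752  0.8205897
```

Each row of `res$metrics` is one subject: raw clustering (`cp`), path
length (`lp`), efficiencies, and their null-normalized counterparts
(`gamma`, `lambda`, `sigma`, ...). The test table shows the permutation
ANOVA F and p for each metric plus the three pairwise post-hoc p-values —
here the generator's planted patient effect (reduced within-module
coupling in both patient groups) surfaces as significant Cp and Lp
differences against controls with no AVH-vs-nAVH difference, even in
this deliberately small cohort. `generate_structural_cohort()` and
`run_structural_arm()` provide the fiber-count arm; `write_cohort()` /
`read_cohort()` persist cohorts as TSV files with a manifest.

The default `cohort_spec()` reproduces the full study design (group
sizes 35/41/50, 90 ROIs, 180 volumes, TR = 2 s) with group effects
calibrated to a standardized ~1 SD contrast on the least sensitive
metric; see the methods vignette
(`vignettes/connectome-group-analysis.Rmd`) for the generator's design
and every numerical convention.

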