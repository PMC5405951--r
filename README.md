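# regionGSEA

Pathway-level analysis of multi-region, multi-group expression studies —
the design typical of post-mortem brain cohorts in HIV-associated
neurocognitive disease, where three brain regions (white matter, frontal
cortex, basal ganglia) are profiled across a clinical gradient of four
groups (controls; infection without impairment; impairment without
encephalitis; impairment with encephalitis). Single-gene tests are
underpowered in cells of 5–15 subjects, so the unit of inference is the
pathway.

For a two-group contrast in one region, genes are ranked by the Welch t
statistic transformed to a signed significance metric,
`m = -sign(S) * log10(p)`, and each gene set receives the weighted
Kolmogorov–Smirnov running-sum enrichment score

    ES = extremum of the running sum that gains |m_i|^w / N_R at set
         members and loses 1/(N - k) elsewhere,        ES in [-1, 1]

Significance comes from sample-label permutation with full re-ranking
(preserving inter-gene correlation under the null), normalized enrichment
scores `NES = ES / mean |same-sign null ES|`, and GSEA-style pooled-null
FDR q-values. On top of the per-contrast engine the package provides:

* per-sample pathway activity: the same running-sum score computed within
  each sample of the gene-wise z-transformed matrix;
* cross-region consensus: *common* pathways (q < 0.01 in >= 2 of 3
  regions, concordant direction) and *region-specific* pathways
  (q < 0.01 in one region, q > 0.25 in the other two), plus a
  leading-edge differential-gene table;
* probe-to-gene collapse by highest coefficient of variation, GMT input,
  RNK export, and an advisory marker check (RBFOX3/MBP) for mislabeled
  white-matter/cortex samples;
* a synthetic-study generator with within-set correlation and injected
  pathway shifts, so power and calibration are testable against a known
  ground truth;
* `run_pipeline()`, which executes the five disease transitions
  (B-A, C-A, C-B, D-B, D-C) across all three regions and writes result
  tables, consensus calls, a counts summary and a JSON manifest.

## Worked example

```r
library(regionGSEA)

# a synthetic cohort: 4 groups x 3 regions x 10 samples, 1000 genes,
# 10 pathways of 50 genes; one pathway up-shifted by 1.5 sd in group B,
# in white matter and frontal cortex only
sim <- generate_dataset(sim_config(
  n_genes = 1000, n_sets = 10, set_size = 50, n_per_cell = 10,
  injections = data.frame(set = "SET_002", group = "B",
                          region = c("WM", "FC"), delta = 1.5, direction = 1),
  seed = 42))
expr <- collapse_probes_by_cv(sim$values, sim$probe_map)

gsea_wm <- run_gsea(expr, sim$annotations, "B", "A", "WM", sim$collection,
                    n_perm = 500, seed = 1)
gsea_wm
#> GSEA: B-A in region WM (10 sets, 500 permutations, sampled null)
#>   1 set(s) at FDR q < 0.01
#>       set size    es   nes p_nominal fdr_q
#> 1 SET_002   50 0.959 2.058     0.002 0.000
#> 2 SET_006   50 0.288 0.822     0.723 0.899
#> 3 SET_007   50 0.284 0.750     0.731 0.899
#> ...
```

The injected pathway tops the list: its 50 genes concentrate at the head
of the ranked list (ES 0.96), the normalized score 2.06 exceeds every
same-sign permutation score (nominal p at the 1/501 floor) and the pooled
FDR rounds to zero. The remaining sets sit at NES < 1 with q ~ 0.9.

```r
rr <- lapply(c(WM = "WM", FC = "FC", BG = "BG"), function(r)
  run_gsea(expr, sim$annotations, "B", "A", r, sim$collection,
           n_perm = 500, seed = 1))
common_pathways(rr)
#>       set direction   NES_WM q_WM   NES_FC q_FC   NES_BG      q_BG
#> 1 SET_002         1 2.058135    0 2.022859    0 -0.92463 0.7375657

recovery_report(sim$truth, rr)
#> recovery at q < 0.01: sensitivity 1.000 (2/2), false-call rate 0.0000 (0/28)
```

The cross-region call is exactly the injected truth: significant and
concordantly up in WM and FC, null in basal ganglia — a *common* pathway
for the B-A transition. `region_specific_pathways()`,
`leading_edge_gene_table()`, `sample_activity()` and `run_pipeline()`
continue from here; `write_study()` materializes the TSV/GMT files for the
command-line front end in `inst/cli/regiongsea.R`.

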