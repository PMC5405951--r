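---
title: "Multi-region pathway enrichment: models, parameters and design choices"
author: "regionGSEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-region pathway enrichment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionGSEA)
```

## The problem

Post-mortem brain cohorts for HIV-associated neurocognitive disease are
typically profiled in several anatomical regions — white matter (WM),
frontal cortex (FC) and basal ganglia (BG) — across a clinical gradient:
uninfected controls (A), infected subjects without neurocognitive
impairment (B), infected subjects with impairment but no encephalitis (C),
and subjects with both impairment and encephalitis (D). Single-gene
differential expression is underpowered in such small cohorts (cells of
roughly 5–15 subjects), so the analysis is carried out at the pathway
level: does a curated gene set shift coherently between two clinical
groups, and is that shift shared across brain regions or confined to one?

regionGSEA implements that analysis end to end: gene ranking, the
running-sum enrichment statistic, a sample-label permutation null,
normalized scores and false-discovery rates, per-sample pathway activity,
and cross-region consensus calls — together with a synthetic-data
generator so every stage can be validated against a known ground truth.

## Gene ranking

For a contrast "X−Y" restricted to one region, each gene receives a Welch
(unequal-variance) two-sample t statistic $S$ with Welch–Satterthwaite
degrees of freedom and a two-sided p-value $p$. Genes are ranked by the
signed significance metric

$$m = -\operatorname{sign}(S)\,\log_{10} p,$$

so a gene more expressed in the first-named (test) group sits at the top
of the list with a positive metric. The Welch form is appropriate because
group variances in clinical cohorts are rarely equal; two-sided p-values
are used since the sign of $S$ already carries direction. Ranking ties are
broken by gene symbol so that every downstream quantity is reproducible.
Underflowed p-values are clamped to the smallest positive double before
the logarithm. The raw t statistic is available as an alternative ranking
metric (`metric = "t"`).

## The enrichment statistic

Walking the ranked list of $N$ genes, the running sum gains
$|m_i|^{w}/N_R$ at each member of the set ($N_R$ normalizes the in-set
weights to 1) and loses $1/(N-k)$ at each non-member, where $k$ is the
in-list set size. The enrichment score (ES) is the running-sum value of
maximal absolute deviation from zero and always lies in $[-1, 1]$. The
weight exponent $w$ defaults to 1 (the weighted statistic standard in the
field); $w = 0$ recovers the classic Kolmogorov–Smirnov form. The genes at
or before a positive peak (at or after a negative peak) form the leading
edge — the members actually driving the enrichment.

Degenerate inputs are handled deterministically: if every in-set metric is
zero the set falls back to $w = 0$ with a warning; peak ties take the
smallest index on the positive side and the largest on the negative side,
and a cross-sign tie (compared within a relative tolerance of $10^{-9}$,
since exact ties arise for rational $w=0$ step sizes) resolves positive.

## Permutation null, NES and FDR

Significance comes from phenotype permutation: the group labels of the
contrast's samples are shuffled (group sizes preserved), the entire gene
ranking is recomputed, and every set is rescored against the permuted
ranking. Because the whole ranking is rebuilt per shuffle, inter-gene
correlation within sets is preserved under the null — the property that
makes set-level p-values honest where a gene-permutation null would be
anticonservative. The same shuffled labelings are used for all sets. When
the contrast admits fewer distinct labelings than requested
(\(\binom{n}{n_\text{test}} \le\) `n_perm`), all distinct assignments are
enumerated instead, including the identity.

The normalized enrichment score divides the observed ES by the mean
absolute same-sign null ES of the same set; the nominal p-value is the
same-sign null tail fraction, floored at $1/(n_\text{perm}+1)$ so a finite
null never reports zero. FDR q-values follow the pooled-null construction:
for NES\(^* \ge 0\),

$$q = \frac{\#\{\text{pooled null NES} \ge \text{NES}^*\}/\#\{\text{null NES} \ge 0\}}
           {\#\{\text{observed NES} \ge \text{NES}^*\}/\#\{\text{observed NES} \ge 0\}},$$

mirrored for negative scores and clipped to $[0,1]$, with monotonicity
within each sign enforced by a cumulative minimum taken from the least
extreme set toward the most extreme (the step-up direction used by
standard FDR procedures, which guarantees q never increases as |NES|
grows). A consequence worth knowing: with very few truly shifted sets the
observed-tail denominator is small and q saturates well above the nominal
p-value — a single perfect enrichment among 40 sets on a 10 vs 10 design
rarely reaches q < 0.01. Real disease signatures involve many pathways per
transition, which is the regime the pooled FDR is designed for.

## Per-sample pathway activity

The expression matrix is first z-transformed gene-wise (mean 0, sample sd
1 across samples), then within each sample genes are ranked by their
z-value and each set receives the same running-sum score with $|z|^w$
weights. The resulting activity value in $[-1,1]$ measures how high the
set's genes sit in that sample relative to all other samples, and is the
quantity summarized per group x region for trajectory-style displays.
Whether weighted or unweighted increments are used here is genuinely open;
the package defaults to $w = 1$ for consistency with the enrichment
engine, and the exponent is a parameter. Constant genes are dropped (with
a warning) before z-transformation; within-sample ties are broken by gene
symbol.

## Cross-region consensus

A contrast analyzed in the three regions yields three result tables over
the same collection. A pathway is called **common** when q < 0.01 in at
least two regions with (by default) a concordant NES sign in the
qualifying regions; it is **region-specific** when q < 0.01 in exactly one
region and q > 0.25 in the other two. Both inequalities are strict, so a
q sitting exactly on a threshold never qualifies; the two categories are
mutually exclusive by construction whenever the "in" threshold does not
exceed the "out" threshold. The concordance requirement is interpretive —
a discordant pathway is significant twice but not "the same event" — and
can be disabled. The leading-edge gene table takes the union of
leading-edge genes of the called pathways across their qualifying regions
and retains the genes with Welch p < 0.01 in at least one region in which
one of their source pathways qualified.

## Probe collapse and input QC

Array data carry several probes per gene; the pipeline retains, per gene,
the probe with the highest coefficient of variation (sample sd divided by
mean) across all samples, computed on the normalized log-scale values as
given. CV ties retain the lexicographically smallest probe id. A probe
with near-zero mean (|mean| < 1e-12) but positive sd has undefined CV and
can only win when no finite-CV probe exists, with a warning. As an
advisory check on sample identity, white-matter and cortical samples can
be screened against a neuronal marker (RBFOX3) and an oligodendrocyte
marker (MBP): a WM sample whose z-scored neuronal marker exceeds its
myelin marker by more than 1 z-unit (or the FC mirror image) is flagged,
never dropped — exclusion remains the analyst's decision, because no
principled universal threshold exists for this check.

## The synthetic-data generator

`generate_dataset()` emulates the study design: 4 groups x 3 regions with
8 samples per cell by default, log-scale Gaussian expression
(baseline 7.0, noise sd 1.0), disjoint gene sets, and within-set
correlation induced by a per-set shared factor,

$$x_{gs} = \mu + \sigma\left(\sqrt{\rho}\,L_{\text{set}(g),s}
            + \sqrt{1-\rho}\,\varepsilon_{gs}\right),$$

with injected dysregulations added as mean shifts of `delta` noise-sd
units to all genes of a chosen set in a chosen group x region cell. Probes
replicate their gene plus probe noise (sd 0.2); with several probes per
gene, one random probe per gene receives inflated noise so that CV
collapse has a meaningful choice. The shared-factor correlation is the
feature that makes the phenotype-permutation null worth its cost — under
an independence generator a gene-permutation null would look equally
calibrated — and its default, $\rho = 0.1$, reflects typical mean pairwise
co-expression within curated pathway sets and is the operating point at
which the package's headline recovery property (sensitivity $\ge 0.9$ for
1.5-sd shifts in 50-gene sets at 10 vs 10, 500 permutations) holds.
Correlation strength matters greatly: at $\rho = 0.2$ the same scenario
drops to roughly 60% sensitivity, purely because the shared factor adds
coherent set-level noise to the observed contrast.

What the generator does **not** emulate: probe-level intensity artifacts,
batch effects, missing values, dispersion (variance) changes, overlapping
pathways, and heavy-tailed expression noise. Passing recovery tests on
this generator therefore demonstrates the correctness and calibration of
the statistical machinery, not robustness to every artifact of real array
data.

## Numerical and reproducibility choices

* All randomness flows from explicit integer seeds; the internal helper
  restores the caller's RNG state. Pipeline stages derive child seeds as
  `(seed * 31 + index * 1009) mod (2^31 - 1)` over the contrast x region
  grid, so any single stage can be reproduced in isolation.
* Permutation ES values for the null are computed by a closed-form scan of
  hit positions (extremes of the running sum can only occur at hits,
  immediately before hits, or at the list end), which is algebraically
  identical to the full running sum and is tested for exact agreement
  against it and against an independent brute-force oracle.
* Default problem sizes in the test-suite simulations (2000 genes, 20–100
  sets, 500 permutations, 5–20 replicates) were chosen as the smallest
  designs at which the calibration and power properties are stable and
  statistically meaningful.
* The default gene-set size floor is 10 measured genes, counted after
  intersection with the expression universe, since the statistic only ever
  sees measured genes. No upper size cap is applied by default.

## Known limitations

* FDR q-values inherit the granularity of the permutation count and of the
  observed-tail denominator; q < 0.01 calls on designs with fewer than ~10
  samples per group are conservative (see above).
* Gene identity is exact, case-sensitive symbol match; alias resolution
  must happen upstream.
* The per-sample activity score is relative to the sample cohort in the
  matrix — it is not comparable across independently z-transformed
  datasets.
* Raw array processing (normalization, array-level QC) is out of scope;
  the pipeline expects an already-normalized log-scale matrix.
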