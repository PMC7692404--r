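---
title: "Individual-level pathway scores: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-level pathway scores: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipscore)
```

## The score

Most pathway-level summaries (ssGSEA, GSVA and relatives) aggregate the
*expression levels* of a gene set per sample. `ipscore` instead quantifies how
much a single sample perturbs the *co-expression structure* of a pathway
relative to a reference panel of normal samples. For an edge $(x, y)$ — a
curated gene–gene interaction inside a pathway — let $\mathrm{PCC}_n$ be the
Pearson correlation of the two genes across the $n$ normal samples, and
$\mathrm{PCC}_{n+1}$ the correlation after appending the one sample under
study. The edge-level perturbation is

$$\Delta \mathrm{PCC} = \mathrm{PCC}_{n+1} - \mathrm{PCC}_n,$$

and the individual-level pathway score of a sample on a pathway with $m$
retained edges is the mean absolute perturbation

$$\mathrm{iPS} = \frac{1}{m} \sum_{i=1}^{m} \left| \mathrm{PCC}_{n+1}^{(i)} -
\mathrm{PCC}_n^{(i)} \right| \in [0, 2].$$

A single added sample can move a correlation by at most $O(1/n)$, so iPS
values are small numbers whose scale depends on the reference size; they are
only comparable within one cohort scored against one reference.

Per pathway, the mean $\mu_p$ and sample (n−1 denominator) standard deviation
$\sigma_p$ of the *normal* samples' iPS define the null. A tumor sample is
**perturbed-strong** on the pathway when its iPS lies strictly more than
$k\sigma_p$ (default $k = 2$) from $\mu_p$, otherwise **perturbed-weak**.
Prognosis-related pathways are then screened in two steps among tumor
samples: a two-sided Wilcoxon rank-sum test of iPS between the strong and
weak groups with Benjamini–Hochberg FDR < 0.05, followed by a Kaplan–Meier
log-rank test (p < 0.005, strict) requiring that the strong group has the
*worse* prognosis.

## Assumptions

* The normal panel is homogeneous enough that a single correlation per edge
  is a meaningful baseline; at least 3 normals are required and a warning is
  issued below 20, where the baseline loses representativeness.
* Expression is already normalized; the package performs no normalization
  and refuses matrices with missing cells (imputation would silently change
  correlations).
* Edges whose reference variance is zero in either gene are excluded
  *globally* — for every sample — so each pathway's score always averages
  the same edge set and iPS values stay comparable across samples.

## Tunable parameters

| parameter | default | where | meaning |
|---|---|---|---|
| `zero_fraction_threshold` | 0.75 | `filter_genes` | drop genes that are exactly zero in strictly more than this fraction of all samples (normal + tumor jointly) |
| `min_edges` | 3 | `ips_matrix` | pathways with fewer defined edges are carried as explicitly unscored, never silently dropped |
| `scoring_mode` | `leave_one_out` | `ips_matrix` | how normal samples are scored (below) |
| `k` | 2 | `classify` | strong-call threshold in null standard deviations |
| `rule` | `two_sided` | `classify` | distance from the null mean; `one_sided` flags only upward deviations |
| `min_group` | 10 | `differential_pathways`, `survival_screen` | minimum tumor samples per arm for a pathway to be tested |
| `fdr_threshold` | 0.05 | `survival_screen` | BH FDR gate into the survival stage |
| `logrank_threshold` | 0.005 | `survival_screen` | strict log-rank significance cutoff |

## Design choices where the design was open

**Scoring the normal samples.** The null statistics $\mu_p, \sigma_p$ come
from the normal samples' own iPS values, but a normal sample that is part of
the reference it is scored against contributes almost nothing to its own
$\Delta\mathrm{PCC}$, deflating the null spread and making the $2\sigma$ rule
anti-conservative. The default `leave_one_out` mode therefore scores each
normal against the reference rebuilt without it, via an O(1) downdate of the
per-edge sufficient statistics (exact to ≤ 1e−10 against a from-scratch
rebuild, which the tests verify). The self-inclusive `pooled` mode is kept
behind a flag and recorded in the output metadata, since either convention is
defensible and the choice is material for small normal panels.

**Direction of "worse prognosis".** Median survival is undefined when a
group's Kaplan–Meier curve never crosses 0.5, so the strong-vs-weak direction
is decided by the restricted mean survival time (area under the KM curve) up
to the largest observed time across both arms; the strong arm must be lower
for a pathway to be flagged.

**The Wilcoxon stage.** The screen compares the iPS values of strong versus
weak samples — groups that were themselves defined by thresholding iPS — so
this stage is close to tautological and nearly always significant when both
arms are populated. It is implemented literally for pipeline fidelity, and
`survival_screen(differential = NULL)` (or `--skip-wilcoxon` on the command
line) bypasses it.

**Boundary ties.** "Strictly more than $k\sigma$" is enforced with a
relative guard of 1e−9 so that decimal ties (e.g. a deviation of exactly
$2 \times 0.02$) resolve to weak despite binary floating-point rounding.

**Degenerate edges.** If the augmented sample set has zero variance in
either gene, $\mathrm{PCC}_{n+1}$ is taken as $\mathrm{PCC}_n$
($\Delta\mathrm{PCC} = 0$): the added sample carries no correlation
evidence. The same rule applies when a leave-one-out reference loses an
edge's variance. Arithmetic is plain double precision without compensated
summation; with reference panels of at most a few hundred samples,
cancellation in the sufficient-statistic form stays far below the 1e−10
oracle tolerance enforced by the tests.

## What the synthetic cohorts emulate

`simulate_cohort()` generates the complete input set — expression, edge
list, clinical table — with known ground truth. Each pathway is a disjoint
block of genes whose latent Gaussian values share a common factor, giving
block-constant correlation $\rho$ among normal samples; a configurable
fraction of tumor samples *carry* a planted perturbation on designated
pathways, either `decorrelate` (the factor is removed, correlation 0) or
`sign_flip` (half the block's factor loadings are negated, so cross-loading
pairs flip to $-\rho$; a uniformly $-\rho$ block is not a valid correlation
matrix for more than two genes, which is why the flip acts through the
loadings). Survival times are exponential, with the hazard multiplied by
`hazard_ratio_strong` for carriers on a survival pathway, and censoring is
applied independently at the configured expected fraction. Carrier sets are
drawn independently per perturbed pathway so a planted survival effect is
attributable to its own pathway.

Defaults define the standard planted cohort used throughout the tests:
100 normals, 200 tumors, 10 pathways of 40 genes (≈ 780 edges per pathway,
the edge density of curated pathway exports, which run to hundreds of edges
per pathway), $\rho = 0.8$, two perturbed pathways with half the tumors as
carriers, hazard ratio 3 on one of them, baseline hazard 1/365 per day and
20% censoring. Nonnegativity comes from exponentiating the latent field
(log-normal expression, matching the right skew of normalized RNA-seq); the
latent scale `sigma_log = 0.15` is deliberately small so that the Pearson
correlation realized on the emitted scale stays close to the nominal $\rho$
(at a scale of 0.3 it already drifts to ≈ 0.76). The truth table reports the
realized, not latent, correlation.

What the generator does **not** emulate: batch structure, subtype mixtures,
overlapping pathways (an overlap would make truth attribution ambiguous),
dropout/zero inflation, and real pathway topologies (blocks are complete
graphs). Passing the planted-recovery tests therefore demonstrates that the
pipeline detects genuine correlation perturbation at realistic signal
strength — not that it is robust to every artefact of real cohorts.

A caveat the simulations make visible: under an equicorrelated block the
null iPS distribution inherits a strongly right-skewed component (it is
driven by the squared factor score of each sample, essentially a
$\chi^2_1$), so $\hat\sigma_p$ estimated from a modest normal panel is
volatile — a single extreme normal sample can inflate the threshold and
suppress recall on that pathway. This is a property of the 2-SD rule on
skewed nulls, not of the implementation, and it is why cohorts with few
normals deserve the warning they get.

## Problem sizes used by the test suite

Unit tests run on cohorts of 3–8 pathways with 25–50 samples; the
calibration checks use a perturbation-free cohort of 100 pathways
(50 normals, 100 tumors) and the recovery checks the standard planted cohort
above; the correlation oracle sweeps 1,000 randomized edges with reference
sizes up to 50. The complete suite and the acceptance script each finish in
well under a minute on a single core.

## Known limitations

* iPS is unsigned; a decorrelation and a sign flip of equal magnitude are
  indistinguishable. Perturbation direction is deliberately out of scope.
* No multiple-testing correction is applied at the classification stage,
  and the survival stage uses a fixed 0.005 cutoff rather than an FDR.
* Scores are not comparable across cohorts with different reference sizes.
* Single-pathway survival screening only; no Cox modelling or multi-pathway
  joint predictors.
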