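---
title: "Computational Ras dependency scoring: models, parameters and design"
author: "rdikit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational Ras dependency scoring: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Experimentally measured Ras dependency indices (RDIs) — readouts of how
strongly a cancer cell line depends on oncogenic Ras signaling — exist only
for small panels of cell lines. Because Ras dependency leaves a coordinated
transcriptional footprint (most prominently an epithelial-vs-mesenchymal,
EMT-like, signature), a per-sample enrichment score of a dependency
signature against a sample's expression profile can serve as a
*computational* RDI, extensible to any profiled cell line or tumor.
`rdikit` implements that idea end to end: per-sample signature scoring,
standardisation and comparison against measured RDI tables, selection of
dependency extremes, differential expression between the extremes,
Fisher-exact pathway-pattern (PPEP) matrices, pairwise signature-overlap
tests, and association of the score with censored survival. A synthetic
cohort generator with planted ground truth makes every stage testable
without access to large public compendia.

# Per-sample enrichment score (ssGSEA)

For one sample, genes are ranked by expression; the highest-expressed of
the $N$ measured genes receives rank $N$. Ties are broken deterministically
by gene identifier, so scores are identical across runs and platforms.
Walking the ordering from highest to lowest, with $G$ the signature
($m = |G \cap \text{universe}|$ measured members) and $r_j$ the rank of the
gene at walk position $j$:

$$
P_{in}(i) = \frac{\sum_{j \le i,\; g_j \in G} r_j^{\alpha}}
                 {\sum_{g_j \in G} r_j^{\alpha}},
\qquad
P_{out}(i) = \frac{\#\{j \le i : g_j \notin G\}}{N - m},
\qquad
ES = \sum_{i=1}^{N}\left[P_{in}(i) - P_{out}(i)\right].
$$

$ES > 0$ means the signature is coordinately up-regulated in that sample.
Because only within-sample ranks enter, any strictly increasing per-sample
transform of the expression values (log, quantile normalisation, ...)
leaves scores unchanged; the test suite asserts this as a property.

Parameters (`ssgseaParams()`):

* `alpha` (default **0.25**): the rank-weighting exponent. The scoring
  literature this follows uses 0.25 by default; the choice is immaterial
  for singleton sets (the weight cancels) and mild for small sets. It is
  exposed, not inferred.
* `normalize` (default **"range"**): divide the entire score matrix by
  (max − min). This is cosmetic fidelity to common practice; downstream
  comparisons always z-score per signature row, which removes any global
  scale, so the choice cannot affect correlations, extreme selection, or
  anything derived from them.
* `min_set_size` (default **1**): signatures with fewer measured genes are
  skipped with a warning, as is a signature covering the whole universe
  (the out-of-set ECDF would be undefined). Signature genes absent from
  the matrix are silently dropped ($m$ counts only measured genes).
* An all-constant sample has no ranking and is an error naming the sample.

## Directional signatures

Published dependency signatures often come as up- and down-regulated
halves. `scoreDirectional()` scores both halves and combines them per
sample as $z(ES_{up}) - z(ES_{dn})$ (row z-scores, sample SD), keeping the
separate halves alongside. With no down half the combined score degenerates
to $z(ES_{up})$. The pipeline (`runPipeline()`) adds such a combined row
automatically for every `_Up`/`_Dn` pair in the signature GMT and uses the
first combined row for extreme selection by default. This matters for the
synthetic cohorts: the generator plants half the signature genes pointing
down by default, and an undirected score of a half-up/half-down set cancels
by construction — the directional combination is the scoring route that
recovers the planted gradient.

# Standardisation and RDI comparison

Scores and measured RDI values are compared after z-scoring (mean 0,
sample SD, i.e. denominator $n-1$; population vs sample SD cannot change
rankings or correlations, so the conventional sample SD is used). The
cohort whose mean/SD define the standardisation is an explicit argument,
so a score can be standardised across all samples or across a named
subset.

Measured dependency tables are mapped onto the dependency scale by
$t = s \cdot \log_{10}(\text{raw})$ with $s = -1$ for dependent and $+1$
for independent lines, then z-scored: larger $t$ always means stronger
dependency. Raw values must be strictly positive.

`correlationMatrix()` correlates any set of named per-sample vectors
pairwise on their shared samples (Pearson default; Spearman available for
rank-level claims), excluding missing data pairwise and recording the
shared-sample count; pairs with fewer than 3 shared samples become missing
entries with a warning.

# Dependency extremes and differential expression

`selectExtremes()` takes the $k$ highest- and $k$ lowest-scoring samples
(default pipeline $k = 15$, the conventional top-15/bottom-15 contrast;
top-30/bottom-30 is a robustness variant). Boundary ties are broken by
sample id, lexicographically smaller first, and the groups are guaranteed
disjoint; a grouped variant selects within tissue groups and adds the
pooled high-vs-low contrast.

The built-in differential expression test is deliberately plain: a
per-gene Welch two-sample t-test on intensity values as given (assumed
log-scale), or on $\log_2(\text{CPM} + 0.5)$ for counts (pseudo-count 0.5
avoids $\log 0$), Benjamini–Hochberg adjustment over tested genes, and
filtering at adjusted $p \le 0.05$ and linear fold change $\ge 1.5$
(i.e. $|\log_2 FC| \ge \log_2 1.5$, matching the `FC1_5` naming
convention). Genes with zero variance in both groups are excluded and
logged. This stand-in is not a replication of limma/DESeq2/edgeR — those
moderated models are out of scope by design; `importDegList()` lets lists
computed by any such tool flow into the downstream pathway analysis, which
keeps the pipeline method-agnostic.

# PPEP: the pathway × contrast pattern matrix

Each DEG list is tested against each pathway with a one-sided Fisher exact
test (over-representation) on the 2×2 table (hit, list-only, pathway-only,
neither) whose background is the measured gene universe of the source
expression matrix — the same background convention used for the pairwise
signature-overlap table. Cells are reported as $-\log_{10}(p)$, **zeroed
whenever $p \ge 0.05$ or fewer than 2 hit genes support the cell**; every
surviving entry therefore exceeds $-\log_{10}(0.05) \approx 1.30103$. No
multiple-testing correction enters the zeroing rule — the method is a raw
$p < 0.05$ screen plus a hit-count floor; a BH column is emitted in the
long-format output for inspection only. Zeros are kept explicit so heatmap
rows align across contrasts. `extractPathwayDegs()` recovers the hit genes
of a pathway with their directions for gene-level views.

# Survival association: Cox plus a cutpoint scan

`coxUnivariate()` fits a univariate Cox proportional-hazards model of
survival on the continuous score (Breslow tie handling, tight convergence
control) and reports the Wald p-value. `gradientScan()` reconstructs a
gradient-scan statistic: across the splits induced by the distinct score
values inside a quantile window (default [0.1, 0.9]) that leave both
groups at least a fraction `min_frac` (default 0.1) of the cohort, a
two-group log-rank test is run; `good_count` is the number of cuts with
$p < \alpha$ (default 0.05), calibrated by `B` score permutations
(default 200; fewer than 100 warns) with the add-one-smoothed permutation
p-value $(1 + \#\{good_b \ge good\})/(B+1) \in [1/(B+1), 1]$, bit-
reproducible under a fixed seed.

Numerical choices worth knowing:

* Cuts are placed at **midpoints between adjacent distinct score values**.
  The induced partitions are identical to cutting at the values
  themselves, but no sample ever sits on a cut, which makes the scan
  exactly invariant under score negation — cutting at observed values
  breaks that symmetry because the boundary sample switches sides.
* The log-rank statistic is computed from precomputed risk-set cumulative
  sums so that thousands of (cut × permutation) evaluations stay cheap; it
  is verified in the test suite against both an $O(n^2)$ risk-set
  enumeration oracle and an independent reference implementation,
  including tied event times.
* The scan settings (window, floor, $\alpha$, `B`) are not canonical —
  the module is a documented simplified reconstruction, not a replication
  of the original gradient-scan method — and all settings are recorded in
  the output object.

# The synthetic cohort generator

`makeExpression()` emulates the minimal structure the analysis assumes: a
latent per-sample dependency gradient $d_i \sim U(-1, 1)$ (uniform, not
bimodal, so the dependency *continuum* is exercised), per-gene baselines
$\mu_g \sim N(7, 1)$ on the log2 scale, and signature genes shifted by
$\beta\, dir_g\, d_i$ against residual noise $N(0, \sigma)$. Defaults —
2000 genes × 60 samples, a 50-gene signature with half its genes pointing
down, $\beta = 1$, $\sigma = 0.5$ — are the reference conditions used
throughout the tests: an effect of one log2 unit per unit gradient against
noise SD 0.5 is a strong but realistic coordinated signature, and 60
samples is a typical panel size for a single tissue. A planted pathway
(disjoint from the signature) adds $(s/2)\,d_i$ to its genes, i.e. a log2
shift of $s$ between the gradient endpoints; between top-15 and bottom-15
extremes of a 60-sample cohort the realised contrast is about
$0.75\,s$. Count matrices draw Negative Binomial counts (dispersion 0.1)
from the same log2 surface with expected library size $10^6$.

`makeRdi()` emulates a measured dependency readout:
$\text{raw} = 10^{-\ell_i (d_i + \varepsilon)}$ with
$\ell_i = +1$/"dependent" when $d_i > 0$ and $\ell_i = -1$/"independent"
otherwise, $\varepsilon \sim N(0, \text{noise\_sd})$. The sign-by-label
construction is what makes the log10/sign transform recover $d_i +
\varepsilon$ exactly for every sample (Spearman 1 at zero noise) — the
measured value shrinks with dependency strength for dependent lines and
grows with independency strength for independent lines.

`makeSurvival()` draws exponential event times with hazard
$h_0 \exp(\log(HR)\, d_i / SD(d))$ and independent Uniform$(0, c)$
censoring, with $c$ solved numerically (closed-form expected censoring
fraction per sample, root-finding on the mean) to hit the requested
censoring fraction in expectation.

What the generator deliberately does **not** emulate: batch effects,
tissue hierarchies and tissue-specific baselines, correlated gene modules
outside the planted structure, mutation/copy-number covariates, and the
heavy-tailed or bimodal marginals of real compendia. Passing tests on
these cohorts therefore demonstrate that the machinery recovers the
structure it assumes — not that real CCLE/TCGA data satisfy those
assumptions.

# Test and calibration conditions

The suite runs at deliberately modest problem sizes: exhaustive ssGSEA
oracle checks on universes up to 10 genes, exhaustive hypergeometric
checks on backgrounds up to 60 genes, 2000 × 60 cohorts for recovery, 50
replicate seeds for null calibrations, 20 seeds for end-to-end pathway
recovery, and 200/100 replicates for Cox type-I/power — sizes at which
every property is decisive while the full suite runs in a couple of
minutes. One calibration is intrinsically knife-edge and worth
understanding: under a global null, the probability that BH produces *any*
discovery is exactly the nominal level (Simes' identity), so "zero DEGs in
at least 95% of null replicates" sits exactly at the expected rate and a
given seed sequence can legitimately land on either side of it.

# Known limitations

* The ssGSEA variant is one fixed member of the family (rank weights,
  exponent default 0.25, range normalisation); other published variants
  weight by raw expression or normalise per signature.
* The built-in DEG test ignores variance moderation and covariates; use
  the importer for serious analyses.
* PPEP reports raw-p screened cells by design; treat the matrix as a
  pattern-discovery view, not as FDR-controlled inference.
* The survival scan is a reconstruction with explicit, non-canonical
  defaults; `good_count` and the permutation p answer slightly different
  questions and both are reported.
* Gene matching is exact string match after upper-casing; alias resolution
  is out of scope.
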