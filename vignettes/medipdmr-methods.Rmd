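---
title: "Methods: window-based differential methylation and biomarker validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based differential methylation and biomarker validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

## The problem

MeDIP-seq (methylated DNA immunoprecipitation sequencing) proxies DNA
methylation by read depth: methylated fragments are pulled down by an
antibody and sequenced, so regions with altered methylation show altered
coverage. Because the antibody works best where CpG dinucleotides are
sparse, the assay interrogates the >90% of the genome with low CpG
density ("CpG deserts") that array platforms miss. `medipdmr` implements
the canonical window-based analysis of such data for a two-group design —
here sperm samples from 13 case and 13 control donors — and the validation
battery used to assess whether the resulting differential DNA methylation
regions (DMRs) carry a usable biomarker signal.

## The statistical model

The genome is tiled into non-overlapping 1-kb windows (0-based, half-open;
a trailing partial window per chromosome is kept with its true length).
Read counts per window and sample are modeled as negative binomial (NB):

$$Y_{wj} \sim \mathrm{NB}(\mu_{wj}, \phi), \qquad
  \mathrm{Var}(Y_{wj}) = \mu_{wj} + \phi\,\mu_{wj}^2,$$

with a single common dispersion $\phi$ shared by all windows. Counts are
first scaled to the geometric-mean library size $N^* = \exp(\overline{\log
N_j})$ with half-up rounding, which makes the equal-mean assumption of the
conditional test hold approximately. This deterministic equalization is a
documented stand-in for edgeR's quantile adjustment; the whole testing
stage re-implements the classic common-dispersion exact-test path — not
TMM normalization, not tagwise empirical-Bayes shrinkage — because it is
the simplest fully documented member of that family. Results on real data
may therefore differ in detail from pipelines that use the full edgeR
stack.

$\phi$ is estimated by maximizing the conditional log-likelihood of each
group's counts given their sum (the quantity in which the NB mean
cancels), summed over both groups and all windows passing the low-count
filter (mean adjusted count $\ge 1$), by golden-section search on
$\log\phi \in [10^{-6}, 10]$ at tolerance $10^{-6}$. A boundary optimum is
reported with a warning rather than an error, since Poisson-like data
legitimately push $\phi$ to the lower bound.

Per window, the group sums $S_1 \sim \mathrm{NB}(n_1 r, \pi)$ and $S_2 \sim
\mathrm{NB}(n_2 r, \pi)$ (with $r = 1/\phi$) are compared conditionally on
$s = s_1 + s_2$: the two-sided p-value sums the probabilities of all
splits no more probable than the observed one, with a $1 + 10^{-12}$
relative tolerance for floating-point ties. This "doubling-free"
convention is exactly checkable by enumeration, which the test suite does
for every total $s \le 60$. The log2 fold change uses a prior count of
0.125 per group mean, signed so that positive values mean increased
methylation in cases. Benjamini–Hochberg adjustment runs over all tested
windows; filtered windows keep the sentinel $p = q = 1$ and a `low_count`
flag rather than disappearing.

## DMR calling and characterization

Windows with $p$ below the working threshold ($10^{-5}$ by default) are
merged into DMRs when adjacent on the same chromosome; boundaries are the
union of member windows with no flank extension, which is what makes the
modal DMR length exactly 1 kb. Merging uses the raw p-value, with the
$q < 0.05$ property checked afterwards per DMR, because FDR control is
reported as a consequence of the working threshold rather than used as the
merge criterion. `maxLFC` is taken from the minimum-p member window (ties
broken toward the larger $|$lfc$|$) — the aggregation is otherwise
undefined in the field's table legends. CpG density bins clamp
`round(100 * CpG / length)` into 1..10, with densities below 0.5 assigned
to bin 1 since the density histogram has no zero bin.

One subtlety of the threshold table: the number of *significant windows*
is monotone non-increasing as the p-threshold tightens, but the number of
*DMRs* is not a mathematical invariant — tightening can split a
multi-window run whose interior window loses significance into two
regions, increasing the count by one. On realistic data (mostly
single-window DMRs) the counts decrease in practice, which is what the
published threshold figures show.

Gene association is strand-aware: a DMR overlapping a gene is `overlap`;
one upstream of the TSS is binned by its 1-based end-to-TSS gap into
`proximal_1k` (1–1000 bp), `proximal_5k` (1001–5000) or `distal_10k`
(5001–10000); other neighbours within 10 kb are `downstream_10k`; DMRs
with nothing in range are `intergenic`. The proprietary pathway analysis
of the original workflow is replaced by a generic hypergeometric
overlap test (`gene_set_overlap`) against a user-declared gene universe.

## Validation battery

* **Permutation null** (`permutation_test`): group labels are shuffled
  uniformly among the 26 labeled samples (preserving 13/13), the whole
  test + DMR-calling pipeline reruns, and the observed DMR count is
  compared with the permutation distribution. The empirical p-value uses
  the add-one rule $(1 + \#\{\text{perm} \ge \text{obs}\})/(n+1)$, so it
  is never zero; a permutation identical to the original labeling is
  allowed and counted. "Random subset analysis" is operationalized as
  balanced label permutation — the alternative (random window subsets)
  does not produce a per-comparison DMR count, which is what the null
  distribution is over.
* **Leave-one-out cross-validation** (`cross_validate`): each fold
  re-derives DMRs from the 25 remaining samples only, so the held-out
  sample can never influence DMR selection (the suite verifies this by
  corrupting a held-out sample's counts and checking the fold's DMR count
  is unchanged). When a fold yields fewer than 2 DMRs — possible only for
  weak signal — the two smallest-p windows stand in so the fold can still
  be scored; with no signal this makes the classifier guess, which is the
  behavior a chance-level check needs.
* **PCA nearest-centroid classification** (`pca_fit`, `classify_samples`,
  `blinded_workflow`): DMR-level RPKM (counts summed over member windows,
  true union length, per-million library scaling) is centered per DMR
  (no variance scaling), projected onto the first two principal
  components, and a blinded sample is assigned to the nearer group
  centroid, with an exact tie mapped to `unclassified`. The original
  study never states its blinded-assignment rule; nearest-centroid in the
  two-component space of DMR RPKM is the minimal rule consistent with the
  published PCA figure, and is this package's largest interpretive
  decision.
* **Batch-outlier DMR removal** (`remove_outlier_dmrs`): before blinded
  classification, a DMR is dropped when some blinded sample's RPKM falls
  outside the training mean ± 3 SD band of *both* groups simultaneously —
  a value consistent with neither group indicates a batch artifact, not a
  group difference. The ±3 SD operationalization of an undefined step is
  configurable (`outlier_sd`).

## The synthetic world

The generator (`sim_config`, `simulate_dataset`) emulates the 13-vs-13
MeDIP-seq design so every stage is testable without sequencing data. The
study-design statements it encodes: 1-kb windows; 13 case and 13 control
samples; a minority of truly differential regions, mostly single-window,
with 62% decreasing in cases; and low-CpG sequence context (2 CpG per
100 bp). Where no value is stated, defaults were chosen once as
desk-scale-realistic and are not revisited: expected depth 30
reads/window (enough power at the default 2.5-fold effect for recovery
tests to be meaningful on one CPU), NB dispersion 0.1, lognormal
library-size factors with CV 0.2 (strictly positive, realistically
skewed), and a lognormal per-window baseline with CV 0.5. The baseline CV
is the one generator parameter beyond the specification's list: the count
model names a per-window baseline $b(w)$, and a flat baseline would make
the low-count filter and the mean-dependence of the data degenerate.

The generator is NB because NB is what the test assumes — recovery tests
are then well-posed. What a green test does **not** establish: real MeDIP
data have fragment-level pulldown chemistry, CpG-density-dependent
enrichment, mappability structure, duplicate reads and batch effects, none
of which are simulated; planted effects are clean multiplicative shifts.
Synthetic results validate the machinery, not the biology. Planted DMRs
are kept mutually non-adjacent so that after merging, ground truth equals
the planted count, and read simulation places uniform midpoints within
windows (sequence content does not influence counts). The per-window
baseline $b(w)$ is a property of the windows, not of a batch: when blinded
batches are simulated (`simulate_dataset`, or `simulate_counts` with its
`baseline` argument), they share the training batch's baseline — redrawing
it would inject a genome-wide batch effect far larger than any the
outlier-removal step is meant to absorb.

## Numerical choices and degenerate inputs

* Reads are assigned to the unique window containing their midpoint
  `floor((start+stop)/2)` — no overlap-fraction splitting — which avoids
  double counting and makes `count_reads(simulate_reads(M)) == M` exact.
* Half-up rounding (`floor(x + 0.5)`) is used both for library-size
  equalization and for presenting clinical means/SDs as integers.
* Exact-test ties use a `1 + 1e-12` relative probability tolerance.
* `s1 = s2 = 0` gives $p = 1$ (the only outcome has probability 1); an
  all-zero window is flagged `low_count` rather than dropped.
* Determinism: every simulation operation derives an independent stream
  from the single config seed, so identical configs give byte-identical
  output; permutation and read simulation take explicit seeds.
* The clinical 2-SD exclusion pass is single-pass (not iterated) and by
  default applied within the control group only: the one re-analysis it
  mirrors excluded a single control donor while leaving a case value that
  also exceeds its own group's 2-SD band untouched. Two-sided pooled
  t-tests are the default; the printed significance bounds of the source
  table reproduce only one-sided, which the test suite records explicitly
  by asserting the one-sided bounds and two-sided significance at 0.05.

## Known limitations

* The differential stage is a documented stand-in for edgeR's exact-test
  path, not a bit-compatible clone; normalization differs (geometric-mean
  scaling vs quantile adjustment) and no tagwise shrinkage is offered.
* Covariates (e.g. paternal age) are assumed controlled by design; there
  is no GLM path.
* Headline real-data results (hundreds of DMRs, blinded accuracies)
  require the original sequencing data and are mirrored only qualitatively
  on synthetic data at desk scale.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg, n_blinded_case = 5, n_blinded_control = 5)
res <- test_all(sim$counts)
dmrs <- dmr_features(call_dmrs(res, sim$grid), sim$genome)
perm <- permutation_test(sim$counts, sim$grid, n_permutations = 50, seed = 2)
cv <- cross_validate(sim$counts, sim$grid)
cls <- blinded_workflow(sim$counts, sim$blinded_counts, sim$grid)
```
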