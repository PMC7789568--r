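# medipdmr

Window-based differential DNA methylation analysis and epigenetic-biomarker
validation for sperm MeDIP-seq, at desk scale.

## What problem this solves, and for whom

MeDIP-seq (methylated DNA immunoprecipitation sequencing) proxies DNA
methylation by sequencing read depth, preferentially over the >90% of the
genome with low CpG density. Given aligned-read intervals (or precomputed
window counts) for two groups of sperm samples — e.g. 13 fathers of
children with a condition vs 13 without — `medipdmr` finds *differential
DNA methylation regions* (DMRs), characterizes them, and assesses whether
they carry a classification signal usable as an epigenetic biomarker. It is
aimed at epigenomics analysts who want the classic window/NB-exact-test/DMR
pipeline as small, tested, scriptable R functions, plus a synthetic-data
generator so the whole pipeline can be exercised and validated with no
sequencing data at all.

## The statistics at the core

* The genome is tiled into 1-kb windows; counts `Y(w,j)` are modeled as
  negative binomial with common dispersion:
  `Var(Y) = mu + phi mu^2`.
* After scaling to the geometric-mean library size, `phi` is estimated by
  maximizing the conditional log-likelihood of counts given their group
  sums (golden-section search on `log phi`).
* Each window's group sums `S1 ~ NB(n1 r, pi)`, `S2 ~ NB(n2 r, pi)`
  (`r = 1/phi`) are compared by a conditional two-sided exact test: sum the
  probabilities of all splits of `s = s1 + s2` no more probable than the
  observed one. Benjamini–Hochberg controls FDR across windows.
* Adjacent significant windows (`p < 1e-5` by default) merge into DMRs,
  annotated with length, CpG density, max log2 fold change and
  strand-aware gene proximity (overlap / 1 kb / 5 kb / 10 kb upstream).
* Validation: balanced label-permutation null for the DMR count,
  leave-one-out cross-validation (DMRs re-derived per fold), and
  PCA nearest-centroid classification of blinded samples on DMR RPKM,
  with ±3 SD batch-outlier DMR removal.
* A clinical stage reproduces group `mean ± SD` summaries and Student's
  t-tests from a bundled per-sample semen-analysis table, including a 2-SD
  outlier-exclusion re-analysis.

## Worked example

```r
library(medipdmr)

cfg <- sim_config(seed = 1)          # 13 vs 13, 2 x 1 Mb, 50 planted DMRs
sim <- simulate_dataset(cfg, n_blinded_case = 5, n_blinded_control = 5)

res  <- test_all(sim$counts)         # per-window NB exact test
dmrs <- dmr_features(call_dmrs(res, sim$grid), sim$genome)
dmrs
#> dmr_set: 47 DMRs at p < 1e-05 (5 multi-window)
table(dmrs$direction)
#> decrease increase
#>       28       19

permutation_test(sim$counts, sim$grid, n_permutations = 50, seed = 2)
#> permutation null: observed 47 DMRs vs null max 2 over 50 perms; p = 0.01961

cross_validate(sim$counts, sim$grid)
#> leave-one-out cross-validation: accuracy 1.000 over 26 folds

cls <- blinded_workflow(sim$counts, sim$blinded_counts, sim$grid)
all(cls$predicted == sim$blinded_truth)
#> [1] TRUE
```

What the numbers mean: of the 50 planted differential regions, 47 are
recovered at `p < 1e-5` (the estimated dispersion, 0.102, matches the
generating 0.1); the 62/38 decrease/increase planting ratio shows through
in the called directions; no label permutation yields anything close to
the observed DMR count (empirical p = 1/51, the smallest possible with 50
permutations); and the DMR signature classifies every held-out and blinded
sample correctly at the simulated effect size.

The clinical stage:

```r
clinical_summary(load_semen_table())
#>                 field      case   control       t p_value     verdict
#> 1              volume     3 ± 1     3 ± 2  0.297  0.7690          NS
#> 4     progressive_pct   49 ± 11   36 ± 13  2.745  0.0113 significant
#> 6        immotile_pct   38 ± 12   52 ± 14 -2.676  0.0132 significant
#> ...
```

## Command line

Every stage is also a subcommand of the bundled CLI (see
`?medipdmr_cli`):

```sh
Rscript -e 'medipdmr::medipdmr_cli()' count --genome g.fa --reads r.bed \
    --sample-sheet samples.tsv --out counts.tsv
Rscript -e 'medipdmr::medipdmr_cli()' test --counts counts.tsv \
    --sample-sheet samples.tsv --out results.tsv
Rscript -e 'medipdmr::medipdmr_cli()' call-dmrs --results results.tsv --out dmrs.tsv
```

## Documentation

`vignettes/medipdmr-methods.Rmd` describes the model and its assumptions,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, numerical conventions, and known
limitations.
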