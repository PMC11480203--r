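# cooccupy

Tools for asking how one transcription factor reshapes the chromatin program
of another — in the motivating biology, how the AP-1 factor JUN restrains
the target-gene program of the Hippo-pathway coactivator YAP — and for
carrying that question from chromatin profiling all the way to patient
survival and a gain-of-function screen.

The package is a desk-scale, fully testable re-implementation of the
computational analyses such a study requires:

* **Spike-in normalization** of antibody-targeted nuclease profiling
  (CUT&RUN-style) counts: each sample is scaled by
  `reads_target(<120 bp) / reads_spike`, so genome-wide occupancy shifts
  survive library normalization.
* **Interval algebra** on peak tables: BED I/O, replicate-conservative peak
  sets ("keep peaks present in all replicates"), multi-set Venn
  categorization (joint vs factor-exclusive sites), closest-TSS distances,
  and random same-size peak subsets for permutation nulls.
* **Differential binding**: a transparent moderated log-ratio t-test with a
  pooled variance floor, BH correction, MA coordinates, and stratification
  of peaks into co-occupancy-change categories ("YAP only", "JUN only",
  "Joint", "none") at `padj < 0.1`.
* **Permutation empirical FDR** on TSS-distance distributions: the observed
  category's Kolmogorov–Smirnov statistic against the pooled remaining
  categories is compared to 10,000 random same-size draws; when no draw
  reaches the observed `D`, the eFDR is reported at its procedural floor
  `1/10,000 = 1e-4`.
* **Fuzzy c-means clustering** of top-induced genes (selected at
  `log2FC > 1`, `padj < 1e-4`) into three clusters, with per-condition-group
  summaries that read out which clusters are blunted by the repressor.
* **Dual-gene-signature survival screen**: per cohort, patients are scored by
  mean z-scored signature expression, median-split, and compared by log-rank
  test with an O/E hazard ratio; cohorts significant for signature 1 but not
  signature 2 localize the biology to one cluster.
* **RSA screen scoring**: reads-per-million normalization with a +1
  pseudocount, per-sgRNA log2 fold changes, activity bounds
  `l = median + 1·SD`, `u = median + 3·SD`, and the redundant-siRNA-activity
  iterative hypergeometric gene score.
* **Synthetic data with planted ground truth** for every input (peak
  landscapes, binding counts with spike-in tallies, expression matrices with
  three planted clusters, survival cohorts with a signature-linked hazard,
  sgRNA screens with planted hits), so the whole pipeline runs and validates
  itself without any download.

Everything is tidyverse-native: functions take a data frame first and return
tibbles, results have `tidy()`/`glance()` and `autoplot()` methods, and the
whole pipeline chains with the pipe.

## Worked example

```r
library(cooccupy)
library(dplyr)

cfg  <- sim_config(seed = 42)
land <- simulate_peak_landscape(make_genome(cfg), cfg)

# distance of every TSS to the closest peak of each planted category,
# then the permutation eFDR of the factor-A-exclusive category against
# the pooled other categories
dist_by_cat <- lapply(split(land$truth, land$truth$category), function(s)
  closest_distance(land$tss, s)$distance)
efdr_test(dist_by_cat[["factorA_only"]],
          c(dist_by_cat[["joint"]], dist_by_cat[["factorB_only"]]),
          n_draws = 10000, seed = 43)
#> Permutation eFDR (KS statistic)
#>   observed D = 0.1040  (n = 500 vs pool n = 1000)
#>   draws = 10000, exceedances = 68
#>   eFDR = 0.0068

# top-induced gene selection and fuzzy clustering
ex  <- simulate_expression(cfg)
tyi <- select_tyi(ex$de)            # 434 genes at log2FC > 1, padj < 1e-4
fit <- fuzzy_cmeans(zscore_expr(filter(ex$expr, gene %in% tyi$gene)),
                    c = 3, seed = 44)
fit
#> Fuzzy c-means fit: 434 genes, c = 3, m = 1.25
#>   objective 299.9709 after 4 iteration(s)
#> # A tibble: 3 × 2
#>   cluster     n
#>     <int> <int>
#> 1       1   150
#> 2       2   134
#> 3       3   150
```

The eFDR of 0.0068 says that only 68 of 10,000 random same-size distance
sets drawn from the pooled other categories separate from their complement
as strongly as the factor-A-exclusive category does: that category sits at
genuinely different distances from transcription start sites.  In the
clustering, the three recovered clusters match the three planted expression
archetypes (150/150/134 genes); `summarize_clusters()` then shows which
cluster is induced on activation but blunted under repressor
overexpression.

A single call runs every stage end to end and writes BED/TSV/JSON outputs
plus a machine-readable summary:

```r
run_pipeline(sim_config(seed = 1), outdir = "run1")
```

## Scope notes

The package consumes alignment *tallies* and count tables, not raw reads:
trimming, alignment, fragment-size filtering, and peak calling are upstream
of its interface, as is the differential-expression engine (a DE table is an
input contract).  The methods vignette (`vignettes/cooccupancy-methods.Rmd`)
documents the models, their assumptions, all tunable parameters, and what
the synthetic-data validation does and does not demonstrate about real data.
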