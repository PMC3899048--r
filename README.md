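# ripfisher

Genome-wide microRNA target identification from paired **PABP RIP-seq**
and **total RNA-seq** read counts.

When a miRNA mimic is transfected into cells, the miRNA-induced
silencing complex displaces poly(A)-binding protein (PABP) from its
target mRNAs and destabilises them. Sequencing the PABP-bound mRNA pool
(RIP-seq) alongside total RNA therefore reads out miRNA action twice:
targets lose representation in the immunoprecipitated library (strongly)
and in the total-RNA library (more weakly). `ripfisher` implements the
complete analysis that turns such paired count data into a
high-confidence target list, plus the downstream prediction-catalog and
tumor-expression analyses used to characterise that list. It is aimed at
computational biologists analysing RIP-seq/RNA-seq mimic-transfection
experiments, and at methodologists who want a fully simulated, truth-known
version of that analysis to probe.

## The statistical core

For each gene *g* and each control-vs-mimic pair of libraries, the
package forms the 2×2 contingency table

|                  | gene *g* | all other genes |
|------------------|----------|-----------------|
| control library  | *a*      | *b*             |
| mimic library    | *c*      | *d*             |

and computes the two-sided Fisher exact p-value (probability-sum
convention over the hypergeometric support) together with the
down-regulation odds ratio **OR = (a/b)/(c/d)**, so OR > 2 means at
least two-fold relative depletion under the mimic. Within each
comparison, p-values over all testable genes (a + c > 0) are
Benjamini–Hochberg corrected; a gene passes one comparison when
**OR > 2 and q < 0.001**, and enters the final call set only when it
passes **every** control×mimic comparison of that assay and cell line
(the strict intersection). Call sets are then combined across assays
(union and both-methods intersection) and cell lines, annotated against
target-prediction catalogs with upper-tail hypergeometric enrichment
tests over an expressed-gene background, compared across the four
miRNAs' prediction sets, and — for the tumor stage — related to
expression z-scores via sign classification, an exact two-tailed
binomial test of directional bias, |z| thresholded change counts, and
miRNA–target correlation profiles.

Counting units are per-gene "super-transcripts": the interval union of
all isoform exons, built with `collapse_isoforms()`; reads are assigned
uniquely (ambiguous multi-gene overlaps are discarded).

## Worked example

Everything is pipeable and truth-known thanks to the built-in simulator:

```r
library(ripfisher)

sim <- simulate_counts(
  sim_config(n_genes = 2000, n_targets = 100,
             rna_effect = 2.5, rip_effect = 1.6,   # combined RIP effect: 4x
             reads_per_sample = 1e6),
  seed = 42
)
rip <- call_targets(sim$counts, "RIP", "U251")
rna <- call_targets(sim$counts, "totalRNA", "U251")
rip
#> <target_call_set> RIP / U251: 96 genes called across 4 comparisons (OR > 2, q < 0.001)

comb <- combine_assays(rip, rna)
nrow(comb); sum(comb$both)
#> [1] 96
#> [1] 82

catalog <- simulate_predictions(sim$truth, seed = 43)
bg <- expressed_background(sim$counts, "U251")
enrichment_vs_tool(intersect(comb$gene_id, bg), catalog,
                   "TargetScan", "miR-137", bg)
#> # A tibble: 1 × 7
#>   tool       mirna       k     n     K     N  p_value
#>   <chr>      <chr>   <int> <int> <int> <int>    <dbl>
#> 1 TargetScan miR-137    79    96   180  2000 2.11e-73
```

96 of the 100 planted targets are called from the RIP branch alone (the
four weakest-expressed targets fall below the power of four intersected
exact tests at this depth), 82 are confirmed by both assays, and the
called set is overwhelmingly enriched for the simulated TargetScan
catalog (79 of 96 called genes among 180 predicted in a background of
2000 expressed genes).

`tidy()`/`glance()` methods expose per-gene and per-run summaries;
`autoplot()` draws volcano-style comparison panels, directional-bias
bars, threshold-count panels and correlation-sign profiles. The whole
analysis — counts (real or simulated) → differential calling →
combination → enrichment → multi-miRNA overlap → tumor stage — runs from
one configuration via `run_pipeline()`, which writes per-stage TSVs and
a JSON manifest of stage cardinalities.

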