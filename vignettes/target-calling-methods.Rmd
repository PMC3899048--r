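---
title: "Calling miRNA targets from PABP RIP-seq and RNA-seq counts: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling miRNA targets from PABP RIP-seq and RNA-seq counts: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripfisher)
```

## The experimental readout and its statistical model

A transfected miRNA mimic acts on its target mRNAs in two measurable
ways: the silencing complex displaces poly(A)-binding protein (PABP)
from the transcript, and the transcript is subsequently destabilised.
Sequencing the PABP-co-immunoprecipitated mRNA pool (the RIP assay) and
total RNA from the same transfections therefore yields two count
matrices in which genuine targets lose *relative representation* under
the mimic — strongly in RIP (displacement plus decay), more weakly in
total RNA (decay only).

`ripfisher` models each library as a fixed-depth draw: conditional on
the total number of assigned reads, a single gene's count against the
rest of the library is a 2×2 contingency problem. For gene $g$ in a
(control, mimic) pair of libraries the table is
$(a, b, c, d)$ = (reads on $g$ in control, other reads in control,
reads on $g$ in mimic, other reads in mimic), tested with the two-sided
Fisher exact test. The two-sided p-value uses the probability-sum
convention — the total probability of all tables with the observed
margins whose hypergeometric probability does not exceed that of the
observed table — rather than doubling one tail; this is the common
exact-test convention and remains well defined for asymmetric margins.
The implementation sums `dhyper` over the support with the same
relative tolerance (`1e-7`) that `stats::fisher.test` uses when
comparing probabilities, and the test suite verifies equality against
both an independent binomial-coefficient enumeration oracle (to 1e-12,
exhaustively for all tables with total ≤ 60) and `stats::fisher.test`
itself on random tables. Effect direction is *not* taken from the test:
it is enforced separately through the cross-product odds ratio
$\mathrm{OR} = (a/b)/(c/d)$, oriented so that OR > 1 means depletion
under the mimic. OR is $+\infty$ when the gene's mimic count is zero
(which passes any finite threshold), and undefined ($NA$) when the gene
has no reads in either library of the pair — such genes are excluded
from the comparison's testing family altogether.

## The calling procedure and its tuning parameters

Within one assay and cell line, every control library is compared
against every mimic library (2×2 replicates give four comparisons; extra
replicates extend the cross product). Per comparison:

1. Fisher p for every gene with $a + c > 0$;
2. Benjamini–Hochberg step-up correction with the family = all genes
   tested *in that comparison* (per-comparison families are the natural
   reading of repeating the procedure per pair; pooling all pairs into
   one family is the main defensible alternative and would be slightly
   more conservative after intersection);
3. retain genes with **OR > 2** and **q < 0.001**, both strict.

A gene is called only if it is retained in **every** comparison. The
thresholds are exposed (`or_min`, `q_max`) with those canonical
defaults; OR > 2 encodes "at least two-fold relative depletion" and
q < 0.001 makes the per-comparison lists stringent enough that their
4-way intersection is essentially free of multinomial noise (see the
null results below). Assay call sets are combined per cell line into a
union ("negatively impacted by either method") and a both-methods
intersection; cell-line unions are combined the same way.

For genes called by exactly one assay, `cross_method_fc_difference()`
compares average log2 fold changes (control rate over mimic rate,
+0.5 pseudocount on gene counts only — the exact test itself never sees
pseudocounts) between the identifying and the other assay. A
difference of one log2 unit — e.g. two-fold down where the other assay
shows no change — is the reporting threshold: "1× greater decrease" is
interpreted on the doubling scale, since a ratio-of-ratios is the only
scale on which the quantity is depth-free.

## Counting units

Counting uses one "super-transcript" per gene: the interval union of
all isoform exons (`collapse_isoforms()`, IRanges `reduce` underneath;
GTF input is converted from 1-based inclusive to 0-based half-open
coordinates on read). A read is assigned to a gene when it overlaps the
gene's blocks by at least one base (configurable) and overlaps no other
gene; ambiguous reads are discarded rather than fractionally assigned,
keeping all contingency cells integral, and unassigned/ambiguous/skipped
tallies are reported so that read conservation is checkable. Counting
ignores strand by default (random-hexamer libraries are unstranded); a
`same_strand` flag restricts overlaps when the protocol warrants it.

## What the simulator emulates — and what it does not

`simulate_counts()` draws each library multinomially at fixed depth
over genes with probabilities proportional to a log-normal baseline
(default $\mu = 0, \sigma = 1$, a typical span of bulk expression)
times a per-gene effect: 1 for controls and non-targets,
$1/\mathrm{rna\_effect}$ for targets in mimic total-RNA libraries, and
$1/(\mathrm{rna\_effect}\cdot\mathrm{rip\_effect})$ in mimic RIP
libraries — displacement multiplies on top of decay, so the RIP assay
always carries at least the RNA-level effect. The reference operating
point used throughout the tests is 5,000 genes, 250 targets,
`rna_effect = 2.5`, `rip_effect = 1.6` (combined RIP effect 4), two
replicates per condition and 2–5×10⁶ reads per library; at these sizes
the whole calling pipeline runs in seconds per simulated experiment.

The default `overdispersion = 0` makes the generator *exactly* the null
model of the contingency construction (fixed-depth multinomial), which
is the right default for validating the test's type-I behaviour: any
false calls then reflect the procedure, not a modelled biological
variance. Setting `overdispersion > 0` multiplies each replicate's
probabilities by independent mean-1 gamma factors of that variance,
emulating biological replicate dispersion; because the Fisher test
assumes pure multinomial sampling, overdispersed runs will inflate
per-comparison positives, and it is precisely the all-comparisons
intersection that restores stringency. Passing tests on the default
conditions therefore demonstrate correctness of the procedure under its
own sampling assumptions — not robustness to replicate heterogeneity,
library-preparation batch effects, multi-mapping ambiguity or
transfection-efficiency kinetics, none of which are modelled.

`simulate_predictions()` emulates prediction catalogs with a per-tool
sensitivity and false-annotation rate; additional miRNAs share each
annotated focal-miRNA target with probability `shared_fraction`
(independently per miRNA) and annotate non-annotated genes at the
tool's false rate so the extra catalogs have realistic sizes.
`simulate_zscores()` generates the tumor stage's inputs from a latent
per-sample miRNA activity $a_s \sim N(0,1)$: the miRNA z-score is
$-\mathrm{mir\_shift} + a_s$, target z-scores are
$\mathrm{target\_shift} - \mathrm{coupling}\cdot a_s + \varepsilon$,
non-targets pure noise. Under this definition the expected miRNA
down-proportion is $\Phi(\mathrm{mir\_shift})$ and positive coupling
plants the negative miRNA–target correlation that the correlation
profile should recover. All generators take a mandatory seed, restore
the caller's RNG state, and are byte-reproducible.

## Enrichment, overlap and tumor analyses

Enrichment of a called set against one prediction tool is the
upper-tail hypergeometric probability with background $N$ = genes with
at least `min_count` (default 1) read in at least one library of the
cell line; identified sets must be contained in the background, and
predictions outside it are not counted. The same background is used for
the pairwise overlap tests of the multi-miRNA analysis (the analysis
takes its gene universe as an explicit argument, since restricting to a
shared cross-cell-line background is equally defensible). One
numerical point deserves note: upper-tail hypergeometric p-values are
discrete, so under uniform draws they are conservative rather than
exactly uniform — the calibration tests check one-sided validity of the
raw p and apply the Kolmogorov–Smirnov test to the standard
tie-randomized transform $p - U\cdot P(X = k)$, which is exactly
uniform for a correct implementation.

The tumor stage classifies a z-score as up (z > 0), down (z < 0) or
excluded (z = 0 or missing — with continuous z-scores ties are
measure-zero, and excluding them follows the strict sign rule);
directional bias is the exact two-tailed binomial test against a 0.5
down-proportion with a Clopper–Pearson 95% interval (exactness
preferred since the interval method is otherwise unconstrained).
Thresholded change counts tally gene-sample events at |z| > 2, 3, 4, 5
by subtype, counting a gene once per sample in which it passes.
Correlation profiles use Pearson correlation by default (Spearman via a
flag), drop missing values pairwise, and exclude genes with fewer than
three complete pairs or zero variance, reporting the exclusion count.

## Worked demonstration

```{r demo}
sim <- simulate_counts(
  sim_config(n_genes = 800, n_targets = 60, rna_effect = 2.5,
             rip_effect = 1.6, reads_per_sample = 4e5),
  seed = 11
)
rip <- call_targets(sim$counts, "RIP", "U251")
rna <- call_targets(sim$counts, "totalRNA", "U251")
glance(rip)
comb <- combine_assays(rip, rna)
c(union = nrow(comb), both = sum(comb$both),
  true_positives = sum(comb$gene_id %in%
                         sim$truth$gene_id[sim$truth$is_target]))
```

```{r volcano, fig.width = 7, fig.height = 5}
autoplot(rip)
```

```{r tumor}
zs <- simulate_zscores(n_genes = 300, n_samples = 261, mir_shift = 1,
                       coupling = 0.5, seed = 12)
directional_bias(zs$mir_z)
tidy(correlation_profile(zs$mir_z, zs$zscores))
```

## Design choices and known limitations

* **Exact test over count-model regression.** A negative-binomial GLM
  (DESeq2/edgeR style) would model replicate dispersion; the exact
  contingency approach instead conditions on depth and leans on the
  all-comparisons intersection for replicate robustness. This is the
  procedure implemented and validated here; it is anti-conservative if
  libraries are strongly overdispersed and only the intersection guards
  against that.
* **Per-comparison BH families.** See above; family sizes are reported
  per comparison so the choice is auditable.
* **Ambiguous reads discarded.** No fractional assignment; at typical
  gene spacing this loses little and keeps the test exact.
* **Ties and degenerate inputs.** Strict thresholds throughout
  (OR > 2, q < 0.001, z ≠ 0); genes untestable in a pair are dropped
  from that family; all-zero contingency tables and all-excluded
  z-vectors raise errors rather than silently propagating.
* **Problem sizes.** The test suite exercises the full operating point
  (5,000 genes, 2–5×10⁶ reads, five null replicates) and smaller
  configurations elsewhere; the exhaustive Fisher sweep covers every
  table with total ≤ 60.
* **Not modelled.** Spliced (multi-block) read alignments, BAM input,
  aligner behaviour, catalog retrieval from the prediction tools'
  native formats, GO/network analyses, and any wet-lab readout. The
  2⁻ΔΔCt helper is provided for analysing qRT-PCR follow-up
  measurements but no instrument parsing is attempted.
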