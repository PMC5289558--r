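# epiresponder

Integrative epigenome–transcriptome analysis of cell reprogramming, built
around one question: when fibroblasts are pushed toward pluripotency, which
genes switch to the embryonic-stem-cell program early, which switch late, and
which go off the rails entirely in partially reprogrammed cells?

The package is for computational biologists working with histone-mark
ChIP-seq (H3K4me3, H3K27me3) and replicate gene-expression data across a
panel of cell states — a somatic baseline, a partially reprogrammed iPSC
(iPSCp), fully reprogrammed iPSCs, and ESCs. It provides:

* **ChIP tag-density quantification**: normalized tag densities in 200-bp
  windows around every TSS (`tss_profile()`), per-gene densities over gene
  bodies or promoters in tags/kb/10M tags (`gene_density()`), mark fold
  changes with a pseudocount (`mark_log2fc()`), and cross-sample profile
  correlations (`profile_correlation()`).
* **Hilbert-curve maps** of chromosome-wide signal (`hilbert_d2xy()`,
  `signal_to_grid()`), which keep genomic neighborhoods visually adjacent.
* **Differential expression**: quantile normalization
  (`quantile_normalize()`), one-way ANOVA DEG calling with the joint rule
  *p* < 0.01 and fold change ≥ 2 (`call_degs()`), and complete-linkage
  Euclidean sample clustering (`cluster_samples()`).
* **Responder classification** (`classify_responders()`): given the two
  contrasts ESC-vs-somatic and iPSCp-vs-somatic, each gene is assigned per
  direction stratum to

  | class | ESC vs somatic | iPSCp vs somatic | reading |
  |---|---|---|---|
  | convergent | DEG | DEG, same direction | early responder |
  | resistant | DEG | not DEG | late responder |
  | divergent | not DEG | DEG | iPSCp-only dysregulation |
  | unchanged | not DEG | not DEG | — |

  with class-wise mark summaries (`class_mark_summary()`) and stratum
  fold-change correlations (`class_fc_correlation()`).
* **A synthetic-data generator** (`simulate_study()`) that plants known gene
  classes — somatic-specific, ESC-specific, early/late responders, divergent,
  housekeeping — into a miniature genome with mark-consistent tag libraries
  and replicate expression, plus a truth table, so the whole pipeline is
  verifiable by parameter recovery.

## The model in brief

Tag densities are counts of single-bp tag positions in half-open windows,
normalized per 10 million tags. A gene is a DEG between groups A and B when
the one-way ANOVA F-test on log2 replicate values gives *p* < 0.01 **and**
|log2FC| ≥ 1, where log2FC is the difference of group means (a geometric-mean
fold change). The responder classes are pure set logic over the two contrasts
against the somatic baseline, stratified by direction; a gene DEG-up in one
contrast and DEG-down in the other is recorded in both strata and flagged.

## Worked example

```r
library(epiresponder)

study <- simulate_study(sim_config(seed = 7))      # 2,000 genes, 4 cell types
esc   <- call_degs(study$expression, "ESC",   "somatic")
ipscp <- call_degs(study$expression, "iPSCp", "somatic")
responders <- add_truth(classify_responders(esc, ipscp), study$truth)

attr(responders, "class_counts")
#>             stratum
#> class        down none  up
#>   convergent  406    0  96
#>   divergent    75    0  92
#>   resistant   122    0 370
#>   unchanged     0  839   0

round(recovery_stats(responders, "convergent"), 3)
#> precision    recall  n_called   n_truth
#>      1.00      0.99    502.00    507.00
round(recovery_stats(responders, "resistant"), 3)
#> precision    recall  n_called   n_truth
#>     0.992     0.992   492.000   492.000

cat(sprintf("r(down) = %.3f   r(up) = %.3f\n",
    class_fc_correlation(esc, ipscp, "down"),
    class_fc_correlation(esc, ipscp, "up")))
#> r(down) = 0.259   r(up) = 0.151
```

The class counts partition the 2,000 genes per stratum; precision and recall
are measured against the planted truth, so ≥ 0.99 means the classifier
recovered essentially every planted early responder as convergent and every
late responder as resistant. The down-stratum fold-change correlation
exceeding the up stratum reflects the planted asymmetry: repression of the
somatic program runs ahead of activation of the ESC program in the partial
iPSC.

The end-to-end pipeline, including tag quantification, Hilbert grids,
clustering and all TSV/Newick outputs, runs with

```r
run_pipeline(demo_config(seed = 7), "demo_out")
```

and is byte-for-byte reproducible for a fixed seed.

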