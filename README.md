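# longacc

Differential chromatin accessibility and transcription-factor nomination
for case–control multi-omics cohorts, as used in extreme-longevity studies
of peripheral blood mononuclear cells (PBMCs).

## What it does

Cohort studies of exceptional longevity profile centenarians against
younger controls with bulk ATAC-seq (chromatin accessibility) and RNA-seq
(expression) from the same donors. The analytical question is regulatory:
which genomic regions systematically open or close with extreme age, what
chromatin states do they occupy, do accessibility changes track expression
changes of nearby genes, and which transcription factors (TFs) plausibly
drive the remodeling — overall and within each sex?

`longacc` implements that full analysis as a tested, reusable R package
built on Bioconductor containers (`GenomicRanges`, `Biostrings`):

1. **Consensus peaks** (`consensus_peaks`, `filter_peaks`) — merge
   per-sample scored peak calls (q ≤ 0.01) into a consensus set, then
   filter by sample support (> 20 samples), a CPM cap against
   hyper-accessible artifacts (≤ 500), blacklist overlap, and restriction
   to autosomes; every removal is attributed to a rule in a filter report.
2. **Differential testing** (`differential_test`, `nb_wald_test`) — a
   negative-binomial log-link GLM per feature with median-of-ratios size
   factors, method-of-moments dispersion, IRLS fitting, and a Wald test on
   the group coefficient; BH-adjusted, with calls requiring both
   padj < 0.05 and |fold change| > 1.5. The same engine runs on ATAC peak
   counts and RNA gene counts, pooled and within each sex stratum.
3. **Chromatin-state annotation** (`annotate_states`, `resolve_state`) —
   per-cell-type state maps resolved by a fixed 11-state priority order,
   pooled into 6 meta-states, with cell-specificity labeling.
4. **Peak–gene integration** (`pair_promoter_genes`, `nearest_gene_great`,
   `correlate_lfc`) — promoter pairing within ±1 kb of a TSS, GREAT-style
   nearest-gene assignment, and Pearson correlation of accessibility
   versus expression log2 fold changes.
5. **Motif analysis** (`scan_peaks`, `motif_enrichment`,
   `occurrence_profile`, `footprint_profile`) — PWM scanning of both
   strands at 80% of the maximum score, hypergeometric enrichment of
   motifs in differential versus stable peaks (counting only hits within
   ±200 bp of the summit), summit-relative occurrence profiles, and
   footprint depth summaries.
6. **TF nomination** (`nominate_tfs`, `assign_tf_targets`) — the
   intersection rule: a TF is nominated when its motif is enriched
   (padj < 0.05) in opening peaks **and** its own gene is significantly
   up-regulated (or the closing/down mirror image), evaluated in the
   pooled cohort and in each sex stratum; nominations report which strata
   support them.

A synthetic-cohort generator (`sim_config`, `simulate_cohort`,
`write_cohort`) produces a complete on-disk input set — sample sheet,
per-sample peak calls, count matrices, state maps, peak sequences with
planted motifs, a JASPAR-style motif panel, and machine-readable ground
truth — so that every stage, and the pipeline end to end, is testable
against known planted effects.

## Worked example

Simulate a small cohort (15 centenarians vs 15 controls, 600 peaks, 200
genes), write it to disk, and run the whole pipeline on the directory:

```r
library(longacc)

cfg <- sim_config(n_peaks = 600, n_genes = 200, seed = 1)
cohort <- simulate_cohort(cfg)
dir <- file.path(tempdir(), "cohort")
write_cohort(cohort, dir)

result <- run_pipeline(pipeline_config(dir), verbose = FALSE)
print(result)
#> longacc pipeline result
#>   consensus peaks: 612 ( 583 after filtering )
#>  stratum da_opening da_closing de_up de_down
#>      all         57         34    15      11
#>   female         62         42    15      13
#>     male         43         31    14      11
#>   promoter fold-change correlation: R = 0.744 (n = 239)
#>   nominated TFs: LTF1
```

The differential table carries the per-peak statistics:

```r
head(result$diff_atac$all[result$diff_atac$all$call != "ns",
                          c("feature_id", "log2fc", "wald_p", "padj", "call")])
#>     feature_id     log2fc       wald_p         padj    call
#> 11 peak_000011  1.5236252 3.128278e-27 9.118929e-25 opening
#> 14 peak_000014 -1.8653651 4.853088e-15 2.357792e-13 closing
#> 40 peak_000041  0.9942180 8.290305e-05 6.531416e-04 opening
#> 50 peak_000051 -1.5425992 8.938601e-13 2.481526e-11 closing
#> 58 peak_000059  1.5269257 1.273968e-05 1.160505e-04 opening
#> 66 peak_000067 -0.7372182 3.962876e-04 2.961996e-03 closing
```

Motif enrichment separates the planted TF from the decoy (whose gene is
up-regulated but whose motif is never planted) and from the inert
database motifs:

```r
result$enrichment$all$opening[1:3, c("tf", "fg_with_motif", "fg_total",
                                     "bg_with_motif", "bg_total", "padj")]
#>       tf fg_with_motif fg_total bg_with_motif bg_total         padj
#> 1   LTF1            24       57            39      492 2.809585e-09
#> 2   DTF1             0       57            20      492 1.000000e+00
#> 3 DBTF01            0       57             4      492 1.000000e+00

result$nominations
#>     tf  direction stratum_support n_strata
#> 1 LTF1 opening+up all,female,male        3
```

Only `LTF1` — the TF whose motif is planted in opening peaks *and* whose
gene is up-regulated — is nominated, with support in all three strata.
`write_pipeline_result(result, "out/")` exports every table as TSV.

The methods vignette (`vignettes/longacc-methods.Rmd`) documents the
statistical model, every numerical decision, and what the generator
emulates versus simplifies.

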