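---
title: "longacc: methods and design of the synthetic longevity multi-omics pipeline"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{longacc: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`longacc` implements a complete chromatin-accessibility case/control study
in miniature: a synthetic cohort generator that plants known effects, and
an analysis pipeline — consensus peaks, negative-binomial differential
testing, chromatin-state annotation, ATAC/RNA integration, motif
enrichment and transcription-factor nomination — that must recover them.
This vignette documents the statistical model behind each stage, the
meaning and defaults of every generator parameter, and the numerical
decisions that are easy to get subtly wrong.

```{r load}
library(longacc)
```

## 1. The study design being emulated

The package models a two-group bulk multi-omics comparison (`control` vs
`centenarian`) profiled with ATAC-seq (chromatin accessibility peaks) and
RNA-seq (gene expression), with both sexes represented and analyses run in
three strata: `all` (pooled, sex as a covariate), `female` and `male`
(single-sex, group-only design). The scientific questions mirrored by the
pipeline are:

1. Which regulatory regions open or close with extreme longevity?
2. In which chromatin context (enhancer, promoter, quiescent, ...) and in
   which cell population do those regions sit?
3. Do accessibility changes at promoters propagate to expression changes?
4. Which transcription factor is the upstream driver — evidenced jointly
   by motif enrichment in opening peaks and upregulation of the TF's own
   gene, consistently across strata?

## 2. Synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate everything the pipeline
consumes. Defaults describe a 15 vs 15 cohort with balanced sexes,
5,000 true peaks and 2,000 genes.

### Count model

Counts are negative binomial with a log-linear mean:

$$K_{ij} \sim \mathrm{NB}\!\left(\mu_{ij},\ \alpha\right),\qquad
\mu_{ij} = c_i \cdot \frac{d_j}{10^6}\cdot
2^{\,\beta_i\, x_j\, s_{ij}},\qquad
\mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha\,\mu_{ij}^2$$

where $c_i$ is the feature's baseline CPM (log-normal, median 3 for
peaks), $d_j$ the sample's sequencing depth (log-uniform over
`lib_size_range`, default $10^7$–$3\times10^7$), $x_j$ the group
indicator, $s_{ij}$ a sex-match indicator for sex-specific effects and
$\beta_i$ the planted log2 fold change. The dispersion default
$\alpha = 0.2$ corresponds to a biological coefficient of variation of
$\sqrt{0.2}\approx 0.45$, typical of bulk human cohorts.

A deliberate design point: sequencing depths are carried in the sample
sheet (`lib_size_atac`, `lib_size_rna`) and used for CPM computation. At
desk scale a few thousand peaks capture only a sliver of the genome, so
column sums of the count matrix overstate per-region CPM by orders of
magnitude; using the true depth keeps the CPM-based artifact filter
(≤ 500) meaningful.

### Planted structure

* `frac_opening = 0.10`, `frac_closing = 0.05` of peaks receive
  $\beta_i \sim \pm N(1.5, 0.1)$ (`lfc_mean`, on the log2 scale).
* `frac_sex_specific = 0.20` of planted peaks act in one sex only (80%
  female, matching the direction of the sex imbalance the pipeline must
  detect via strata).
* Genes sit under the first `n_genes` peaks (TSS near the peak summit);
  a gene whose promoter peak is planted inherits the effect with
  $N(0, 0.2)$ noise, clamped away from the calling threshold so gene
  truth labels are unambiguous.
* One planted TF (`LTF1`, an ETS-like `CCGGAAGT` consensus) has its motif
  inserted near the summit of opening peaks with probability 0.4 versus
  0.05 elsewhere, and its gene upregulated four-fold in all strata — sized
  so the expression gate stays powered in the single-sex strata, where
  the standard error of the log2 fold change is about 0.4. A decoy TF
  (`DTF1`, `TGACGTCA`) is upregulated identically but its motif is planted
  only at the background rate — the nomination logic must reject it.
  The scanned panel additionally carries 14 inert "database" motifs
  (`DBTF01`–`DBTF14`, mapped to unaffected genes), so the BH correction
  across motifs operates over a realistic family rather than a vacuous
  two-motif one; with only two motifs the decoy's adjusted p-value
  collapses to its raw p-value and any 5%-level null enrichment in any
  stratum would nominate it.
* Nuisance classes among unplanted peaks: ~2% low-support peaks (fail the
  read-support filter), ~0.4% pile-up artifacts (fail the CPM cap),
  ~0.5% blacklisted regions, plus chrX decoy peaks (fail the autosome
  rule). Planted peaks keep ordinary baselines and stay off the
  blacklist, so recovery measures the engine rather than the filters.
* Per-sample peak calls are the true peaks with Gaussian boundary jitter
  (sd 25 bp), 10% dropout and 90% of q-values below the 1% threshold.
* Peak sequences are i.i.d. uniform ACGT with the planted/decoy consensus
  instances inserted; chromatin-state segmentations tile each chromosome
  so ~5% of peaks are active in exactly one of three cell types.

Everything is deterministic given `seed`: each stage draws from a
sub-seed derived by hashing the stage name (`stage_seed()`), so
generating sequences before or after peak calls cannot change either.

```{r cohort}
co <- simulate_cohort(sim_config(n_peaks = 300, n_genes = 120, seed = 7))
table(co$truth$peak_effects$effect)
```

## 3. Consensus peaks and filters

`build_consensus()` keeps per-sample peaks with q ≤ 1% (inclusive) and
merges across samples, coalescing overlapping *and* book-ended intervals.
`filter_consensus()` then applies four rules, each reported separately by
`filter_consensus_report()`:

* support: maximum raw count strictly greater than 20 in at least one
  sample;
* artifact cap: maximum CPM at most 500 (inclusive);
* no blacklist overlap (≥ 1 bp);
* autosomes only (chr1–chr22).

## 4. The NB Wald differential engine

`differential_test()` is the package's own implementation, written to be
checkable against independent oracles rather than delegating to them:

1. **Normalization** — median-of-ratios size factors over all-positive
   features, with a library-size fallback (and warning) when none exist.
2. **Dispersion** — method-of-moments, pooling
   $(s^2_c - \bar m_c)/\bar m_c^2$ across design cells weighted by their
   residual degrees of freedom, floored at $10^{-8}$. Dispersions may
   also be supplied, which is how the test suite pins both this engine
   and a reference implementation to identical inputs.
3. **GLM fit** — per-feature NB log-link IRLS with weights
   $\mu/(1+\alpha\mu)$, design `~ group` (+ `sex` in the pooled stratum),
   deviance-based convergence.
4. **Wald test** — $z = \hat\beta_g / \mathrm{se}(\hat\beta_g)$ from the
   observed information; `log2fc` is $\hat\beta_g/\ln 2$.
5. **Adjustment and calling** — hand-implemented Benjamini–Hochberg
   (step-up) for the genome-wide screens and Holm (step-down) for small
   enrichment panels; both are unit-tested against `p.adjust`. Calls
   require `padj < 0.05` **and** `|FC| > 1.5`, both strict.

A worked contrast, used throughout the tests: counts 10, 12, 11 versus
30, 28, 33 give fitted group means equal to the sample means, hence

```{r worked}
X <- cbind(`(Intercept)` = 1, group = c(0, 0, 0, 1, 1, 1))
nb_wald_test(c(10, 12, 11, 30, 28, 33), X, rep(1, 6), alpha = 0.1)$log2fc
log2(91 / 33)
```

## 5. Chromatin-state annotation

Peaks are intersected with per-cell-type 11-state segmentations. When
several states overlap a peak the conflict is resolved by a fixed
priority order (`state_vocabulary()`): Active Enhancer first, then Genic
Enhancer, Bivalent TSS, Weak Enhancer, Bivalent Enhancer, PolyComb
repressed, TSS Flanking, Transcription, ZNF Genes and repeats,
Heterochromatin, and Quiescent/Low signal last; no overlap defaults to
Quiescent/Low signal. States pool into 6 meta-states (TSS, Enhancer,
Repressed PolyComb, Transcription, Quiescent, Other). A peak is
*cell-specific* when its resolved state is an active promoter/enhancer
state in exactly one cell type. `resolve_state()` is tested against a
brute-force argmax over all 2,047 non-empty state subsets.

## 6. ATAC/RNA integration

`pair_promoter_genes()` pairs a peak with every gene whose TSS ±1,000 bp
window it touches (all pairs are kept; the distance reported is the
signed, strand-aware edge distance). `assign_nearest_gene()` implements
single-nearest-gene assignment with a basal domain (5 kb upstream / 1 kb
downstream, strand-aware) and a 1 Mb cap, from the peak midpoint.
`correlate_lfc()` joins peak and gene log2 fold changes over the pairs
and reports Pearson's r with the regression t-test p-value.

## 7. Motifs and TF nomination

PFMs become log-odds PWMs with pseudocount 0.25 added per cell (column
sums include the pseudocounts), scored in bits against a uniform
background. Scanning covers both strands — reverse-strand hits found at
1-based position $j$ of the reverse complement map back to 0-based
forward offset $L - w + 1 - j$ — with the default threshold at 80% of the
PWM's maximum score. Enrichment counts a peak as carrying the motif when
a hit's center falls within ±200 bp of the summit, and tests the
foreground against the pooled universe with a one-sided hypergeometric
upper tail (`phyper(k - 1, ...)`, the classic off-by-one). Occurrence
profiles bin hit centers (±500 bp, 10 bp bins, counting peaks not hits);
footprint depth is `mean(flank) − mean(core)` over ±50 bp flanks, so
positive depth means protection.

`nominate_tfs()` applies the headline rule: a TF is nominated in a
stratum when its motif is enriched (BH padj < 0.05) in that stratum's
opening peaks *and* its own gene is called up (mirrored for
closing/down). The per-stratum nominations are aggregated into a
`stratum_support` string; the decoy TF, upregulated but not enriched,
must never appear.

## 8. Numerical and implementation decisions

* **Strict inequalities.** `padj < 0.05`, `|FC| > 1.5` and support
  `> 20` are strict; q `≤ 0.01` and CPM `≤ 500` are inclusive. The test
  suite pins each boundary.
* **Coordinates.** All disk formats are 0-based half-open (BED);
  in-memory `GRanges` are 1-based closed. Summit positions are
  `start + summit_offset`; TSS distances are computed between single-bp
  positions (not interval gaps, which differ by one).
* **Priority resolution** is a total order, implemented as an argmax over
  ranks so it cannot depend on input order.
* **Determinism.** `with_seed()` saves and restores `.Random.seed`;
  every randomized stage uses a named sub-seed below $2^{31}$.
* **Oracles, not dependencies.** DESeq2, `p.adjust`, `fisher.test` and
  `Biostrings::matchPWM` appear only in the tests as independent
  cross-checks; the shipped implementations are self-contained.
* **Problem sizes.** Unit and property tests run on 250–600-peak
  cohorts; calibration and recovery checks use 1,500–5,000 features; the
  20-seed end-to-end nomination check runs 600-peak cohorts — the largest
  size whose 20 repetitions fit the test-suite compute budget while
  keeping the per-stratum foregrounds large enough for the enrichment
  test to be adequately powered.

## 9. What the generator does and does not emulate

It emulates: NB overdispersion with realistic depths, sex-specific
effects, promoter-coupled expression changes, imperfect peak calling
(jitter, dropout, sub-threshold q-values), technical nuisance peaks,
motif planting with positional preference for summits, and multi-cell
chromatin-state structure.

It does **not** emulate: GC or fragment-length bias, peak-width signal
structure within peaks, linkage between neighbouring peaks, realistic
genomic sequence composition (background is uniform ACGT), cell-type
deconvolution, batch effects, or mean-dependent dispersion trends. The
differential engine likewise fits a fixed per-feature dispersion rather
than shrinking toward a trend — adequate here because the generator
matches that model, and the right scope for desk-scale validation.

## 10. Running the pipeline

```{r pipeline, eval = FALSE}
dir <- tempfile("cohort")
write_cohort(simulate_cohort(sim_config(n_peaks = 400, n_genes = 150,
                                        seed = 1)), dir)
res <- run_pipeline(pipeline_config(dir), out_dir = file.path(dir, "out"))
res$nominations
```

The result bundles every stage's table; `print()` gives a one-screen
summary. `scripts/acceptance.R --seed <int> --out <path>` reproduces the
package's headline quantities as JSON.
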