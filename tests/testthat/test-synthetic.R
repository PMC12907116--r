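# Synthetic cohort generator: determinism, truth-table closure, count
# model fidelity, peak calls and sequences.

small_cfg <- function(..., seed = 11) {
  sim_config(n_control = 6, n_centenarian = 6, n_peaks = 300,
             n_genes = 120, seed = seed, ...)
}

test_that("seeded RNG helpers are deterministic and order-independent", {
  expect_identical(stage_seed(42L, "layout"), stage_seed(42L, "layout"))
  stages <- c("layout", "effects", "samples", "counts", "states",
              "peak_calls", "sequences")
  seeds <- vapply(stages, stage_seed, numeric(1), seed = 42L)
  expect_equal(anyDuplicated(seeds), 0)
  expect_true(all(seeds >= 0 & seeds < 2^31))

  # with_seed restores the caller's RNG state
  set.seed(1); before <- .Random.seed
  x <- with_seed(99, runif(5))
  expect_identical(.Random.seed, before)
  expect_identical(x, with_seed(99, runif(5)))
})

test_that("simulate_cohort is reproducible and seed-sensitive", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_identical(a$atac_counts, b$atac_counts)
  expect_identical(a$rna_counts, b$rna_counts)
  expect_equal(a$peaks, b$peaks)
  expect_identical(a$truth$peak_effects, b$truth$peak_effects)
  c_ <- simulate_cohort(small_cfg(seed = 12))
  expect_false(identical(a$atac_counts, c_$atac_counts))
})

test_that("derived artefacts do not depend on generation order", {
  co1 <- simulate_cohort(small_cfg())
  calls1 <- simulate_peak_calls(co1)
  seqs1 <- simulate_sequences(co1)
  co2 <- simulate_cohort(small_cfg())
  seqs2 <- simulate_sequences(co2)   # reversed order
  calls2 <- simulate_peak_calls(co2)
  expect_identical(as.character(seqs1$sequences),
                   as.character(seqs2$sequences))
  expect_equal(calls1, calls2)
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(n_control = 0), "positive")
  expect_error(sim_config(frac_opening = 1.2), "fractions")
  expect_error(sim_config(frac_opening = 0.7, frac_closing = 0.5),
               "exceed 1")
  expect_error(sim_config(n_genes = 10, n_peaks = 5), "n_genes")
  expect_error(sim_config(lib_size_range = c(3e7, 1e7)), "increasing")
  expect_error(sim_config(dispersion = 0), "> 0")
})

test_that("truth tables are closed over peaks, genes and states", {
  co <- shared_cohort()
  cfg <- co$config
  ids <- S4Vectors::mcols(co$peaks)$name
  expect_identical(co$truth$peak_effects$peak_id, ids)
  expect_identical(co$truth$gene_effects$gene_id,
                   S4Vectors::mcols(co$tss)$gene_id)
  # chrX decoys exist and carry no effect
  chrx <- as.character(GenomeInfoDb::seqnames(co$peaks)) == "chrX"
  expect_equal(sum(chrx), max(2, ceiling(0.02 * cfg$n_peaks)))
  expect_true(all(co$truth$peak_effects$effect[chrx] == "none"))
  # planted fractions are honoured exactly (TF forcing can only convert
  # 'none' peaks when no candidates exist, so allow >=)
  eff <- co$truth$peak_effects$effect
  expect_gte(sum(eff == "opening"), round(cfg$frac_opening * cfg$n_peaks))
  expect_equal(sum(eff == "closing"), round(cfg$frac_closing * cfg$n_peaks))
  # every (peak, cell type) has exactly one state assignment
  st <- co$truth$state_assignments
  expect_equal(nrow(st), length(ids) * length(co$state_maps))
  expect_true(all(st$state %in% state_vocabulary()$priority))
  # the planted TF gene is upregulated and not sex-specific
  tf <- co$truth$planted_tf
  ge <- co$truth$gene_effects
  for (g in c(tf$gene_id, tf$decoy_gene)) {
    expect_equal(ge$effect[ge$gene_id == g], "up")
    expect_equal(ge$sex_specificity[ge$gene_id == g], "all")
    expect_gte(ge$lfc[ge$gene_id == g], log2(1.5) + 0.5)
  }
  db <- names(default_database_motifs())
  expect_setequal(co$tf_gene_map$tf, c("LTF1", "DTF1", db))
  # database motifs map to unaffected genes, distinct from TF/decoy genes
  dbg <- co$tf_gene_map$gene_id[co$tf_gene_map$tf %in% db]
  dbg <- dbg[!is.na(dbg)]
  expect_true(all(ge$effect[match(dbg, ge$gene_id)] == "none"))
  expect_false(any(dbg %in% c(tf$gene_id, tf$decoy_gene)))
})

test_that("a null cohort plants nothing", {
  co <- simulate_cohort(small_cfg(frac_opening = 0, frac_closing = 0))
  expect_true(all(co$truth$peak_effects$effect == "none"))
  expect_true(all(co$truth$peak_effects$lfc == 0))
  expect_true(all(co$truth$gene_effects$effect == "none"))
  expect_true(is.na(co$truth$planted_tf$gene_id))
  planted_rows <- co$tf_gene_map$tf %in% c("LTF1", "DTF1")
  expect_true(all(is.na(co$tf_gene_map$gene_id[planted_rows])))
})

test_that("planted fold changes are realized in the counts", {
  co <- simulate_cohort(sim_config(n_peaks = 2000, n_genes = 500,
                                   frac_opening = 0.1, frac_closing = 0.05,
                                   lfc_mean = 1.5, seed = 7))
  sheet <- co$sample_sheet
  cpm <- sweep(co$atac_counts, 2, sheet$lib_size_atac / 1e6, "/")
  pe <- co$truth$peak_effects
  open_all <- pe$peak_id[pe$effect == "opening" &
                           pe$sex_specificity == "all"]
  cent <- sheet$group == "centenarian"
  ratio <- rowMeans(cpm[open_all, cent]) / rowMeans(cpm[open_all, !cent])
  med <- median(log2(ratio))
  expect_gt(med, 1.2)
  expect_lt(med, 1.8)
  # closing peaks move the other way
  close_all <- pe$peak_id[pe$effect == "closing" &
                            pe$sex_specificity == "all"]
  expect_lt(median(log2(rowMeans(cpm[close_all, cent]) /
                          rowMeans(cpm[close_all, !cent]))), -1.2)
  # sex-specific opening effects are attenuated in the pooled contrast
  open_f <- pe$peak_id[pe$effect == "opening" & pe$sex_specificity == "F"]
  if (length(open_f) >= 10) {
    expect_lt(median(log2(rowMeans(cpm[open_f, cent]) /
                            rowMeans(cpm[open_f, !cent]))), med)
  }
})

test_that("counts follow the stated NB mean-variance relationship", {
  co <- simulate_cohort(
    sim_config(n_control = 40, n_centenarian = 5, n_peaks = 1500,
               n_genes = 300, dispersion = 0.2,
               lib_size_range = c(2e7, 2e7), seed = 23))
  ctrl <- co$sample_sheet$group == "control"
  m <- co$atac_counts[, ctrl]
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu > 20  # moment estimates need signal
  alpha_hat <- (v[keep] - mu[keep]) / mu[keep]^2
  expect_gt(median(alpha_hat), 0.1)
  expect_lt(median(alpha_hat), 0.3)
})

test_that("simulated peak calls jitter, drop and threshold as configured", {
  co <- shared_cohort()
  exact <- simulate_peak_calls(co, jitter = 0, drop_prob = 0,
                               q_pass_rate = 1)
  expect_length(exact, nrow(co$sample_sheet))
  one <- exact[[1]]
  expect_length(one, length(co$peaks))
  expect_equal(GenomicRanges::start(one), GenomicRanges::start(co$peaks))
  expect_equal(GenomicRanges::end(one), GenomicRanges::end(co$peaks))
  expect_true(all(S4Vectors::mcols(one)$q <= 0.01))

  # q_pass_rate controls the fraction passing the 1% threshold
  half <- simulate_peak_calls(co, jitter = 0, drop_prob = 0,
                              q_pass_rate = 0.5)
  qs <- unlist(lapply(half, function(g) S4Vectors::mcols(g)$q))
  expect_equal(mean(qs <= 0.01), 0.5, tolerance = 0.05)

  # heavy dropout still leaves every peak represented somewhere
  sparse <- simulate_peak_calls(co, drop_prob = 0.35)
  seen <- unique(unlist(lapply(sparse, function(g)
    S4Vectors::mcols(g)$name)))
  expect_setequal(seen, S4Vectors::mcols(co$peaks)$name)
})

test_that("sequences match peak widths and carry the planted instances", {
  co <- shared_cohort()
  sq <- simulate_sequences(co)
  seqs <- as.character(sq$sequences)
  expect_identical(names(seqs), S4Vectors::mcols(co$peaks)$name)
  expect_equal(unname(nchar(seqs)), GenomicRanges::width(co$peaks))
  # every recorded plant is literally present at its offset
  cons <- c(LTF1 = co$motifs$planted$consensus,
            DTF1 = co$motifs$decoy$consensus)
  for (i in seq_len(nrow(sq$plants))) {
    p <- sq$plants[i, ]
    sub <- substr(seqs[p$peak_id], p$offset + 1,
                  p$offset + nchar(cons[p$motif]))
    expect_equal(unname(sub), unname(cons[p$motif]))
  }
  # plant rates: high near opening summits, low elsewhere
  pe <- co$truth$peak_effects
  open_ids <- pe$peak_id[pe$effect == "opening"]
  none_ids <- pe$peak_id[pe$effect == "none"]
  ltf <- sq$plants$peak_id[sq$plants$motif == "LTF1"]
  expect_gt(mean(open_ids %in% ltf), 0.2)
  expect_lt(mean(none_ids %in% ltf), 0.15)
  # planted instances sit near opening-peak summits
  op <- sq$plants[sq$plants$motif == "LTF1" &
                    sq$plants$peak_id %in% open_ids, ]
  summits <- setNames(S4Vectors::mcols(co$peaks)$summit_offset,
                      S4Vectors::mcols(co$peaks)$name)
  centers <- op$offset + 4 - summits[op$peak_id]
  expect_lt(median(abs(centers)), 60)
})

test_that("write_cohort emits a complete, re-readable input directory", {
  dir <- shared_cohort_dir()
  co <- shared_cohort()
  need <- c("sample_sheet.tsv", "atac_counts.tsv", "rna_counts.tsv",
            "true_peaks.bed", "blacklist.bed", "tss.bed",
            "gene_bodies.bed", "peaks.fa", "motif.pfm",
            "tf_gene_map.tsv", "truth_peaks.tsv", "truth_genes.tsv",
            "truth_states.tsv", "truth_tf.tsv", "truth_plants.tsv")
  expect_true(all(file.exists(file.path(dir, need))))
  expect_length(list.files(dir, pattern = "^peaks_.*broadPeak$"),
                nrow(co$sample_sheet))
  expect_length(list.files(dir, pattern = "^states_.*bed$"),
                length(co$state_maps))

  counts <- read_counts_tsv(file.path(dir, "atac_counts.tsv"))
  expect_identical(counts, co$atac_counts)
  tss <- read_tss_bed(file.path(dir, "tss.bed"))
  expect_identical(S4Vectors::mcols(tss)$gene_id,
                   S4Vectors::mcols(co$tss)$gene_id)
  expect_equal(GenomicRanges::start(tss), GenomicRanges::start(co$tss))
  motifs <- read_jaspar_pfm(file.path(dir, "motif.pfm"))
  expect_setequal(names(motifs),
                  c("LTF1", "DTF1", names(default_database_motifs())))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "peaks.fa"))
  expect_identical(names(fa), S4Vectors::mcols(co$peaks)$name)
})
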