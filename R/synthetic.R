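# Synthetic cohort generator with machine-readable ground truth.
#
# Emulates the statistical structure of a case-control PBMC multi-omics
# cohort: two groups x two sexes, NB-distributed peak and gene counts with
# planted opening/closing/up/down effects (optionally sex-specific, as a
# group x sex interaction on the NB mean), per-sample jittered scored peak
# calls, cell-type chromatin-state segmentations, peak sequences with a
# planted "longevity TF" motif enriched near opening-peak summits, and a
# decoy TF whose motif occurs only at background rate. Every planted effect
# is recorded in a truth table that drives the recovery tests.

#' Configuration for the synthetic cohort
#'
#' Defaults define the generator's study conditions: 15 controls vs 15
#' centenarians with a balanced sex ratio, 5,000 peaks with 10% opening and
#' 5% closing at a mean log2 fold change of 1.5, NB dispersion 0.2,
#' log-uniform sequencing depths, and a planted TF motif at probability 0.4
#' in opening peaks versus 0.05 background.
#'
#' @param n_control,n_centenarian Samples per group.
#' @param sex_ratio Fraction of female samples within each group.
#' @param n_peaks Number of autosomal peaks (a further ~2% chrX decoy peaks
#'   are appended to exercise the autosome filter).
#' @param n_genes Number of genes (each gene's TSS sits under one peak's
#'   promoter; must not exceed `n_peaks`).
#' @param frac_opening,frac_closing Fractions of peaks with planted
#'   opening/closing effects (`frac_opening + frac_closing <= 1`).
#' @param frac_sex_specific Fraction of effect peaks whose effect is
#'   restricted to one sex (80% of those female, mirroring the
#'   female-dominant differential structure of such cohorts).
#' @param lfc_mean Mean planted |log2 fold change|.
#' @param dispersion NB dispersion alpha (`Var = mu + alpha mu^2`).
#' @param lib_size_range Sequencing-depth range (reads); depths are drawn
#'   log-uniformly.
#' @param motif_plant_prob_fg,motif_plant_prob_bg Probability of planting
#'   the TF consensus near the summit of opening peaks / elsewhere.
#' @param n_cell_types Number of chromatin-state segmentations.
#' @param chrom_sizes Optional named vector of chromosome sizes; computed
#'   from the layout when NULL.
#' @param seed Master seed; per-stage sub-seeds are derived by a stable
#'   hash of the stage name so outputs do not depend on call order.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_control = 15, n_centenarian = 15, sex_ratio = 0.5,
                       n_peaks = 5000, n_genes = 2000,
                       frac_opening = 0.10, frac_closing = 0.05,
                       frac_sex_specific = 0.20, lfc_mean = 1.5,
                       dispersion = 0.2, lib_size_range = c(1e7, 3e7),
                       motif_plant_prob_fg = 0.4, motif_plant_prob_bg = 0.05,
                       n_cell_types = 3, chrom_sizes = NULL, seed = 1) {
  cfg <- list(n_control = n_control, n_centenarian = n_centenarian,
              sex_ratio = sex_ratio, n_peaks = n_peaks, n_genes = n_genes,
              frac_opening = frac_opening, frac_closing = frac_closing,
              frac_sex_specific = frac_sex_specific, lfc_mean = lfc_mean,
              dispersion = dispersion, lib_size_range = lib_size_range,
              motif_plant_prob_fg = motif_plant_prob_fg,
              motif_plant_prob_bg = motif_plant_prob_bg,
              n_cell_types = n_cell_types, chrom_sizes = chrom_sizes,
              seed = as.integer(seed))
  if (n_control <= 0 || n_centenarian <= 0 || n_peaks <= 0 || n_genes <= 0 ||
      n_cell_types <= 0) {
    stop("cohort dimensions must be positive")
  }
  fr <- c(sex_ratio, frac_opening, frac_closing, frac_sex_specific,
          motif_plant_prob_fg, motif_plant_prob_bg)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (frac_opening + frac_closing > 1) {
    stop("frac_opening + frac_closing must not exceed 1")
  }
  if (n_genes > n_peaks) stop("n_genes must not exceed n_peaks")
  if (any(lib_size_range <= 0) || lib_size_range[1] > lib_size_range[2]) {
    stop("lib_size_range must be a positive increasing pair")
  }
  if (dispersion <= 0) stop("dispersion must be > 0")
  structure(cfg, class = "sim_config")
}

CELL_TYPE_NAMES <- c("pbmc", "tcell", "bcell", "nk", "monocyte", "plasma",
                     "dendritic", "hsc")

STATE_PROBS <- c("Quiescent/Low signal" = 0.35, "Transcription" = 0.10,
                 "Weak Enhancer" = 0.10, "Active Enhancer" = 0.10,
                 "TSS Flanking" = 0.08, "Genic Enhancer" = 0.05,
                 "Bivalent TSS" = 0.04, "Bivalent Enhancer" = 0.04,
                 "PolyComb repressed" = 0.06, "ZNF Genes and repeats" = 0.03,
                 "Heterochromatin" = 0.05)

# ETS-family-like core (planted longevity TF) and an unrelated decoy.
default_planted_motif <- function(name = "LTF1") {
  w <- 8
  pfm <- matrix(1, 4, w, dimnames = list(BASES, NULL))
  cons <- c("C", "C", "G", "G", "A", "A", "G", "T")
  for (i in seq_len(w)) pfm[cons[i], i] <- 37
  motif_model(name, pfm)
}

default_decoy_motif <- function(name = "DTF1") {
  w <- 8
  pfm <- matrix(1, 4, w, dimnames = list(BASES, NULL))
  cons <- c("T", "G", "A", "C", "G", "T", "C", "A")
  for (i in seq_len(w)) pfm[cons[i], i] <- 37
  motif_model(name, pfm)
}

#' Inert database motifs scanned alongside the planted and decoy TFs
#'
#' The scanned panel mimics a motif database: besides the planted and decoy
#' TFs it carries unrelated motifs that are never planted, so that the BH
#' correction across motifs operates over a realistic family. The consensus
#' 8-mers are mutually distinct including reverse complements and distinct
#' from the planted/decoy consensus.
#'
#' @return Named list of 14 [motif_model()] objects (`DBTF01`--`DBTF14`).
#' @export
default_database_motifs <- function() {
  cons <- c(DBTF01 = "AACCAGTG", DBTF02 = "AGGTCATT", DBTF03 = "CATGGCAA",
            DBTF04 = "CCATTGTC", DBTF05 = "CTAGAGGA", DBTF06 = "GAACTTGC",
            DBTF07 = "GATCCAGT", DBTF08 = "GGTATCAC", DBTF09 = "GTCAGGAT",
            DBTF10 = "TCCGATAC", DBTF11 = "TGGATAGC", DBTF12 = "TTCAGCGA",
            DBTF13 = "ACGATTGG", DBTF14 = "CAGTACGG")
  lapply(setNames(names(cons), names(cons)), function(nm) {
    b <- strsplit(cons[[nm]], "")[[1]]
    pfm <- matrix(1, 4, length(b), dimnames = list(BASES, NULL))
    for (i in seq_along(b)) pfm[b[i], i] <- 37
    motif_model(nm, pfm)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Generates the genome layout (peaks, genes, chromatin-state maps,
#' blacklist), plants effects, and draws NB peak and gene counts:
#' `counts ~ NB(mean = baseline_cpm * depth/1e6 * 2^(lfc * group [* sex
#' match]), alpha = dispersion)`. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort` list: `config`, `sample_sheet` (with
#'   per-assay sequencing depths), `peaks` (true intervals, `GRanges` with
#'   `name` and `summit_offset`), `tss`, `gene_bodies`, `atac_counts`,
#'   `rna_counts`, `state_maps`, `blacklist`, `motifs` (planted + decoy
#'   [motif_model()]s), `tf_gene_map`, and `truth` (`peak_effects`,
#'   `gene_effects`, `state_assignments`, `planted_tf`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  layout <- with_seed(stage_seed(config$seed, "layout"),
                      sim_layout(config))
  effects <- with_seed(stage_seed(config$seed, "effects"),
                       sim_effects(config, layout))
  sheet <- with_seed(stage_seed(config$seed, "samples"),
                     sim_samples(config))
  counts <- with_seed(stage_seed(config$seed, "counts"),
                      sim_counts(config, layout, effects, sheet))
  states <- with_seed(stage_seed(config$seed, "states"),
                      sim_states(config, layout))
  motifs <- list(planted = default_planted_motif(),
                 decoy = default_decoy_motif(),
                 database = default_database_motifs())
  tf_gene_map <- data.frame(
    tf = c(motifs$planted$name, motifs$decoy$name,
           vapply(motifs$database, function(m) m$name, character(1))),
    gene_id = c(effects$tf_gene, effects$decoy_gene, effects$db_genes),
    stringsAsFactors = FALSE)
  structure(list(
    config = config,
    sample_sheet = sheet,
    peaks = layout$peaks,
    tss = layout$tss,
    gene_bodies = layout$gene_bodies,
    atac_counts = counts$atac,
    rna_counts = counts$rna,
    state_maps = states$maps,
    blacklist = effects$blacklist,
    motifs = motifs,
    tf_gene_map = tf_gene_map,
    truth = list(
      peak_effects = effects$peak_effects,
      gene_effects = effects$gene_effects,
      state_assignments = states$assignments,
      planted_tf = list(tf_name = motifs$planted$name,
                        gene_id = effects$tf_gene,
                        decoy_name = motifs$decoy$name,
                        decoy_gene = effects$decoy_gene)
    )
  ), class = "synthetic_cohort")
}

# genome skeleton: peaks on 4 autosomes + chrX decoys, genes under peaks
sim_layout <- function(cfg) {
  n_auto <- 4L
  n_decoy <- max(2L, ceiling(0.02 * cfg$n_peaks))
  per_chrom <- diff(round(seq(0, cfg$n_peaks, length.out = n_auto + 1)))
  chroms <- c(rep(paste0("chr", seq_len(n_auto)), per_chrom),
              rep("chrX", n_decoy))
  n_tot <- cfg$n_peaks + n_decoy
  width <- round(runif(n_tot, 400, 700))
  gap <- round(runif(n_tot, 500, 3000))
  start <- integer(n_tot)
  pos <- setNames(rep(10000L, n_auto + 1L), c(paste0("chr", seq_len(n_auto)),
                                              "chrX"))
  for (i in seq_len(n_tot)) {
    ch <- chroms[i]
    start[i] <- pos[ch] + gap[i]
    pos[ch] <- start[i] + width[i]
  }
  ids <- sprintf("tpk_%05d", seq_len(n_tot))
  summit_offset <- pmin(width - 1L,
                        pmax(0L, round(width / 2 + rnorm(n_tot, 0, 40))))
  peaks <- GenomicRanges::GRanges(
    chroms, IRanges::IRanges(start + 1L, start + width),
    name = ids, summit_offset = as.integer(summit_offset))
  chrom_sizes <- cfg$chrom_sizes %||% (pos + 50000L)
  GenomeInfoDb::seqlengths(peaks) <- chrom_sizes[GenomeInfoDb::seqlevels(peaks)]

  # genes: gene i's TSS sits near the summit of autosomal peak i
  gi <- seq_len(cfg$n_genes)
  summit_pos <- start[gi] + summit_offset[gi] + 1L
  tss_pos <- summit_pos + sample(-300:300, cfg$n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gene_ids <- sprintf("gene_%05d", gi)
  tss <- GenomicRanges::GRanges(chroms[gi],
                                IRanges::IRanges(tss_pos, tss_pos),
                                strand = strand, gene_id = gene_ids)
  body_len <- round(runif(cfg$n_genes, 2000, 8000))
  bstart <- ifelse(strand == "+", tss_pos, pmax(1, tss_pos - body_len))
  bend <- ifelse(strand == "+", tss_pos + body_len, tss_pos)
  gene_bodies <- GenomicRanges::GRanges(chroms[gi],
                                        IRanges::IRanges(bstart, bend),
                                        strand = strand, gene_id = gene_ids)
  list(peaks = peaks, tss = tss, gene_bodies = gene_bodies,
       n_decoy = n_decoy, chrom_sizes = chrom_sizes)
}

sim_effects <- function(cfg, layout) {
  n <- cfg$n_peaks
  n_tot <- length(layout$peaks)
  ids <- S4Vectors::mcols(layout$peaks)$name
  effect <- rep("none", n_tot)
  lfc <- rep(0, n_tot)
  sexspec <- rep("all", n_tot)
  n_open <- round(cfg$frac_opening * n)
  n_close <- round(cfg$frac_closing * n)
  planted <- if (n_open + n_close > 0) {
    sample(seq_len(n), n_open + n_close)
  } else integer(0)
  open_idx <- head(planted, n_open)
  close_idx <- utils::tail(planted, n_close)
  effect[open_idx] <- "opening"
  effect[close_idx] <- "closing"
  lfc[open_idx] <- rnorm(n_open, cfg$lfc_mean, 0.1)
  lfc[close_idx] <- -rnorm(n_close, cfg$lfc_mean, 0.1)
  if (length(planted) && cfg$frac_sex_specific > 0) {
    n_ss <- round(cfg$frac_sex_specific * length(planted))
    ss <- sample(planted, n_ss)
    sexspec[ss] <- sample(c("F", "M"), n_ss, replace = TRUE,
                          prob = c(0.8, 0.2))
  }
  # gene effects mirror the promoter peak's effect with extra noise
  gidx <- seq_len(cfg$n_genes)
  g_eff <- rep("none", cfg$n_genes)
  g_lfc <- rep(0, cfg$n_genes)
  g_ss <- rep("all", cfg$n_genes)
  prom_open <- intersect(gidx, open_idx)
  prom_close <- intersect(gidx, close_idx)
  g_eff[prom_open] <- "up"
  g_eff[prom_close] <- "down"
  g_lfc[prom_open] <- lfc[prom_open] + rnorm(length(prom_open), 0, 0.2)
  g_lfc[prom_close] <- lfc[prom_close] + rnorm(length(prom_close), 0, 0.2)
  g_ss[c(prom_open, prom_close)] <- sexspec[c(prom_open, prom_close)]
  # keep planted gene effects past the calling threshold
  g_lfc[prom_open] <- pmax(g_lfc[prom_open], log2(1.5) + 0.35)
  g_lfc[prom_close] <- pmin(g_lfc[prom_close], -log2(1.5) - 0.35)

  # planted and decoy TF genes: upregulated in all strata, promoter peak
  # opening and not sex-specific
  gene_ids <- S4Vectors::mcols(layout$tss)$gene_id
  if (n_open > 0) {
    cand <- prom_open[sexspec[prom_open] == "all"]
    if (length(cand) < 2L) {
      # ensure the planted/decoy TF genes sit under opening promoter peaks
      need <- 2L - length(cand)
      extra <- head(setdiff(gidx, c(prom_open, prom_close)), need)
      effect[extra] <- "opening"
      lfc[extra] <- cfg$lfc_mean
      sexspec[extra] <- "all"
      g_eff[extra] <- "up"
      cand <- c(cand, extra)
    }
    tf_i <- cand[1]
    decoy_i <- cand[2]
    # four-fold: the TF-gene expression gate must hold in single-sex
    # strata, where se(log2fc) ~ sqrt(2 * alpha / n) ~ 0.4 at 8 vs 8
    g_lfc[c(tf_i, decoy_i)] <- max(cfg$lfc_mean, 2)
    g_ss[c(tf_i, decoy_i)] <- "all"
    tf_gene <- gene_ids[tf_i]
    decoy_gene <- gene_ids[decoy_i]
  } else {
    # null cohort: no longevity TF is planted
    tf_gene <- NA_character_
    decoy_gene <- NA_character_
  }

  # database TFs map to unaffected genes so their expression gate is 'ns'
  n_db <- length(default_database_motifs())
  db_cand <- which(g_eff == "none" & !(gene_ids %in% c(tf_gene, decoy_gene)))
  db_idx <- utils::tail(db_cand, n_db)
  db_genes <- rep(NA_character_, n_db)
  db_genes[seq_along(db_idx)] <- gene_ids[db_idx]

  # baseline accessibility (cpm scale) with low-support and artifact
  # classes; planted peaks keep ordinary baselines and stay off the
  # blacklist so recovery is attributable to the engine, not the filters
  base_cpm <- exp(rnorm(n_tot, log(3), 0.7))
  none_idx <- which(effect[seq_len(n)] == "none")
  low <- sample(none_idx, round(0.02 * n))
  base_cpm[low] <- runif(length(low), 0.02, 0.08)
  rest <- setdiff(none_idx, low)
  art <- sample(rest, max(1, round(0.004 * n)))
  base_cpm[art] <- runif(length(art), 900, 1600)
  rest <- setdiff(rest, art)
  bl <- sample(rest, max(1, round(0.005 * n)))
  blacklist <- granges_strip(layout$peaks[bl])

  list(
    peak_effects = data.frame(peak_id = ids, effect = effect, lfc = lfc,
                              sex_specificity = sexspec,
                              base_cpm = base_cpm,
                              stringsAsFactors = FALSE),
    gene_effects = data.frame(gene_id = gene_ids, effect = g_eff,
                              lfc = g_lfc, sex_specificity = g_ss,
                              base_cpm = exp(rnorm(cfg$n_genes, log(20), 1)),
                              stringsAsFactors = FALSE),
    blacklist = blacklist,
    tf_gene = tf_gene,
    decoy_gene = decoy_gene,
    db_genes = db_genes
  )
}

sim_samples <- function(cfg) {
  mk <- function(n, grp, prefix) {
    n_f <- round(cfg$sex_ratio * n)
    data.frame(sample_id = sprintf("%s_%02d", prefix, seq_len(n)),
               group = grp,
               sex = c(rep("F", n_f), rep("M", n - n_f)),
               stringsAsFactors = FALSE)
  }
  sheet <- rbind(mk(cfg$n_control, "control", "ctrl"),
                 mk(cfg$n_centenarian, "centenarian", "cent"))
  r <- log(cfg$lib_size_range)
  sheet$lib_size_atac <- round(exp(runif(nrow(sheet), r[1], r[2])))
  sheet$lib_size_rna <- round(exp(runif(nrow(sheet), r[1], r[2])))
  sheet
}

nb_count_matrix <- function(base_cpm, lfc, sexspec, sheet, depths, alpha,
                            ids) {
  n_s <- nrow(sheet)
  is_cent <- sheet$group == "centenarian"
  mu <- outer(base_cpm, depths / 1e6)
  for (j in which(is_cent)) {
    match_sex <- sexspec == "all" | sexspec == sheet$sex[j]
    mu[, j] <- mu[, j] * 2^(lfc * match_sex)
  }
  m <- matrix(rnbinom(length(mu), size = 1 / alpha, mu = mu),
              nrow = nrow(mu),
              dimnames = list(ids, sheet$sample_id))
  m
}

sim_counts <- function(cfg, layout, effects, sheet) {
  pe <- effects$peak_effects
  ge <- effects$gene_effects
  list(
    atac = nb_count_matrix(pe$base_cpm, pe$lfc, pe$sex_specificity, sheet,
                           sheet$lib_size_atac, cfg$dispersion, pe$peak_id),
    rna = nb_count_matrix(ge$base_cpm, ge$lfc, ge$sex_specificity, sheet,
                          sheet$lib_size_rna, cfg$dispersion, ge$gene_id)
  )
}

# per-cell-type segmentations tiling each chromosome; each peak falls in
# exactly one segment whose state is recorded in the truth table
sim_states <- function(cfg, layout) {
  peaks <- layout$peaks
  ids <- S4Vectors::mcols(peaks)$name
  n_tot <- length(peaks)
  cts <- CELL_TYPE_NAMES[seq_len(min(cfg$n_cell_types,
                                     length(CELL_TYPE_NAMES)))]
  # ~5% of peaks are active in exactly one cell type by construction
  spec_idx <- sample(seq_len(n_tot), round(0.05 * n_tot))
  spec_ct <- sample(cts, length(spec_idx), replace = TRUE)
  maps <- list()
  assignments <- list()
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  sizes <- layout$chrom_sizes
  for (ct in cts) {
    st <- sample(names(STATE_PROBS), n_tot, replace = TRUE,
                 prob = STATE_PROBS)
    st[spec_idx] <- ifelse(spec_ct == ct, "Active Enhancer",
                           "Quiescent/Low signal")
    segs <- list()
    for (ch in unique(chrom)) {
      w <- which(chrom == ch)
      s <- GenomicRanges::start(peaks)[w]
      e <- GenomicRanges::end(peaks)[w]
      bounds <- c(1L, floor((e[-length(w)] + s[-1]) / 2), sizes[[ch]])
      seg_start <- bounds[-length(bounds)]
      seg_end <- bounds[-1] - 1L
      seg_end[length(seg_end)] <- sizes[[ch]]
      segs[[ch]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(seg_start, seg_end), name = st[w])
    }
    maps[[ct]] <- sort(suppressWarnings(do.call(c, unname(segs))))
    assignments[[ct]] <- data.frame(cell_type = ct, peak_id = ids,
                                    state = st, stringsAsFactors = FALSE)
  }
  list(maps = maps, assignments = do.call(rbind, assignments))
}

#' Simulate per-sample scored peak calls
#'
#' Each sample's call set contains each true peak with probability
#' `1 - drop_prob`, with boundaries jittered by a Gaussian of SD `jitter`
#' bp; peaks dropped everywhere are forced into one random sample so that
#' every true peak appears at least once. Peak q-values fall at or below
#' 0.01 with probability `q_pass_rate` and are otherwise drawn above it.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param jitter Boundary jitter SD in bp (0 reproduces the true
#'   intervals exactly).
#' @param drop_prob Per-sample probability of missing a true peak.
#' @param q_pass_rate Fraction of calls with q-value <= 0.01.
#' @return Named list (one `GRanges` per sample) with metadata columns
#'   `name` (the true peak id), `q` and `signalValue`.
#' @export
simulate_peak_calls <- function(cohort, jitter = 25, drop_prob = 0.1,
                                q_pass_rate = 0.9) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  with_seed(stage_seed(cohort$config$seed, "peak_calls"), {
    peaks <- cohort$peaks
    ids <- S4Vectors::mcols(peaks)$name
    n <- length(peaks)
    samples <- cohort$sample_sheet$sample_id
    present <- matrix(runif(n * length(samples)) >= drop_prob, nrow = n)
    lost <- which(rowSums(present) == 0L)
    for (i in lost) present[i, sample.int(length(samples), 1)] <- TRUE
    out <- list()
    for (j in seq_along(samples)) {
      idx <- which(present[, j])
      s0 <- GenomicRanges::start(peaks)[idx]
      e0 <- GenomicRanges::end(peaks)[idx]
      if (jitter > 0) {
        s <- s0 + round(rnorm(length(idx), 0, jitter))
        e <- e0 + round(rnorm(length(idx), 0, jitter))
      } else {
        s <- s0; e <- e0
      }
      s <- pmax(1L, as.integer(s))
      e <- pmax(s, as.integer(e))
      pass <- runif(length(idx)) < q_pass_rate
      q <- ifelse(pass, runif(length(idx), 1e-8, 0.01),
                  runif(length(idx), 0.0100001, 1))
      out[[samples[j]]] <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(peaks)[idx], IRanges::IRanges(s, e),
        name = ids[idx], q = q,
        signalValue = round(runif(length(idx), 1, 50), 2))
    }
    out
  })
}

#' Simulate peak sequences with planted motif instances
#'
#' Background bases are i.i.d. uniform over ACGT. The planted TF's
#' consensus is inserted near the summit of opening peaks with probability
#' `motif_plant_prob_fg` (background probability elsewhere); the decoy TF's
#' consensus is planted at background probability everywhere. Plant
#' positions are returned for the truth table.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return List: `sequences` (a `DNAStringSet` named by peak id, lengths
#'   equal to the peak widths) and `plants` (data.frame `peak_id`, `motif`,
#'   `offset` of each inserted instance, 0-based).
#' @export
simulate_sequences <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$config
  with_seed(stage_seed(cfg$seed, "sequences"), {
    peaks <- cohort$peaks
    ids <- S4Vectors::mcols(peaks)$name
    widths <- GenomicRanges::width(peaks)
    summit <- S4Vectors::mcols(peaks)$summit_offset
    eff <- cohort$truth$peak_effects$effect[
      match(ids, cohort$truth$peak_effects$peak_id)]
    planted <- cohort$motifs$planted
    decoy <- cohort$motifs$decoy
    if (any(widths < planted$width) || any(widths < decoy$width)) {
      stop("motif longer than a peak sequence")
    }
    seqs <- character(length(peaks))
    plants <- list()
    for (i in seq_along(peaks)) {
      L <- widths[i]
      chars <- sample(BASES, L, replace = TRUE)
      p_fg <- if (identical(eff[i], "opening")) cfg$motif_plant_prob_fg else
        cfg$motif_plant_prob_bg
      if (runif(1) < cfg$motif_plant_prob_bg) {
        off <- sample.int(L - decoy$width + 1L, 1) - 1L
        chars[(off + 1):(off + decoy$width)] <-
          strsplit(decoy$consensus, "")[[1]]
        plants[[length(plants) + 1L]] <- data.frame(
          peak_id = ids[i], motif = decoy$name, offset = off,
          stringsAsFactors = FALSE)
      }
      if (runif(1) < p_fg) {
        center <- summit[i] + round(rnorm(1, 0, 20))
        off <- center - floor(planted$width / 2)
        off <- min(max(off, 0L), L - planted$width)
        chars[(off + 1):(off + planted$width)] <-
          strsplit(planted$consensus, "")[[1]]
        plants[[length(plants) + 1L]] <- data.frame(
          peak_id = ids[i], motif = planted$name, offset = off,
          stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    plants <- if (length(plants)) do.call(rbind, plants) else
      data.frame(peak_id = character(), motif = character(),
                 offset = integer(), stringsAsFactors = FALSE)
    list(sequences = Biostrings::DNAStringSet(setNames(seqs, ids)),
         plants = plants)
  })
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits `sample_sheet.tsv`, `atac_counts.tsv`, `rna_counts.tsv`, one
#' `peaks_<sample>.broadPeak` per sample, `true_peaks.bed` (peak-id to
#' coordinate map used to attach counts to consensus peaks),
#' `states_<celltype>.bed`, `blacklist.bed`, `tss.bed`, `gene_bodies.bed`,
#' `peaks.fa`, `motif.pfm` (JASPAR counts, planted + decoy),
#' `tf_gene_map.tsv` and the truth tables (`truth_peaks.tsv`,
#' `truth_genes.tsv`, `truth_states.tsv`, `truth_tf.tsv`,
#' `truth_plants.tsv`).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param jitter,drop_prob,q_pass_rate Passed to [simulate_peak_calls()].
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, jitter = 25, drop_prob = 0.1,
                         q_pass_rate = 0.9) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_tsv(cohort$sample_sheet, fp("sample_sheet.tsv"))
  write_counts_tsv(cohort$atac_counts, fp("atac_counts.tsv"), "peak_id")
  write_counts_tsv(cohort$rna_counts, fp("rna_counts.tsv"), "gene_id")
  calls <- simulate_peak_calls(cohort, jitter, drop_prob, q_pass_rate)
  for (s in names(calls)) {
    write_broadpeak(calls[[s]], fp(paste0("peaks_", s, ".broadPeak")))
  }
  write_bed(cohort$peaks, fp("true_peaks.bed"))
  for (ct in names(cohort$state_maps)) {
    write_bed(cohort$state_maps[[ct]], fp(paste0("states_", ct, ".bed")))
  }
  write_bed(cohort$blacklist, fp("blacklist.bed"))
  tss_out <- cohort$tss
  S4Vectors::mcols(tss_out) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(cohort$tss)$gene_id)
  write_bed(tss_out, fp("tss.bed"))
  bodies_out <- cohort$gene_bodies
  S4Vectors::mcols(bodies_out) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(cohort$gene_bodies)$gene_id)
  write_bed(bodies_out, fp("gene_bodies.bed"))
  seqres <- simulate_sequences(cohort)
  Biostrings::writeXStringSet(seqres$sequences, fp("peaks.fa"))
  write_jaspar_pfm(cohort$motifs$planted, fp("motif.pfm"))
  write_jaspar_pfm(cohort$motifs$decoy, fp("motif.pfm"), append = TRUE)
  for (m in cohort$motifs$database) {
    write_jaspar_pfm(m, fp("motif.pfm"), append = TRUE)
  }
  write_tsv(cohort$tf_gene_map, fp("tf_gene_map.tsv"))
  write_tsv(cohort$truth$peak_effects, fp("truth_peaks.tsv"))
  write_tsv(cohort$truth$gene_effects, fp("truth_genes.tsv"))
  write_tsv(cohort$truth$state_assignments, fp("truth_states.tsv"))
  write_tsv(data.frame(tf = c(cohort$truth$planted_tf$tf_name,
                              cohort$truth$planted_tf$decoy_name),
                       gene_id = c(cohort$truth$planted_tf$gene_id,
                                   cohort$truth$planted_tf$decoy_gene),
                       role = c("planted", "decoy"),
                       stringsAsFactors = FALSE),
            fp("truth_tf.tsv"))
  write_tsv(seqres$plants, fp("truth_plants.tsv"))
  invisible(dir)
}
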