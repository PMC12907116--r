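# Pipeline orchestration: consensus -> differential (all/female/male) ->
# annotation -> integration -> motif enrichment -> TF nomination, from the
# plain-text inputs emitted by `write_cohort()` (or equivalently formatted
# real data).

#' Pipeline configuration
#'
#' File locations default to the layout written by [write_cohort()]; any
#' path can be overridden. Thresholds default to the study rules: q <= 1%
#' for per-sample peaks, support > 20 reads, CPM <= 500, blacklist and
#' autosome filters, padj < 0.05 with |FC| > 1.5 calling, +-1,000 bp
#' promoter pairing, summit +-200 bp motif windows.
#'
#' @param input_dir Directory holding the cohort files.
#' @param sample_sheet,atac_counts,rna_counts,true_peaks,blacklist,tss,
#'   gene_bodies,fasta,pfm,tf_gene_map Individual path overrides.
#' @param peak_files Named character vector of per-sample peak-call files
#'   (names = sample ids); discovered from `peaks_<sample>.broadPeak` when
#'   NULL.
#' @param state_files Named character vector of segmentation BEDs (names =
#'   cell types); discovered from `states_<celltype>.bed` when NULL.
#' @param q_max,min_reads,max_cpm,padj_max,fc_min Filtering and calling
#'   thresholds.
#' @param min_score_frac PWM scan threshold as a fraction of the maximum
#'   score.
#' @param summit_window Motif-enrichment half-window around summits (bp).
#' @param promoter_flank Promoter pairing half-width (bp).
#' @param positional_flank Positional "promoter" half-width (bp).
#' @param autosomes Allowed chromosomes for the consensus filter.
#' @param strata Subset of `c("all", "female", "male")` to run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir,
                            sample_sheet = file.path(input_dir, "sample_sheet.tsv"),
                            atac_counts = file.path(input_dir, "atac_counts.tsv"),
                            rna_counts = file.path(input_dir, "rna_counts.tsv"),
                            true_peaks = file.path(input_dir, "true_peaks.bed"),
                            blacklist = file.path(input_dir, "blacklist.bed"),
                            tss = file.path(input_dir, "tss.bed"),
                            gene_bodies = file.path(input_dir, "gene_bodies.bed"),
                            fasta = file.path(input_dir, "peaks.fa"),
                            pfm = file.path(input_dir, "motif.pfm"),
                            tf_gene_map = file.path(input_dir, "tf_gene_map.tsv"),
                            peak_files = NULL, state_files = NULL,
                            q_max = 0.01, min_reads = 20, max_cpm = 500,
                            padj_max = 0.05, fc_min = 1.5,
                            min_score_frac = 0.8, summit_window = 200,
                            promoter_flank = 1000, positional_flank = 2000,
                            autosomes = paste0("chr", 1:22),
                            strata = c("all", "female", "male")) {
  if (is.null(peak_files)) {
    f <- list.files(input_dir, "^peaks_.*\\.broadPeak$", full.names = TRUE)
    names(f) <- sub("^peaks_(.*)\\.broadPeak$", "\\1", basename(f))
    peak_files <- f
  }
  if (is.null(state_files)) {
    f <- list.files(input_dir, "^states_.*\\.bed$", full.names = TRUE)
    names(f) <- sub("^states_(.*)\\.bed$", "\\1", basename(f))
    state_files <- f
  }
  strata <- match.arg(strata, c("all", "female", "male"), several.ok = TRUE)
  cfg <- list(sample_sheet = sample_sheet, atac_counts = atac_counts,
              rna_counts = rna_counts, true_peaks = true_peaks,
              blacklist = blacklist, tss = tss, gene_bodies = gene_bodies,
              fasta = fasta, pfm = pfm, tf_gene_map = tf_gene_map,
              peak_files = peak_files, state_files = state_files,
              q_max = q_max, min_reads = min_reads, max_cpm = max_cpm,
              padj_max = padj_max, fc_min = fc_min,
              min_score_frac = min_score_frac,
              summit_window = summit_window,
              promoter_flank = promoter_flank,
              positional_flank = positional_flank,
              autosomes = autosomes, strata = strata)
  needed <- c(sample_sheet, atac_counts, rna_counts, true_peaks, tss,
              unname(peak_files))
  miss <- needed[!file.exists(needed)]
  if (length(miss)) stop("missing input file(s): ",
                         paste(miss, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

# sum the count rows of source peaks overlapping each target peak
aggregate_counts_by_overlap <- function(target, source, counts) {
  hits <- GenomicRanges::findOverlaps(target, source)
  src_ids <- S4Vectors::mcols(source)$name
  m <- matrix(0, nrow = length(target), ncol = ncol(counts),
              dimnames = list(S4Vectors::mcols(target)$name,
                              colnames(counts)))
  qh <- S4Vectors::queryHits(hits)
  rows <- match(src_ids[S4Vectors::subjectHits(hits)], rownames(counts))
  ok <- !is.na(rows)
  for (k in which(ok)) {
    m[qh[k], ] <- m[qh[k], ] + counts[rows[k], ]
  }
  m
}

# the single source peak with the largest overlap per target peak (for
# attaching representative sequences)
best_overlap_map <- function(target, source) {
  hits <- GenomicRanges::findOverlaps(target, source)
  if (!length(hits)) return(setNames(character(0), character(0)))
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    target[S4Vectors::queryHits(hits)],
    source[S4Vectors::subjectHits(hits)]))
  df <- data.frame(q = S4Vectors::queryHits(hits),
                   s = S4Vectors::subjectHits(hits), ov = ov)
  df <- df[order(df$q, -df$ov), ]
  df <- df[!duplicated(df$q), ]
  setNames(S4Vectors::mcols(source)$name[df$s],
           S4Vectors::mcols(target)$name[df$q])
}

stratum_subset <- function(sheet, stratum) {
  switch(stratum,
         all = sheet,
         female = sheet[sheet$sex == "F", , drop = FALSE],
         male = sheet[sheet$sex == "M", , drop = FALSE],
         stop("unknown stratum: ", stratum))
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order: consensus construction and
#' filtering, per-stratum NB Wald differential testing of peaks and genes
#' (the `all` stratum uses a sex covariate, single-sex strata a group-only
#' design), chromatin-state and positional annotation, promoter
#' peak-to-gene pairing with fold-change correlation, per-stratum motif
#' enrichment in opening/closing peaks, TF nomination and target
#' assignment. Results are written as TSVs when `out_dir` is given.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for stage TSVs and the summary.
#' @param verbose Log stage progress to stderr (default TRUE).
#' @return A `pipeline_result` list: `consensus`, `filtered_peaks`,
#'   `filter_report`, `diff_atac` and `diff_rna` (one data.frame per
#'   stratum), `annotations`, `cell_specific`, `positional`, `pairs`,
#'   `correlation`, `enrichment` (per stratum, opening/closing),
#'   `nominations`, `targets` (per nominated TF), and `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[longacc] ", ...)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    v <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say(sprintf("%-12s %6.1fs", name,
                as.numeric(difftime(Sys.time(), s, units = "secs"))))
    v
  }

  sheet <- read.delim(config$sample_sheet, stringsAsFactors = FALSE)
  calls <- stage("peak calls", lapply(config$peak_files, read_broadpeak))
  consensus <- stage("consensus", build_consensus(calls, config$q_max))

  true_peaks <- read_bed(config$true_peaks)
  atac_raw <- read_counts_tsv(config$atac_counts)
  atac_raw <- atac_raw[, sheet$sample_id, drop = FALSE]
  counts <- stage("counts", aggregate_counts_by_overlap(
    consensus, true_peaks, atac_raw))

  blk <- if (file.exists(config$blacklist)) read_bed(config$blacklist) else
    GenomicRanges::GRanges()
  lib_sizes <- if ("lib_size_atac" %in% names(sheet)) {
    setNames(sheet$lib_size_atac, sheet$sample_id)[colnames(counts)]
  } else colSums(counts)
  filt_rep <- stage("filter", filter_consensus_report(
    consensus, counts, blk, config$min_reads, config$max_cpm,
    config$autosomes, lib_sizes))
  filtered <- consensus[filt_rep$keep]
  fcounts <- counts[filt_rep$keep, , drop = FALSE]

  rna <- read_counts_tsv(config$rna_counts)
  rna <- rna[, sheet$sample_id, drop = FALSE]
  diff_atac <- list()
  diff_rna <- list()
  for (st in config$strata) {
    sub <- stratum_subset(sheet, st)
    inc_sex <- st == "all"
    diff_atac[[st]] <- stage(paste0("diff atac/", st), differential_test(
      fcounts[, sub$sample_id, drop = FALSE], sub, include_sex = inc_sex,
      padj_max = config$padj_max, fc_min = config$fc_min,
      labels = c("opening", "closing")))
    diff_rna[[st]] <- stage(paste0("diff rna/", st), differential_test(
      rna[, sub$sample_id, drop = FALSE], sub, include_sex = inc_sex,
      padj_max = config$padj_max, fc_min = config$fc_min,
      labels = c("up", "down")))
  }

  vocab <- state_vocabulary()
  state_maps <- lapply(config$state_files, read_bed)
  anns <- stage("annotation", annotate_states(filtered, state_maps, vocab))
  cellspec <- label_cell_specific(anns)
  tss <- read_tss_bed(config$tss)
  bodies <- if (file.exists(config$gene_bodies)) {
    read_bed(config$gene_bodies)
  } else GenomicRanges::GRanges()
  positional <- stage("positional", positional_annotate(
    filtered, tss, bodies, config$positional_flank))

  pairs <- stage("integration", pair_promoter_genes(
    filtered, tss, config$promoter_flank))
  correlation <- correlate_lfc(pairs, diff_atac[["all"]] %||%
                                 diff_atac[[1]],
                               diff_rna[["all"]] %||% diff_rna[[1]])

  seqs <- Biostrings::readDNAStringSet(config$fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  motifs <- read_jaspar_pfm(config$pfm)
  seq_map <- best_overlap_map(filtered, true_peaks)
  cons_seqs <- seqs[seq_map[S4Vectors::mcols(filtered)$name]]
  names(cons_seqs) <- S4Vectors::mcols(filtered)$name

  # scan each motif once over the consensus sequences; every stratum x side
  # enrichment and the target assignment reuse the cached hits
  summit_off <- setNames(floor(Biostrings::width(cons_seqs) / 2),
                         names(cons_seqs))
  hits_by_motif <- stage("motif scan", lapply(
    motifs, function(m) scan_peaks(cons_seqs, m, config$min_score_frac)))
  carriers <- lapply(names(motifs), function(nm) {
    peaks_with_summit_hit(hits_by_motif[[nm]], motifs[[nm]]$width,
                          summit_off, config$summit_window)
  })
  names(carriers) <- names(motifs)

  enr <- list()
  for (st in names(diff_atac)) {
    res <- diff_atac[[st]]
    enr[[st]] <- list()
    for (side in c("opening", "closing")) {
      fg <- res$feature_id[res$call == side]
      bg <- res$feature_id[res$call == "ns"]
      enr[[st]][[side]] <- if (length(fg)) {
        enrich_from_carriers(fg, bg, carriers)
      } else NULL
    }
  }
  say("motif enrichment done")

  tfmap <- read.delim(config$tf_gene_map, stringsAsFactors = FALSE)
  nominations <- stage("nomination", nominate_tfs(enr, diff_rna, tfmap,
                                                  config$padj_max))

  targets <- list()
  if (nrow(nominations)) {
    de_all <- diff_rna[["all"]] %||% diff_rna[[1]]
    atac_all <- diff_atac[["all"]] %||% diff_atac[[1]]
    for (i in seq_len(nrow(nominations))) {
      tf <- nominations$tf[i]
      side <- if (nominations$direction[i] == "opening+up") "opening" else
        "closing"
      da_ids <- atac_all$feature_id[atac_all$call == side]
      da <- filtered[S4Vectors::mcols(filtered)$name %in% da_ids]
      hits <- hits_by_motif[[tf]]
      hits <- hits[hits$peak_id %in% S4Vectors::mcols(da)$name, ,
                   drop = FALSE]
      targets[[tf]] <- assign_tf_targets(da, hits, tss, de_all)
    }
  }

  summary <- pipeline_summary(diff_atac, diff_rna, anns, cellspec,
                              correlation, nominations)
  res <- structure(list(
    consensus = consensus, filtered_peaks = filtered,
    filter_report = filt_rep, counts = fcounts,
    diff_atac = diff_atac, diff_rna = diff_rna,
    annotations = anns, cell_specific = cellspec, positional = positional,
    pairs = pairs, correlation = correlation, enrichment = enr,
    nominations = nominations, targets = targets, summary = summary
  ), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  say(sprintf("total %.1fs", as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))))
  res
}

pipeline_summary <- function(diff_atac, diff_rna, anns, cellspec,
                             correlation, nominations) {
  n_call <- function(res, lab) sum(res$call == lab, na.rm = TRUE)
  rows <- list()
  for (st in names(diff_atac)) {
    rows[[st]] <- data.frame(
      stratum = st,
      da_opening = n_call(diff_atac[[st]], "opening"),
      da_closing = n_call(diff_atac[[st]], "closing"),
      de_up = n_call(diff_rna[[st]], "up"),
      de_down = n_call(diff_rna[[st]], "down"),
      stringsAsFactors = FALSE)
  }
  meta <- table(anns$meta)
  list(
    per_stratum = do.call(rbind, rows),
    meta_state_counts = as.data.frame(meta, stringsAsFactors = FALSE),
    n_cell_specific = sum(!is.na(cellspec$cell_type)),
    correlation_r = correlation$r,
    correlation_p = correlation$p,
    nominated_tfs = nominations$tf
  )
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  write_bed(res$consensus, fp("consensus.bed"))
  write_bed(res$filtered_peaks, fp("consensus_filtered.bed"))
  write_tsv(res$filter_report, fp("filter_report.tsv"))
  for (st in names(res$diff_atac)) {
    write_tsv(res$diff_atac[[st]], fp(paste0("diff_atac_", st, ".tsv")))
    write_tsv(res$diff_rna[[st]], fp(paste0("diff_rna_", st, ".tsv")))
  }
  write_tsv(res$annotations, fp("annotations.tsv"))
  write_tsv(res$cell_specific, fp("cell_specific.tsv"))
  write_tsv(res$positional, fp("positional.tsv"))
  write_tsv(res$pairs, fp("peak_gene_pairs.tsv"))
  for (st in names(res$enrichment)) {
    for (side in names(res$enrichment[[st]])) {
      e <- res$enrichment[[st]][[side]]
      if (!is.null(e)) {
        write_tsv(e, fp(paste0("motif_enrichment_", st, "_", side, ".tsv")))
      }
    }
  }
  write_tsv(res$nominations, fp("tf_nominations.tsv"))
  for (tf in names(res$targets)) {
    write_tsv(res$targets[[tf]], fp(paste0("tf_targets_", tf, ".tsv")))
  }
  s <- res$summary
  write_tsv(s$per_stratum, fp("summary_per_stratum.tsv"))
  lines <- c(sprintf("correlation_r\t%.6f", s$correlation_r),
             sprintf("correlation_p\t%.6g", s$correlation_p),
             sprintf("n_cell_specific\t%d", s$n_cell_specific),
             sprintf("nominated_tfs\t%s",
                     paste(s$nominated_tfs, collapse = ",")))
  writeLines(lines, fp("summary.tsv"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("longacc pipeline result\n")
  cat("  consensus peaks:", length(x$consensus),
      "(", length(x$filtered_peaks), "after filtering )\n")
  print(x$summary$per_stratum, row.names = FALSE)
  cat(sprintf("  promoter fold-change correlation: R = %.3f (n = %d)\n",
              x$correlation$r, x$correlation$n))
  cat("  nominated TFs:",
      if (nrow(x$nominations)) paste(x$nominations$tf, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
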