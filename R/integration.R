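# ATAC-RNA integration: peak-to-gene assignment and fold-change congruence.
#
# Promoter pairing uses a +-1,000 bp window around each TSS and retains all
# peak-gene pairs when a promoter peak overlaps several genes. Distal
# assignment follows the single-nearest-gene regulatory-domain model
# (proximal basal window 5 kb upstream / 1 kb downstream, distal cap
# 1,000 kb). Congruence is the Pearson correlation of peak and gene log2
# fold changes with the p-value from the linear-model slope t test.

#' Pair peaks with genes through promoter windows
#'
#' Emits a pair for every (peak, TSS) whose `+-flank` promoter window
#' overlaps the peak by at least 1 bp; one peak may yield several pairs.
#' `distance` is the signed, strand-aware distance from the TSS to the peak
#' edge nearest the TSS (negative upstream of the TSS, 0 when the peak
#' covers it).
#'
#' @param peaks Consensus `GRanges` with a `name` metadata column.
#' @param tss `GRanges` of single-bp TSS positions with `gene_id` metadata
#'   and strand (e.g. [read_tss_bed()]).
#' @param flank Promoter half-width in bp (default 1000).
#' @return Data.frame `peak_id`, `gene_id`, `rule` (= "promoter"),
#'   `distance`.
#' @export
pair_promoter_genes <- function(peaks, tss, flank = 1000) {
  stopifnot(length(tss) > 0)
  win <- GenomicRanges::resize(tss, width = 2 * flank + 1, fix = "center",
                               ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(peaks, win, minoverlap = 1L)
  if (!length(hits)) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      rule = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  tpos <- GenomicRanges::start(tss)[sh]
  s <- GenomicRanges::start(peaks)[qh]
  e <- GenomicRanges::end(peaks)[qh]
  # signed distance from TSS to the nearer peak edge; 0 when peak spans TSS
  d <- ifelse(e < tpos, e - tpos, ifelse(s > tpos, s - tpos, 0L))
  neg <- as.character(GenomicRanges::strand(tss))[sh] == "-"
  d[neg] <- -d[neg]
  data.frame(peak_id = S4Vectors::mcols(peaks)$name[qh],
             gene_id = S4Vectors::mcols(tss)$gene_id[sh],
             rule = "promoter",
             distance = as.integer(d),
             stringsAsFactors = FALSE)
}

#' Single-nearest-gene assignment with a regulatory-domain cap
#'
#' Each peak's midpoint is assigned to the gene with the nearest TSS. The
#' rule is `proximal` when the midpoint falls in the gene's strand-aware
#' basal window (`basal_up` upstream to `basal_down` downstream of the TSS),
#' `distal` when the nearest TSS is within `max_dist`, and no assignment
#' beyond that.
#'
#' @param peaks Consensus `GRanges` with a `name` metadata column.
#' @param tss TSS `GRanges` with `gene_id` and strand.
#' @param basal_up,basal_down Basal window extents in bp (defaults 5000 and
#'   1000).
#' @param max_dist Distal cap in bp (default 1e6).
#' @return Data.frame `peak_id`, `gene_id` (NA beyond the cap), `rule`
#'   (`proximal`/`distal`/NA), `distance` (signed, strand-aware midpoint -
#'   TSS).
#' @export
assign_nearest_gene <- function(peaks, tss, basal_up = 5000,
                                basal_down = 1000, max_dist = 1e6) {
  stopifnot(length(tss) > 0)
  mid <- GenomicRanges::start(peaks) +
    floor((GenomicRanges::width(peaks) - 1L) / 2L)
  pt <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                               IRanges::IRanges(mid, mid))
  nb <- GenomicRanges::nearest(pt, tss, ignore.strand = TRUE)
  gene <- rep(NA_character_, length(peaks))
  rule <- rep(NA_character_, length(peaks))
  dist <- rep(NA_integer_, length(peaks))
  ok <- which(!is.na(nb))
  if (length(ok)) {
    tpos <- GenomicRanges::start(tss)[nb[ok]]
    d <- mid[ok] - tpos
    neg <- as.character(GenomicRanges::strand(tss))[nb[ok]] == "-"
    d[neg] <- -d[neg]
    within <- abs(d) <= max_dist
    basal <- d >= -basal_up & d <= basal_down
    gene[ok[within]] <- S4Vectors::mcols(tss)$gene_id[nb[ok]][within]
    rule[ok[within]] <- ifelse(basal[within], "proximal", "distal")
    dist[ok] <- as.integer(d)
  }
  data.frame(peak_id = S4Vectors::mcols(peaks)$name,
             gene_id = gene, rule = rule, distance = dist,
             stringsAsFactors = FALSE)
}

#' Correlate accessibility and expression fold changes over peak-gene pairs
#'
#' Pearson correlation between peak and gene log2 fold changes; the p-value
#' comes from the t test on the slope of the linear regression of gene on
#' peak fold change. Duplicate pairs are deduplicated by (peak, gene);
#' optionally only the nearest pair per gene is kept.
#'
#' @param pairs Data.frame with `peak_id`, `gene_id` and optionally
#'   `distance` (needed for `collapse = "nearest_per_gene"`).
#' @param atac_results Differential results for peaks (`feature_id`,
#'   `log2fc`).
#' @param rna_results Differential results for genes (`feature_id`,
#'   `log2fc`).
#' @param collapse `"pair"` (default, dedup by peak-gene) or
#'   `"nearest_per_gene"`.
#' @return List of class `correlation_result`: `r`, `p` (NA when fewer than
#'   3 pairs), `n`, `slope`.
#' @export
correlate_lfc <- function(pairs, atac_results, rna_results,
                          collapse = c("pair", "nearest_per_gene")) {
  collapse <- match.arg(collapse)
  pairs <- unique(pairs[, intersect(c("peak_id", "gene_id", "distance"),
                                    names(pairs)), drop = FALSE])
  pairs <- pairs[!duplicated(pairs[, c("peak_id", "gene_id")]), , drop = FALSE]
  if (collapse == "nearest_per_gene") {
    if (is.null(pairs$distance)) stop("'distance' needed for nearest_per_gene")
    o <- order(pairs$gene_id, abs(pairs$distance))
    pairs <- pairs[o, ][!duplicated(pairs$gene_id[o]), , drop = FALSE]
  }
  x <- atac_results$log2fc[match(pairs$peak_id, atac_results$feature_id)]
  y <- rna_results$log2fc[match(pairs$gene_id, rna_results$feature_id)]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) {
    return(structure(list(r = NA_real_, p = NA_real_, n = n,
                          slope = NA_real_), class = "correlation_result"))
  }
  r <- cor(x, y)
  if (n >= 3L && stats::sd(x) > 0 && stats::sd(y) > 0) {
    fit <- summary(lm(y ~ x))
    p <- fit$coefficients["x", "Pr(>|t|)"]
    slope <- fit$coefficients["x", "Estimate"]
  } else {
    p <- NA_real_
    slope <- NA_real_
  }
  structure(list(r = r, p = p, n = n, slope = slope),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Fold-change correlation: R = %.4f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}
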