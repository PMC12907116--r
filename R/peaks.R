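# Consensus peak construction and filtering.
#
# Per-sample peak calls are thresholded on their q-value, pooled and merged
# into a non-overlapping consensus set, which is then filtered on read
# support, a CPM ceiling, blacklist overlap and chromosome.

#' Build a consensus peak set from per-sample scored peak calls
#'
#' Peaks with q-value at or below `q_max` are kept from each sample; the
#' survivors are pooled and merged so that overlapping or book-ended
#' intervals coalesce. The result is sorted and non-overlapping.
#'
#' @param peak_sets A list of `GRanges`, one per sample, each with a numeric
#'   `q` metadata column (q-values in `(0, 1]`), e.g. from [read_broadpeak()].
#' @param q_max Maximum q-value for a per-sample peak to enter the merge
#'   (default 0.01, i.e. a 1% peak score).
#' @return A sorted, non-overlapping `GRanges` with a `name` metadata column
#'   of zero-padded consensus ids (`peak_000001`, ...). Empty when no peak
#'   survives (with a warning).
#' @export
build_consensus <- function(peak_sets, q_max = 0.01) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  kept <- lapply(peak_sets, function(gr) {
    q <- S4Vectors::mcols(gr)$q
    if (is.null(q)) stop("each peak set needs a 'q' metadata column")
    gr[!is.na(q) & q <= q_max]
  })
  pooled <- suppressWarnings(do.call(c, unname(lapply(kept, granges_strip))))
  if (length(pooled) == 0L) {
    warning("no peaks pass q <= ", q_max, "; consensus set is empty")
    return(GenomicRanges::GRanges())
  }
  merged <- GenomicRanges::reduce(GenomicRanges::sort(pooled))
  S4Vectors::mcols(merged)$name <- sprintf("peak_%06d", seq_along(merged))
  merged
}

granges_strip <- function(gr) {
  gr2 <- GenomicRanges::granges(gr)
  GenomeInfoDb::seqlevels(gr2) <- GenomeInfoDb::seqlevelsInUse(gr2)
  gr2
}

#' Counts-per-million normalization
#'
#' `cpm[i, j] = counts[i, j] * 1e6 / lib_sizes[j]`.
#'
#' @param counts Non-negative count matrix, features x samples.
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return Matrix of CPM values with the same dimnames.
#' @export
compute_cpm <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2L, lib_sizes / 1e6, "/")
}

#' Filter a consensus peak set on support, CPM ceiling, blacklist, chromosome
#'
#' A peak is retained iff all of the following hold:
#' * its maximum raw count over samples is strictly greater than `min_reads`
#'   ("more than `min_reads` short reads in at least one sample");
#' * its maximum CPM over samples does not exceed `max_cpm` (inclusive);
#' * it overlaps no blacklisted region (>= 1 bp overlap excludes);
#' * its chromosome is in `autosomes`.
#'
#' @param peaks Consensus `GRanges` with a `name` metadata column.
#' @param counts Count matrix whose rownames cover `peaks`' names.
#' @param blacklist `GRanges` of blacklisted regions (may be empty).
#' @param min_reads Support threshold, strict (default 20).
#' @param max_cpm CPM ceiling, inclusive (default 500).
#' @param autosomes Character vector of allowed chromosome names
#'   (default `chr1`..`chr22`).
#' @param lib_sizes Per-sample library sizes for the CPM computation;
#'   defaults to the column sums of `counts`.
#' @return The retained subset of `peaks`, order preserved, with a
#'   `filter_reason` attribute-free design: use [filter_consensus_report()]
#'   for per-peak reasons.
#' @export
filter_consensus <- function(peaks, counts, blacklist = GenomicRanges::GRanges(),
                             min_reads = 20, max_cpm = 500,
                             autosomes = paste0("chr", 1:22),
                             lib_sizes = colSums(counts)) {
  rep <- filter_consensus_report(peaks, counts, blacklist, min_reads,
                                 max_cpm, autosomes, lib_sizes)
  peaks[rep$keep]
}

#' Per-peak filter report
#'
#' Same rules as [filter_consensus()] but returns, for every input peak,
#' which rules it fails. Useful for auditing exclusions.
#'
#' @inheritParams filter_consensus
#' @return A data.frame with columns `peak_id`, `keep` and one logical
#'   column per rule (`fail_support`, `fail_cpm`, `fail_blacklist`,
#'   `fail_chrom`).
#' @export
filter_consensus_report <- function(peaks, counts,
                                    blacklist = GenomicRanges::GRanges(),
                                    min_reads = 20, max_cpm = 500,
                                    autosomes = paste0("chr", 1:22),
                                    lib_sizes = colSums(counts)) {
  ids <- S4Vectors::mcols(peaks)$name
  if (is.null(ids)) stop("peaks need a 'name' metadata column")
  missing <- setdiff(ids, rownames(counts))
  if (length(missing)) {
    stop("no count row for peak(s): ", paste(head(missing, 5), collapse = ", "))
  }
  counts <- as.matrix(counts)[ids, , drop = FALSE]
  cpm <- compute_cpm(counts, lib_sizes)
  max_raw <- apply(counts, 1L, max)
  max_cpm_obs <- apply(cpm, 1L, max)
  fail_support <- !(max_raw > min_reads)
  fail_cpm <- !(max_cpm_obs <= max_cpm)
  fail_blacklist <- if (length(blacklist)) {
    GenomicRanges::countOverlaps(peaks, blacklist, minoverlap = 1L) > 0
  } else rep(FALSE, length(peaks))
  fail_chrom <- !(as.character(GenomeInfoDb::seqnames(peaks)) %in% autosomes)
  data.frame(
    peak_id = ids,
    keep = !(fail_support | fail_cpm | fail_blacklist | fail_chrom),
    fail_support = fail_support,
    fail_cpm = fail_cpm,
    fail_blacklist = fail_blacklist,
    fail_chrom = fail_chrom,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
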