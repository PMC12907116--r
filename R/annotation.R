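# Chromatin-state annotation of consensus peaks.
#
# Each peak is intersected with per-cell-type chromHMM-style segmentations;
# conflicts where several states overlap one peak are resolved by a fixed
# priority order; resolved states are pooled into 6 meta-states; peaks whose
# resolved state is an active promoter/enhancer state in exactly one cell
# type are labeled cell-specific.

#' Default chromatin-state vocabulary
#'
#' The 11 states in priority order (highest first) with their meta-state
#' pooling. `Genic Enhancer` pools into Enhancer and `TSS Flanking` into
#' TSS, following Roadmap naming conventions; both assignments are
#' overridable by supplying a custom vocabulary.
#'
#' @param states Optional character vector of state names in priority order.
#' @param meta_map Optional named character vector, state -> meta-state; the
#'   meta-states are `TSS`, `Enhancer`, `Repressed PolyComb`,
#'   `Transcription`, `Quiescent`, `Other`.
#' @return A `state_vocabulary` list with elements `priority` (states,
#'   highest priority first) and `meta_map`.
#' @export
state_vocabulary <- function(states = NULL, meta_map = NULL) {
  if (is.null(states)) {
    states <- c("Active Enhancer", "Genic Enhancer", "Bivalent TSS",
                "Weak Enhancer", "Bivalent Enhancer", "PolyComb repressed",
                "TSS Flanking", "Transcription", "ZNF Genes and repeats",
                "Heterochromatin", "Quiescent/Low signal")
  }
  if (is.null(meta_map)) {
    meta_map <- c(
      "Active Enhancer" = "Enhancer",
      "Genic Enhancer" = "Enhancer",
      "Bivalent TSS" = "TSS",
      "Weak Enhancer" = "Enhancer",
      "Bivalent Enhancer" = "Enhancer",
      "PolyComb repressed" = "Repressed PolyComb",
      "TSS Flanking" = "TSS",
      "Transcription" = "Transcription",
      "ZNF Genes and repeats" = "Other",
      "Heterochromatin" = "Other",
      "Quiescent/Low signal" = "Quiescent"
    )
  }
  if (anyDuplicated(states)) stop("duplicate state names")
  if (!all(states %in% names(meta_map))) {
    stop("meta_map must cover every state")
  }
  structure(list(priority = states, meta_map = meta_map[states]),
            class = "state_vocabulary")
}

#' Resolve overlapping chromatin states to a single annotation
#'
#' Returns the highest-priority member of `states` under the vocabulary's
#' total order.
#'
#' @param states Non-empty character vector (or set) of state names.
#' @param vocab A [state_vocabulary()].
#' @return Single state name.
#' @export
resolve_state <- function(states, vocab = state_vocabulary()) {
  states <- unique(as.character(states))
  if (!length(states)) stop("empty state set")
  unknown <- setdiff(states, vocab$priority)
  if (length(unknown)) {
    stop("unknown state name(s): ", paste(unknown, collapse = ", "))
  }
  vocab$priority[min(match(states, vocab$priority))]
}

#' Pool a state into its meta-state
#'
#' @param state State name in the vocabulary.
#' @param vocab A [state_vocabulary()].
#' @return Meta-state name (one of 6 over the default vocabulary).
#' @export
pool_meta <- function(state, vocab = state_vocabulary()) {
  if (!all(state %in% vocab$priority)) {
    stop("unknown state name(s): ",
         paste(setdiff(state, vocab$priority), collapse = ", "))
  }
  unname(vocab$meta_map[state])
}

#' Annotate peaks with a resolved chromatin state per cell type
#'
#' For every (peak, cell type), all states whose segments overlap the peak by
#' at least 1 bp are collected and resolved by priority; peaks with no
#' overlap default to `"Quiescent/Low signal"`. Segmentations must not
#' overlap internally within a cell type.
#'
#' @param peaks Consensus `GRanges` with a `name` metadata column.
#' @param state_maps Named list of segmentation `GRanges` (state name in the
#'   `name` metadata column), one element per cell type.
#' @param vocab A [state_vocabulary()].
#' @return Data.frame: `peak_id`, `cell_type`, `state`, `meta`.
#' @export
annotate_states <- function(peaks, state_maps, vocab = state_vocabulary()) {
  stopifnot(length(state_maps) >= 1, !is.null(names(state_maps)))
  ids <- S4Vectors::mcols(peaks)$name
  prio <- match(vocab$priority, vocab$priority)  # identity; for clarity
  out <- vector("list", length(state_maps))
  for (k in seq_along(state_maps)) {
    seg <- state_maps[[k]]
    ct <- names(state_maps)[k]
    if (!isDisjoint(seg)) {
      stop("segmentation for cell type '", ct, "' has overlapping intervals")
    }
    st <- S4Vectors::mcols(seg)$name
    unknown <- setdiff(unique(st), vocab$priority)
    if (length(unknown)) {
      stop("unknown state name(s) in '", ct, "': ",
           paste(unknown, collapse = ", "))
    }
    hits <- GenomicRanges::findOverlaps(peaks, seg, minoverlap = 1L)
    # resolve by priority: take the minimum priority rank among overlaps
    rank <- match(st, vocab$priority)
    best <- tapply(rank[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), min)
    state <- rep("Quiescent/Low signal", length(peaks))
    state[as.integer(names(best))] <- vocab$priority[best]
    out[[k]] <- data.frame(peak_id = ids, cell_type = ct, state = state,
                           meta = pool_meta(state, vocab),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default set of active promoter/enhancer states for specificity labeling
#' @param vocab A [state_vocabulary()].
#' @return Character vector of active state names present in the vocabulary.
#' @export
default_active_states <- function(vocab = state_vocabulary()) {
  intersect(c("Active TSS", "Active Enhancer", "Genic Enhancer",
              "TSS Flanking"), vocab$priority)
}

#' Label peaks active in exactly one cell type
#'
#' A peak is labeled specific to cell type `c` iff its resolved state is in
#' `active_states` in `c` and in no other cell type.
#'
#' @param annotations Output of [annotate_states()].
#' @param active_states States counted as active promoter/enhancer
#'   (default [default_active_states()]).
#' @return Data.frame `peak_id`, `cell_type` (NA when not specific), one row
#'   per peak.
#' @export
label_cell_specific <- function(annotations,
                                active_states = default_active_states()) {
  act <- annotations[annotations$state %in% active_states, , drop = FALSE]
  n_active <- table(act$peak_id)
  single <- names(n_active)[n_active == 1L]
  lab <- act[act$peak_id %in% single, c("peak_id", "cell_type")]
  all_ids <- unique(annotations$peak_id)
  out <- data.frame(peak_id = all_ids,
                    cell_type = NA_character_,
                    stringsAsFactors = FALSE)
  out$cell_type[match(lab$peak_id, out$peak_id)] <- lab$cell_type
  out
}

#' Positional annotation of peaks relative to TSS and gene bodies
#'
#' The peak summit (midpoint when no summit is recorded) is classified as
#' `promoter` when within `promoter_flank` bp of any TSS (inclusive), else
#' `genic` when the peak overlaps a gene body, else `intergenic`.
#'
#' @param peaks Consensus `GRanges` with a `name` column; an optional
#'   integer `summit_offset` metadata column gives the summit as bp from the
#'   peak start.
#' @param tss `GRanges` of single-bp TSS positions (e.g. [read_tss_bed()]).
#' @param gene_bodies `GRanges` of gene bodies (may be empty).
#' @param promoter_flank Promoter half-width in bp (default 2000).
#' @return Data.frame `peak_id`, `positional`, `dist_tss` (unsigned bp to
#'   the nearest TSS).
#' @export
positional_annotate <- function(peaks, tss,
                                gene_bodies = GenomicRanges::GRanges(),
                                promoter_flank = 2000) {
  stopifnot(length(tss) > 0)
  summit <- peak_summit_pos(peaks)
  pt <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                               IRanges::IRanges(summit, summit))
  nb <- GenomicRanges::nearest(pt, tss, ignore.strand = TRUE)
  dist <- abs(summit - GenomicRanges::start(tss)[nb])
  pos <- rep("intergenic", length(peaks))
  if (length(gene_bodies)) {
    genic <- GenomicRanges::countOverlaps(peaks, gene_bodies) > 0
    pos[genic] <- "genic"
  }
  pos[!is.na(dist) & dist <= promoter_flank] <- "promoter"
  data.frame(peak_id = S4Vectors::mcols(peaks)$name,
             positional = pos, dist_tss = dist,
             stringsAsFactors = FALSE)
}

# 1-based genomic position of the summit (or midpoint) of each peak
peak_summit_pos <- function(peaks) {
  off <- S4Vectors::mcols(peaks)$summit_offset
  s <- GenomicRanges::start(peaks)
  if (is.null(off)) {
    s + floor((GenomicRanges::width(peaks) - 1L) / 2L)
  } else {
    mid <- floor((GenomicRanges::width(peaks) - 1L) / 2L)
    off2 <- ifelse(is.na(off), mid, off)
    s + as.integer(off2)
  }
}
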