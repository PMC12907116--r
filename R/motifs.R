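# PWM motif scanning, differential-peak motif enrichment, occurrence and
# footprint profiles, and TF nomination by the motif-by-expression
# intersection.

BASES <- c("A", "C", "G", "T")

#' Construct a motif model from a position frequency matrix
#'
#' @param name TF/motif name.
#' @param pfm 4 x w non-negative count matrix with rows A, C, G, T.
#' @param background Background base frequencies (must sum to 1; default
#'   uniform).
#' @param pseudocount Pseudocount added per cell (default 0.25).
#' @return A `MotifModel` list: `name`, `pfm`, `background`, `pseudocount`,
#'   `width`, `consensus` (max-count base per column).
#' @export
motif_model <- function(name, pfm, background = rep(0.25, 4),
                        pseudocount = 0.25) {
  pfm <- as.matrix(pfm)
  if (is.null(rownames(pfm))) rownames(pfm) <- BASES
  stopifnot(nrow(pfm) == 4, all(rownames(pfm) == BASES))
  if (any(pfm < 0)) stop("negative counts in PFM")
  if (ncol(pfm) < 4) stop("motif width must be >= 4")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  structure(list(name = name, pfm = pfm, background = background,
                 pseudocount = pseudocount, width = ncol(pfm),
                 consensus = paste(BASES[apply(pfm, 2L, which.max)],
                                   collapse = "")),
            class = "MotifModel")
}

#' Convert a PFM to a log-odds PWM
#'
#' `pwm[b, i] = log2(((pfm[b, i] + pseudocount) / colsum_i) / background[b])`
#' where `colsum_i` includes the pseudocounts.
#'
#' @param motif A [motif_model()].
#' @return 4 x w numeric matrix of log-odds scores in bits.
#' @export
pfm_to_pwm <- function(motif) {
  pc <- motif$pseudocount
  m <- motif$pfm + pc
  cs <- colSums(m)
  if (any(cs <= 0)) stop("non-positive column sum after pseudocount")
  freq <- sweep(m, 2L, cs, "/")
  log2(freq / motif$background)
}

#' Maximum attainable PWM score (bits)
#' @param pwm A 4 x w PWM.
#' @return Sum of per-column maxima.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm, 2L, max))

# character conversion that keeps names (base as.character drops them)
as_named_chr <- function(x) {
  nm <- names(x)
  out <- as.character(x)
  if (is.null(names(out))) names(out) <- nm
  out
}

# integer-encode a sequence; non-ACGT -> NA
encode_seq <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1]], BASES)
}

# score every window of `codes` against `pwm`; NA where a window contains a
# non-ACGT base
score_windows <- function(codes, pwm) {
  w <- ncol(pwm)
  L <- length(codes)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  sc <- numeric(n)
  for (i in seq_len(w)) {
    sc <- sc + pwm[cbind(codes[i:(i + n - 1L)], i)]
  }
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Slides the PWM over the forward sequence and over its reverse complement;
#' every window scoring at least `min_score` bits is reported. Windows
#' containing non-ACGT bases are skipped. Reverse-strand hits are reported
#' in forward-sequence coordinates.
#'
#' @param seq Character or `DNAString` sequence.
#' @param pwm 4 x w log-odds matrix from [pfm_to_pwm()].
#' @param min_score Score threshold in bits; default 80% of the PWM maximum.
#' @return Data.frame `offset` (0-based window start on the forward
#'   strand), `strand`, `score`.
#' @export
scan_sequence <- function(seq, pwm, min_score = 0.8 * pwm_max_score(pwm)) {
  codes <- encode_seq(seq)
  w <- ncol(pwm)
  if (length(codes) < w) stop("sequence shorter than motif width")
  fwd <- score_windows(codes, pwm)
  # reverse strand: score the reverse complement, then map offsets back
  rc <- rev(5L - codes)
  rc[is.na(rc)] <- NA_integer_
  rev_sc <- score_windows(rc, pwm)
  L <- length(codes)
  hits_f <- which(!is.na(fwd) & fwd >= min_score)
  hits_r <- which(!is.na(rev_sc) & rev_sc >= min_score)
  data.frame(
    offset = c(hits_f - 1L, L - w + 1L - hits_r),
    strand = rep(c("+", "-"), c(length(hits_f), length(hits_r))),
    score = c(fwd[hits_f], rev_sc[hits_r]),
    stringsAsFactors = FALSE
  )
}

#' Scan many peak sequences with a motif
#'
#' @param sequences Named `DNAStringSet` (or named character vector) of peak
#'   sequences; names are peak ids.
#' @param motif A [motif_model()].
#' @param min_score_frac Threshold as a fraction of the PWM maximum
#'   (default 0.8); overridden by `min_score`.
#' @param min_score Absolute threshold in bits (optional).
#' @return Data.frame `peak_id`, `offset`, `strand`, `score`.
#' @export
scan_peaks <- function(sequences, motif, min_score_frac = 0.8,
                       min_score = NULL) {
  pwm <- pfm_to_pwm(motif)
  thr <- min_score %||% (min_score_frac * pwm_max_score(pwm))
  seqs <- as_named_chr(sequences)
  out <- lapply(seq_along(seqs), function(i) {
    h <- scan_sequence(seqs[i], pwm, thr)
    if (nrow(h)) cbind(peak_id = names(seqs)[i], h,
                       stringsAsFactors = FALSE) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(peak_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif enrichment in differential peaks around summits
#'
#' A peak "has" the motif when it carries at least one hit within
#' `+-window` bp of its summit. The foreground (e.g. opening peaks) is
#' tested against the pooled foreground+background universe with a
#' one-sided hypergeometric upper tail.
#'
#' @param fg_ids,bg_ids Disjoint character vectors of peak ids (foreground =
#'   differential peaks, background = the remaining consensus peaks).
#' @param sequences Named `DNAStringSet`/character vector of peak sequences
#'   covering both sets.
#' @param motifs A [motif_model()] or list of them.
#' @param summit_offsets Named integer vector, bp from sequence start to the
#'   summit; defaults to the sequence midpoints.
#' @param window Half-width of the summit window in bp (default 200).
#' @param min_score_frac Scan threshold as fraction of PWM max (default 0.8).
#' @return Data.frame per motif: `tf`, `fg_with_motif`, `fg_total`,
#'   `bg_with_motif`, `bg_total`, `fold`, `p`, `padj` (BH across motifs).
#' @export
motif_enrichment <- function(fg_ids, bg_ids, sequences, motifs,
                             summit_offsets = NULL, window = 200,
                             min_score_frac = 0.8) {
  if (!length(fg_ids)) stop("empty foreground")
  if (length(intersect(fg_ids, bg_ids))) stop("fg and bg must be disjoint")
  if (inherits(motifs, "MotifModel")) motifs <- list(motifs)
  seqs <- as_named_chr(sequences)
  univ <- c(fg_ids, bg_ids)
  missing <- setdiff(univ, names(seqs))
  if (length(missing)) stop("sequences missing for: ",
                            paste(head(missing, 5), collapse = ", "))
  if (is.null(summit_offsets)) {
    summit_offsets <- setNames(floor(nchar(seqs) / 2), names(seqs))
  }
  carriers <- lapply(motifs, function(m) {
    hits <- scan_peaks(seqs[univ], m, min_score_frac)
    peaks_with_summit_hit(hits, m$width, summit_offsets, window)
  })
  names(carriers) <- vapply(motifs, function(m) m$name, character(1))
  enrich_from_carriers(fg_ids, bg_ids, carriers)
}

# hypergeometric table over precomputed carrier sets (motif name -> ids of
# peaks with a summit-window hit); used by motif_enrichment and by the
# pipeline, which scans each motif once across all strata
enrich_from_carriers <- function(fg_ids, bg_ids, carriers) {
  n_fg <- length(fg_ids)
  n_bg <- length(bg_ids)
  rows <- lapply(names(carriers), function(nm) {
    has <- carriers[[nm]]
    fg_with <- sum(fg_ids %in% has)
    bg_with <- sum(bg_ids %in% has)
    white <- fg_with + bg_with
    p <- phyper(fg_with - 1, white, n_fg + n_bg - white, n_fg,
                lower.tail = FALSE)
    fold <- if (bg_with > 0) (fg_with / n_fg) / (bg_with / n_bg) else {
      if (fg_with > 0) Inf else 0
    }
    data.frame(tf = nm, fg_with_motif = fg_with, fg_total = n_fg,
               bg_with_motif = bg_with, bg_total = n_bg,
               fold = fold, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- adjust_bh(res$p)
  rownames(res) <- NULL
  res
}

# ids of peaks with >= 1 hit whose motif center lies within the summit window
peaks_with_summit_hit <- function(hits, width, summit_offsets, window) {
  if (!nrow(hits)) return(character())
  center <- hits$offset + floor(width / 2)
  rel <- center - summit_offsets[hits$peak_id]
  unique(hits$peak_id[abs(rel) <= window])
}

#' Summit-relative motif occurrence profile
#'
#' For each bin of a `+-span` window around peak summits, the fraction of
#' peaks with at least one motif hit centered in that bin.
#'
#' @param hits Data.frame from [scan_peaks()].
#' @param motif_width Motif width (to compute hit centers).
#' @param summit_offsets Named integer vector, peak id -> summit offset
#'   within the scanned sequence.
#' @param n_peaks Number of peaks in the denominator.
#' @param span Half-width of the profile in bp (default 500).
#' @param bin Bin width in bp (default 10).
#' @return Data.frame `bin_start`, `bin_end` (summit-relative bp) and
#'   `occurrence` in `[0, 1]`; `span * 2 / bin` rows.
#' @export
occurrence_profile <- function(hits, motif_width, summit_offsets, n_peaks,
                               span = 500, bin = 10) {
  breaks <- seq(-span, span, by = bin)
  nb <- length(breaks) - 1L
  occ <- numeric(nb)
  if (nrow(hits) && n_peaks > 0) {
    center <- hits$offset + floor(motif_width / 2)
    rel <- center - summit_offsets[hits$peak_id]
    keep <- !is.na(rel) & rel >= -span & rel < span
    if (any(keep)) {
      idx <- findInterval(rel[keep], breaks, rightmost.closed = FALSE)
      # count peaks (not hits) per bin
      tab <- table(unique(data.frame(p = hits$peak_id[keep], b = idx))$b)
      occ[as.integer(names(tab))] <- as.integer(tab) / n_peaks
    }
  }
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             occurrence = occ)
}

#' Aggregate transposase-insertion footprint profile at motif hits
#'
#' Averages per-bp insertion counts across hits aligned on the motif
#' center; the depth score is `mean(flank) - mean(core)` so that positive
#' depth indicates protection (a footprint).
#'
#' @param insertion_counts Named list of per-bp numeric vectors (one per
#'   peak, covering the scanned sequence).
#' @param hits Data.frame from [scan_peaks()].
#' @param motif_width Motif width in bp (the core).
#' @param flank Flank width on each side in bp (default 50).
#' @return List: `profile` (length `motif_width + 2 * flank`), `depth`,
#'   `n_hits`. With zero usable hits, `profile` is empty and `depth` is NA.
#' @export
footprint_profile <- function(insertion_counts, hits, motif_width,
                              flank = 50) {
  width_tot <- motif_width + 2L * flank
  mats <- list()
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      v <- insertion_counts[[hits$peak_id[i]]]
      if (is.null(v)) next
      a <- hits$offset[i] - flank + 1L
      b <- hits$offset[i] + motif_width + flank
      if (a < 1L || b > length(v)) next  # too close to the peak edge
      mats[[length(mats) + 1L]] <- v[a:b]
    }
  }
  if (!length(mats)) {
    return(list(profile = numeric(0), depth = NA_real_, n_hits = 0L))
  }
  prof <- colMeans(do.call(rbind, mats))
  core_idx <- (flank + 1L):(flank + motif_width)
  depth <- mean(prof[-core_idx]) - mean(prof[core_idx])
  list(profile = prof, depth = depth, n_hits = length(mats))
}

#' Nominate TFs by intersecting motif enrichment with expression calls
#'
#' Within each stratum, a TF is nominated in direction `opening+up` when its
#' motif is enriched (padj below `padj_max`) in that stratum's opening peaks
#' and its own gene is called `up`; `closing+down` mirrors this. The
#' nomination lists which strata support each TF/direction.
#'
#' @param enrichment_by_stratum Named list (stratum -> list with elements
#'   `opening` and `closing`, each a [motif_enrichment()] data.frame).
#' @param de_by_stratum Named list (stratum -> differential results for
#'   genes with `feature_id` and `call` in `up`/`down`/`ns`).
#' @param tf_gene_map Data.frame with columns `tf` and `gene_id`.
#' @param padj_max Enrichment padj threshold (default 0.05).
#' @return Data.frame `tf`, `direction`, `stratum_support` (comma-joined),
#'   `n_strata`; empty when nothing is nominated.
#' @export
nominate_tfs <- function(enrichment_by_stratum, de_by_stratum, tf_gene_map,
                         padj_max = 0.05) {
  strata <- names(enrichment_by_stratum)
  stopifnot(!is.null(strata), all(strata %in% names(de_by_stratum)))
  recs <- list()
  for (st in strata) {
    de <- de_by_stratum[[st]]
    for (dir in c("opening+up", "closing+down")) {
      side <- if (dir == "opening+up") "opening" else "closing"
      want_call <- if (dir == "opening+up") "up" else "down"
      enr <- enrichment_by_stratum[[st]][[side]]
      if (is.null(enr) || !nrow(enr)) next
      for (i in seq_len(nrow(enr))) {
        tf <- enr$tf[i]
        gene <- tf_gene_map$gene_id[match(tf, tf_gene_map$tf)]
        if (is.na(gene)) {
          warning("TF '", tf, "' absent from tf_gene_map; skipped")
          next
        }
        call <- de$call[match(gene, de$feature_id)]
        if (!length(call) || is.na(call)) {
          warning("gene '", gene, "' for TF '", tf,
                  "' absent from expression results; skipped")
          next
        }
        if (!is.na(enr$padj[i]) && enr$padj[i] < padj_max &&
            call == want_call) {
          recs[[length(recs) + 1L]] <- data.frame(
            tf = tf, direction = dir, stratum = st,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(tf = character(), direction = character(),
                      stratum_support = character(), n_strata = integer(),
                      stringsAsFactors = FALSE))
  }
  recs <- do.call(rbind, recs)
  agg <- aggregate(stratum ~ tf + direction, recs,
                   function(s) paste(sort(unique(s)), collapse = ","))
  names(agg)[3] <- "stratum_support"
  agg$n_strata <- lengths(strsplit(agg$stratum_support, ","))
  agg[order(-agg$n_strata, agg$tf), , drop = FALSE]
}

#' Assign potential TF target genes from motif-bearing differential peaks
#'
#' Differential peaks carrying at least one motif hit are assigned to their
#' nearest gene ([assign_nearest_gene()], or promoter pairing when
#' `method = "promoter"`); each target gene's differential-expression call
#' is joined in.
#'
#' @param da_peaks `GRanges` of differential peaks with a `name` column.
#' @param hits Data.frame from [scan_peaks()] restricted to the motif of
#'   interest.
#' @param tss TSS `GRanges` with `gene_id`.
#' @param de_results Gene differential results (`feature_id`, `call`,
#'   `log2fc`).
#' @param method `"nearest"` (default) or `"promoter"`.
#' @param ... Passed to the assignment function.
#' @return Data.frame `gene_id`, `peak_id`, `de_call`, `gene_log2fc`; one
#'   row per (peak, gene).
#' @export
assign_tf_targets <- function(da_peaks, hits, tss, de_results,
                              method = c("nearest", "promoter"), ...) {
  method <- match.arg(method)
  with_motif <- unique(hits$peak_id)
  sel <- da_peaks[S4Vectors::mcols(da_peaks)$name %in% with_motif]
  if (!length(sel)) {
    return(data.frame(gene_id = character(), peak_id = character(),
                      de_call = character(), gene_log2fc = numeric(),
                      stringsAsFactors = FALSE))
  }
  asn <- if (method == "nearest") {
    a <- assign_nearest_gene(sel, tss, ...)
    a[!is.na(a$gene_id), c("peak_id", "gene_id")]
  } else {
    pair_promoter_genes(sel, tss, ...)[, c("peak_id", "gene_id")]
  }
  idx <- match(asn$gene_id, de_results$feature_id)
  data.frame(gene_id = asn$gene_id,
             peak_id = asn$peak_id,
             de_call = de_results$call[idx],
             gene_log2fc = de_results$log2fc[idx],
             stringsAsFactors = FALSE)
}
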