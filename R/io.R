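# Readers and writers for the plain-text interchange formats the pipeline
# consumes: broadPeak/BED peak calls, BED4 chromatin-state segmentations,
# BED6 TSS/gene tables, JASPAR-style PFMs and GMT gene-set files.
# All BED I/O is 0-based half-open on disk (rtracklayer converts to the
# 1-based closed GRanges convention in memory).

#' Read a broadPeak (BED6+3) file of scored peak calls
#'
#' Column 9 holds the q-value as -log10(q), following the ENCODE broadPeak
#' convention; it is converted back to a plain q-value in `(0, 1]` and stored
#' in the `q` metadata column.
#'
#' @param path Path to a broadPeak file.
#' @return A `GRanges` with metadata columns `name`, `score`, `q` and, when a
#'   narrowPeak-style 10th column is present, `summit_offset` (bp from the
#'   peak start).
#' @export
read_broadpeak <- function(path) {
  cols <- c(signalValue = "numeric", pValue = "numeric", qValue = "numeric")
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (length(first) >= 10L) cols <- c(cols, peak = "integer")
  gr <- rtracklayer::import(path, format = "bed", extraCols = cols)
  S4Vectors::mcols(gr)$q <- 10^(-S4Vectors::mcols(gr)$qValue)
  if ("peak" %in% names(S4Vectors::mcols(gr))) {
    S4Vectors::mcols(gr)$summit_offset <- S4Vectors::mcols(gr)$peak
  }
  gr
}

#' Write scored peaks as broadPeak
#'
#' @param gr A `GRanges` with metadata column `q` (q-values in `(0,1]`);
#'   optional `name` and `score`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_broadpeak <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  df <- granges_to_df(gr)
  df$name <- mc$name %||% paste0("peak", seq_along(gr))
  df$score <- mc$score %||% 0
  df$strand <- "."
  df$signalValue <- mc$signalValue %||% 0
  df$pValue <- -1
  df$qValue <- -log10(pmax(mc$q, 1e-300))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into GRanges
#'
#' Handles BED3/BED4/BED6; for BED4 segmentations the state name lands in the
#' `name` metadata column.
#'
#' @param path Path to a BED file.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write GRanges to BED
#'
#' @param gr A `GRanges`; a `name` metadata column becomes BED column 4.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a TSS table (BED6: chrom, start, end, gene, score, strand)
#'
#' @param path Path to a BED6 file with gene identifiers in column 4.
#' @return A `GRanges` of single-bp TSS positions with metadata column
#'   `gene_id` and strand set.
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  S4Vectors::mcols(gr)$gene_id <- S4Vectors::mcols(gr)$name
  gr
}

#' Read JASPAR-style position frequency matrices
#'
#' Accepts the JASPAR text format: a `>identifier name` header line followed
#' by four rows (A, C, G, T) of counts, optionally wrapped in brackets.
#'
#' @param path Path to a PFM file (may contain several motifs).
#' @param background Background base frequencies (A, C, G, T); must sum to 1.
#' @param pseudocount Pseudocount added per cell when converting to a PWM.
#' @return A list of `MotifModel` objects (see [motif_model()]).
#' @export
read_jaspar_pfm <- function(path, background = rep(0.25, 4),
                            pseudocount = 0.25) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' motif headers found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  motifs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(header, "\\s+")[[1]]
    name <- toks[length(toks)]
    body <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(body[seq_len(4)], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    motifs[[i]] <- motif_model(name, pfm, background = background,
                               pseudocount = pseudocount)
  }
  names(motifs) <- vapply(motifs, function(m) m$name, character(1))
  motifs
}

#' Write a motif as a JASPAR-style counts matrix
#'
#' @param motif A `MotifModel`.
#' @param path Output path.
#' @param append Append to an existing file instead of overwriting.
#' @return Invisibly, `path`.
#' @export
write_jaspar_pfm <- function(motif, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(paste0(">", motif$name, " ", motif$name), con)
  for (b in c("A", "C", "G", "T")) {
    writeLines(paste0(b, " [ ", paste(motif$pfm[b, ], collapse = " "), " ]"),
               con)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (`term_id<TAB>term_name<TAB>gene1<TAB>...`).
#' @return A named list of character gene vectors; names are term ids, the
#'   `term_name` attribute carries the descriptions.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "term_name") <- setNames(
    vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}
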