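# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stable 28-bit string hash, used to derive per-stage sub-seeds from the
# cohort seed so that results do not depend on module call order.
stage_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 268435399L
  as.integer(h)
}

#' Derive a per-stage sub-seed from a cohort seed
#'
#' Hashes the stage name so that results do not depend on the order in
#' which modules consume randomness.
#'
#' @param seed Integer cohort seed.
#' @param stage Stage name (character).
#' @return An integer seed in `[0, 2^31 - 19)`.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage_hash(stage)) %% 2147483629)
}

#' Read a TSV with feature ids in the first column into an integer matrix
#' @noRd
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

write_counts_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# 0-based half-open (chrom, start, end) -> GRanges (1-based closed)
df_to_granges <- function(df, extra = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  if (!is.null(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
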