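# Gene-set over-representation with Holm and BH corrections, and the GO
# category priority resolver that collapses multiple annotations per gene
# to a single label.

#' Hypergeometric gene-set over-representation
#'
#' One-sided upper-tail hypergeometric test per term:
#' `p = P(X >= k)` with `k` query hits in a term of size `K`, a query of
#' size `n` and a universe of size `N`. Terms with no member in the
#' universe are skipped.
#'
#' @param query Character vector of query genes (must be a subset of
#'   `universe`).
#' @param terms Named list of character gene vectors (e.g. [read_gmt()]).
#' @param universe Character vector of background genes.
#' @param padj_method `"holm"` (default, step-down) or `"bh"` (step-up).
#' @return Data.frame `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`,
#'   `padj_method`, `padj`, sorted by `p`.
#' @export
hypergeom_enrich <- function(query, terms, universe,
                             padj_method = c("holm", "bh")) {
  padj_method <- match.arg(padj_method)
  query <- unique(query)
  universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad)) {
    stop("query genes not in universe: ", paste(head(bad, 5), collapse = ", "))
  }
  term_names <- attr(terms, "term_name") %||%
    setNames(names(terms), names(terms))
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(terms), function(tid) {
    members <- intersect(terms[[tid]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid,
               term_name = unname(term_names[tid]) %||% tid,
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(),
                      padj_method = character(), padj = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$padj_method <- padj_method
  res$padj <- if (padj_method == "holm") adjust_holm(res$p) else
    adjust_bh(res$p)
  res[order(res$p), , drop = FALSE]
}

#' Bonferroni-Holm step-down adjustment
#'
#' With p-values sorted ascending, `padj_(i) = max_{j <= i} min(1,
#' (m - j + 1) * p_(j))`. `NA` values are propagated and excluded from `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_holm <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * pv[o]))
  out[ok[o]] <- adj
  out
}

#' Default GO category priority order
#' @return Character vector, highest priority first.
#' @export
default_category_priority <- function() {
  c("immunity", "metabolic", "transcription, translation", "migration",
    "mitochondria", "axon", "development")
}

#' Collapse multiple functional categories per gene to a single label
#'
#' Each gene keeps its highest-priority category. Genes with no category
#' become `"unclassified"`; genes carrying only categories outside the
#' priority list become `"other"`.
#'
#' @param gene_categories Named list, gene -> character vector of
#'   categories.
#' @param priority Ordered character vector, highest first
#'   (default [default_category_priority()]).
#' @return Named character vector, gene -> single category.
#' @export
prioritize_category <- function(gene_categories,
                                priority = default_category_priority()) {
  if (anyDuplicated(priority)) stop("duplicate categories in priority list")
  vapply(gene_categories, function(cats) {
    cats <- unique(as.character(cats))
    if (!length(cats)) return("unclassified")
    ranked <- match(cats, priority)
    if (all(is.na(ranked))) return("other")
    priority[min(ranked, na.rm = TRUE)]
  }, character(1))
}
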