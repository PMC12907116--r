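# Shared fixtures, built in code. The shared cohort is generated once per
# test run and cached.

.fixture_env <- new.env()

# small but fully featured cohort used across module tests
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(
      sim_config(n_peaks = 600, n_genes = 250, seed = 42))
  }
  .fixture_env$cohort
}

shared_cohort_dir <- function() {
  if (is.null(.fixture_env$dir)) {
    d <- file.path(tempdir(), "longacc-shared-cohort")
    write_cohort(shared_cohort(), d)
    .fixture_env$dir <- d
  }
  .fixture_env$dir
}

# GRanges from 0-based half-open triples
gr <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1L, end = end),
                         ...)
}

# brute-force interval merge: per-base occupancy on a small domain
merge_oracle <- function(grs, domain_end = 2000L) {
  chroms <- unique(as.character(GenomicRanges::seqnames(grs)))
  out <- list()
  for (ch in chroms) {
    occ <- rep(FALSE, domain_end)
    sub <- grs[as.character(GenomicRanges::seqnames(grs)) == ch]
    for (i in seq_along(sub)) {
      occ[GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <- TRUE
    }
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(starts[keep], ends[keep]))
    }
  }
  sort(suppressWarnings(do.call(c, unname(out))))
}

# exact NB log-likelihood for a two-group mean model, used as an
# independent oracle for the GLM fit
nb_two_group_loglik <- function(y, group, mu0, mu1, alpha) {
  mu <- ifelse(group == 1, mu1, mu0)
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}
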