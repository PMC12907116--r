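# Negative-binomial Wald differential testing with a sex covariate.
#
# The engine is a NB GLM (log link) fit by IRLS with a fixed per-feature
# dispersion, a Wald z test on the group coefficient, Benjamini-Hochberg
# adjustment, and threshold-based significance calling. It is applied
# identically to peak (accessibility) and gene (expression) count matrices.

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median of its ratios to the geometric-mean
#' pseudo-reference, computed over features positive in every sample. When
#' no feature is positive in all samples, falls back to library-size ratios
#' with a warning.
#'
#' @param counts Count matrix, features x samples.
#' @return Named numeric vector of positive size factors (geometric mean 1
#'   in the usual case).
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) return(setNames(1, colnames(counts)))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    warning("no feature positive in all samples; using library-size ratios")
    ls <- colSums(counts)
    return(setNames(ls / exp(mean(log(ls))), colnames(counts)))
  }
  lc <- log(counts[all_pos, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- apply(lc, 2L, function(x) exp(median(x - ref)))
  setNames(sf, colnames(counts))
}

#' Method-of-moments dispersion estimates
#'
#' For each feature, size-factor-normalized counts are grouped by design
#' cell (group x sex, or group alone); the NB excess variance
#' `(s^2 - m) / m^2` is pooled across cells with degrees-of-freedom weights
#' and floored.
#'
#' @param counts Count matrix, features x samples.
#' @param size_factors Per-sample size factors.
#' @param cells Factor of design-cell membership per sample (e.g.
#'   `interaction(group, sex)`).
#' @param floor Minimum dispersion (default 1e-8).
#' @return Numeric vector of per-feature dispersions alpha, where
#'   `Var = mu + alpha * mu^2`.
#' @export
estimate_dispersion <- function(counts, size_factors, cells, floor = 1e-8) {
  counts <- as.matrix(counts)
  cells <- droplevels(as.factor(cells))
  norm <- sweep(counts, 2L, size_factors, "/")
  num <- rep(0, nrow(counts))
  den <- rep(0, nrow(counts))
  for (cl in levels(cells)) {
    idx <- which(cells == cl)
    if (length(idx) < 2L) next
    sub <- norm[, idx, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, var)
    w <- length(idx) - 1L
    num <- num + w * (v - m)
    den <- den + w * m^2
  }
  alpha <- ifelse(den > 0, num / den, floor)
  pmax(alpha, floor)
}

# One NB GLM fit (log link, fixed dispersion) by iteratively reweighted
# least squares. Returns beta, se, converged.
nb_irls <- function(y, X, offset, alpha, max_iter = 50L, tol = 1e-8) {
  # initialise from a log-linear fit on shifted counts
  z0 <- log(y + 0.5) - offset
  beta <- tryCatch(qr.coef(qr(X), z0), error = function(e) rep(0, ncol(X)))
  beta[is.na(beta)] <- 0
  dev_old <- Inf
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtWX <- crossprod(X, X * w)
    beta_new <- tryCatch(solve(XtWX, crossprod(X, w * z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    dev <- -2 * sum(suppressWarnings(
      stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    dev_old <- dev
    beta <- beta_new
  }
  se <- tryCatch(sqrt(diag(solve(XtWX))), error = function(e) rep(NA_real_, ncol(X)))
  list(beta = beta, se = se, converged = converged)
}

#' Wald test for one feature under the NB GLM
#'
#' Fits `log mu = X beta + log(size_factor)` with fixed dispersion and tests
#' the group coefficient with a Wald z statistic against the standard-normal
#' reference.
#'
#' @param y Integer counts for one feature (length = samples).
#' @param X Design matrix (intercept + group indicator + optional covariates);
#'   the tested coefficient is named `"group"` (or given by `coef_name`).
#' @param size_factors Per-sample size factors.
#' @param alpha NB dispersion for this feature.
#' @param coef_name Column of `X` to test (default "group").
#' @return One-row data.frame: `base_mean`, `log2fc`, `se` (log2 scale),
#'   `wald_p`, `converged`. All-zero features yield NA statistics.
#' @export
nb_wald_test <- function(y, X, size_factors, alpha, coef_name = "group") {
  stopifnot(length(y) == nrow(X), coef_name %in% colnames(X))
  base_mean <- mean(y / size_factors)
  if (all(y == 0)) {
    return(data.frame(base_mean = 0, log2fc = NA_real_, se = NA_real_,
                      wald_p = NA_real_, converged = NA))
  }
  fit <- nb_irls(y, X, log(size_factors), alpha)
  j <- match(coef_name, colnames(X))
  b <- fit$beta[j]
  se <- fit$se[j]
  p <- if (fit$converged && is.finite(se) && se > 0) {
    2 * pnorm(-abs(b / se))
  } else NA_real_
  data.frame(base_mean = base_mean,
             log2fc = b / log(2),
             se = se / log(2),
             wald_p = p,
             converged = isTRUE(fit$converged))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with cumulative minimum; `NA` p-values are
#' propagated and excluded from the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Call significance on differential results
#'
#' `opening`/`up` when `padj < padj_max` and linear fold change strictly
#' exceeds `fc_min` (i.e. `log2fc > log2(fc_min)`); `closing`/`down` on the
#' mirrored condition; otherwise `ns`. Both inequalities are strict.
#'
#' @param results Data.frame with columns `log2fc` and `padj`.
#' @param padj_max Adjusted-p threshold (default 0.05).
#' @param fc_min Linear fold-change threshold (default 1.5).
#' @param labels Length-2 character: labels for the positive and negative
#'   directions (`c("opening","closing")` for peaks,
#'   `c("up","down")` for genes).
#' @return `results` with a `call` column added.
#' @export
call_differential <- function(results, padj_max = 0.05, fc_min = 1.5,
                              labels = c("opening", "closing")) {
  lfc_min <- log2(fc_min)
  call <- rep("ns", nrow(results))
  sig <- !is.na(results$padj) & results$padj < padj_max &
    !is.na(results$log2fc)
  call[sig & results$log2fc > lfc_min] <- labels[1]
  call[sig & results$log2fc < -lfc_min] <- labels[2]
  results$call <- call
  results
}

#' Build the design matrix for a cohort contrast
#'
#' @param sample_sheet Data.frame with columns `sample_id`,
#'   `group` (`control`/`centenarian`) and `sex` (`F`/`M`).
#' @param include_sex Include the sex covariate (default TRUE; stratified
#'   runs on single-sex subsets use `FALSE`).
#' @return Design matrix with columns `(Intercept)`, `group` (1 =
#'   centenarian) and optionally `sexM` (1 = male).
#' @export
design_matrix <- function(sample_sheet, include_sex = TRUE) {
  stopifnot(all(c("group", "sex") %in% names(sample_sheet)))
  g <- as.integer(sample_sheet$group == "centenarian")
  if (length(unique(g)) < 2L) stop("both groups must be present")
  X <- cbind(`(Intercept)` = 1, group = g)
  if (include_sex) {
    s <- as.integer(sample_sheet$sex == "M")
    if (length(unique(s)) < 2L) {
      stop("sex covariate requested but only one sex present; ",
           "use include_sex = FALSE for stratified runs")
    }
    X <- cbind(X, sexM = s)
  }
  X
}

#' Differential testing over a whole count matrix
#'
#' Runs size-factor estimation, method-of-moments dispersion, per-feature NB
#' Wald tests on the group coefficient, BH adjustment and significance
#' calling.
#'
#' @param counts Count matrix, features x samples (columns must match
#'   `sample_sheet$sample_id`).
#' @param sample_sheet Data.frame with `sample_id`, `group`, `sex`.
#' @param include_sex Include sex as a covariate (default TRUE).
#' @param padj_max,fc_min Calling thresholds, see [call_differential()].
#' @param labels Direction labels, see [call_differential()].
#' @param size_factors Optional precomputed size factors.
#' @param dispersions Optional precomputed per-feature dispersions.
#' @return Data.frame with one row per feature: `feature_id`, `base_mean`,
#'   `log2fc`, `se`, `wald_p`, `padj`, `call`, `converged`.
#' @export
differential_test <- function(counts, sample_sheet, include_sex = TRUE,
                              padj_max = 0.05, fc_min = 1.5,
                              labels = c("opening", "closing"),
                              size_factors = NULL, dispersions = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(sample_sheet))
  if (!is.null(colnames(counts))) {
    stopifnot(all(colnames(counts) == sample_sheet$sample_id))
  }
  X <- design_matrix(sample_sheet, include_sex = include_sex)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) {
    cells <- if (include_sex) {
      interaction(sample_sheet$group, sample_sheet$sex)
    } else as.factor(sample_sheet$group)
    dispersions <- estimate_dispersion(counts, size_factors, cells)
  }
  rows <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    rows[[i]] <- nb_wald_test(counts[i, ], X, size_factors, dispersions[i])
  }
  res <- do.call(rbind, rows)
  res <- cbind(feature_id = rownames(counts) %||%
                 as.character(seq_len(nrow(counts))),
               res, stringsAsFactors = FALSE)
  res$padj <- adjust_bh(res$wald_p)
  res <- call_differential(res, padj_max = padj_max, fc_min = fc_min,
                           labels = labels)
  rownames(res) <- NULL
  res
}
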