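# TMM normalization and negative-binomial likelihood-ratio testing of
# circular and linear junction counts between two conditions.

as_counts <- function(m) {
  if (inherits(m, "CountMatrix")) m$counts else as.matrix(m)
}

# Quantile of the count/library-size rate, used to pick the TMM reference.
.rate_quantile <- function(counts, lib, p = 0.75) {
  apply(sweep(counts, 2L, lib, "/"), 2L, stats::quantile, probs = p)
}

# TMM factor of sample `obs` against sample `ref` (counts + library sizes).
# Doubly trimmed (30% on M, 5% on A) weighted mean of log ratios, with
# inverse asymptotic (delta-method) variance weights.
.tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                      logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  f <- sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes one scaling factor per sample by the TMM method: the reference
#' sample is the one whose upper-quartile count rate is closest to the mean
#' upper quartile; for every other sample, features with a zero count in
#' either sample are excluded, the most extreme 30% of log ratios (M) and 5%
#' of log abundances (A) are trimmed, and the factor is the weighted mean of
#' the remaining M values with inverse asymptotic-variance weights. Factors
#' are rescaled to geometric mean 1.
#'
#' @param m A `CountMatrix` or plain count matrix (features x samples).
#' @param logratio_trim Fraction of M values trimmed from each tail
#'   (default 0.3).
#' @param sum_trim Fraction of A values trimmed from each tail
#'   (default 0.05).
#' @return Named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(m, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as_counts(m)
  stopifnot(ncol(counts) >= 2)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  f75 <- .rate_quantile(counts, lib)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Vectorized MLE of the per-feature mean scale m under NB(mu_ij = m_i * L_j,
# dispersion phi), by Newton iteration on log(m). Y: features x samples;
# L: effective library sizes. Returns the fitted scale and log-likelihood
# per feature. phi = 0 is the Poisson limit (closed form).
.nb_fit_scale <- function(Y, L, phi, tol = 1e-10, max_iter = 50L) {
  tot <- rowSums(Y)
  if (phi <= 0) {
    m <- tot / sum(L)
    mu <- outer(m, L)
    ll <- rowSums(stats::dpois(Y, pmax(mu, 1e-300), log = TRUE))
    return(list(scale = m, ll = ll))
  }
  m <- pmax(tot / sum(L), 1e-8)
  t <- log(m)
  zero <- tot == 0
  for (it in seq_len(max_iter)) {
    mu <- outer(exp(t), L)
    g <- rowSums(Y - mu * (1 + phi * Y) / (1 + phi * mu))
    h <- -rowSums(mu * (1 + phi * Y) / (1 + phi * mu)^2)
    step <- g / h
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 5), -5)
    t <- t - step
    if (max(abs(step[!zero])) < tol) break
  }
  m <- exp(t)
  m[zero] <- 0
  mu <- outer(m, L)
  ll <- rowSums(stats::dnbinom(Y, size = 1 / phi, mu = pmax(mu, 1e-300),
                               log = TRUE))
  list(scale = m, ll = ll)
}

# Profile log-likelihood of a common dispersion: per-group means refitted at
# each candidate phi; maximized over a log-spaced grid.
.estimate_common_dispersion <- function(Y, L, groups,
                                        grid = exp(seq(log(1e-4), log(4),
                                                       length.out = 200))) {
  lev <- levels(groups)
  prof <- vapply(grid, function(phi) {
    sum(vapply(lev, function(g) {
      j <- groups == g
      sum(.nb_fit_scale(Y[, j, drop = FALSE], L[j], phi)$ll)
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(prof)]
}

#' Negative-binomial likelihood-ratio test between two conditions
#'
#' For each feature the NB log-likelihood is maximized under the null (one
#' mean scale across all samples, proportional to effective library size)
#' and the alternative (one scale per group) with a fixed dispersion; the
#' p-value is the upper tail of chi-squared(1) at the likelihood-ratio
#' statistic. The log2 fold change is computed from effective-library
#' normalized group mean counts with a 0.5 pseudo-count guard. Features with
#' all-zero counts in both groups are excluded before testing.
#'
#' @param m A `CountMatrix` or count matrix (features x samples).
#' @param groups Two-level factor (or coercible) of length `n_samples`; the
#'   contrast is second level versus first level.
#' @param factors Optional TMM factors from [tmm_factors()]; effective
#'   library size is `colSums(counts) * factors`.
#' @param dispersion Either a fixed NB dispersion (>= 0; 0 is the Poisson
#'   limit) or `"estimate"` to estimate a common dispersion by profile
#'   likelihood over a log-spaced grid.
#' @param alpha Significance threshold used to set `status` (default 0.05,
#'   on the raw p-value).
#' @return A data.frame with `feature_id`, `kind` (when available),
#'   `log2fc`, `pvalue`, `fdr` (Benjamini-Hochberg, reported but not used
#'   for `status`), `mean_cpm`, `status` (`up`/`down`/`unaltered`), and the
#'   `dispersion` used as an attribute.
#' @export
nb_lrt <- function(m, groups, factors = NULL, dispersion = "estimate",
                   alpha = 0.05) {
  counts <- as_counts(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) {
    stop("design must have exactly two levels, got ", nlevels(groups))
  }
  stopifnot(length(groups) == ncol(counts))
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")

  lib <- colSums(counts)
  if (!is.null(factors)) {
    if (!is.null(names(factors)) && !is.null(colnames(counts))) {
      factors <- factors[colnames(counts)]
    }
    lib <- lib * factors
  }

  tested <- rowSums(counts) > 0
  Y <- counts[tested, , drop = FALSE]
  storage.mode(Y) <- "double"

  if (identical(dispersion, "estimate")) {
    dispersion <- .estimate_common_dispersion(Y, lib, groups)
  }
  stopifnot(is.numeric(dispersion), dispersion >= 0)

  lev <- levels(groups)
  j1 <- groups == lev[1]
  j2 <- groups == lev[2]
  fit0 <- .nb_fit_scale(Y, lib, dispersion)
  fit1 <- .nb_fit_scale(Y[, j1, drop = FALSE], lib[j1], dispersion)
  fit2 <- .nb_fit_scale(Y[, j2, drop = FALSE], lib[j2], dispersion)
  lr <- pmax(2 * (fit1$ll + fit2$ll - fit0$ll), 0)
  pvalue <- stats::pchisq(lr, df = 1, lower.tail = FALSE)

  # normalized group means on the count scale (rescaled to the mean
  # effective library), guarded by a 0.5 pseudo-count
  scale_to_counts <- mean(lib)
  m1 <- fit1$scale * scale_to_counts
  m2 <- fit2$scale * scale_to_counts
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  mean_cpm <- rowMeans(sweep(Y, 2L, lib, "/")) * 1e6

  res <- data.frame(
    feature_id = rownames(Y) %||% as.character(seq_len(nrow(Y))),
    log2fc = log2fc,
    pvalue = pvalue,
    fdr = stats::p.adjust(pvalue, "BH"),
    mean_cpm = mean_cpm,
    stringsAsFactors = FALSE
  )
  if (inherits(m, "CountMatrix")) {
    idx <- match(res$feature_id, m$features$feature_id)
    res <- cbind(res[, "feature_id", drop = FALSE],
                 kind = m$features$kind[idx],
                 circ_id = m$features$circ_id[idx],
                 res[, -1, drop = FALSE])
  }
  res$status <- de_status(res$log2fc, res$pvalue, alpha)
  rownames(res) <- NULL
  attr(res, "dispersion") <- dispersion
  attr(res, "alpha") <- alpha
  res
}

#' Classify differential status at a significance threshold
#'
#' `up` iff `pvalue < alpha` and `log2fc > 0`; `down` iff `pvalue < alpha`
#' and `log2fc < 0`; otherwise `unaltered`.
#'
#' @param log2fc,pvalue Numeric vectors.
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of statuses.
#' @export
de_status <- function(log2fc, pvalue, alpha = 0.05) {
  ifelse(pvalue < alpha & log2fc > 0, "up",
         ifelse(pvalue < alpha & log2fc < 0, "down", "unaltered"))
}
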