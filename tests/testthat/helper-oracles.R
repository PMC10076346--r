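# Independent oracles used to validate package statistics by brute force.

# Two-sided Fisher exact p-value by full enumeration of 2x2 tables with the
# observed margins, summing hypergeometric probabilities not exceeding the
# observed table's probability (with a small relative tolerance).
brute_fisher_p <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kolmogorov-Smirnov D by direct ECDF evaluation at all pooled points.
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(fx - fy))
}

# Minimum folding energy by exhaustive recursion over all nested structures
# (first-position branching; no memoization, so every structure is visited).
# Independent of the interval dynamic program in the package.
brute_fold <- function(seq, min_loop = 3) {
  pair_e <- function(x, y) {
    x <- sub("T", "U", x); y <- sub("T", "U", y)
    key <- paste0(x, y)
    switch(key, GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1, NA)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)  # i unpaired
    for (k in (i + min_loop + 1):j) {
      e <- pair_e(chars[i], chars[k])
      if (!is.na(e)) {
        best <- min(best, e + rec(i + 1, k - 1) + rec(k + 1, j))
      }
    }
    best
  }
  if (length(chars) < 2) return(0)
  rec(1, length(chars))
}

# Poisson deviance likelihood-ratio test for a two-group design with
# offsets, via closed-form group means (independent of the NB fitter).
poisson_lrt_p <- function(y, groups, lib) {
  groups <- as.factor(groups)
  mu0 <- sum(y) / sum(lib) * lib
  mu1 <- y * 0
  for (g in levels(groups)) {
    j <- groups == g
    mu1[j] <- sum(y[j]) / sum(lib[j]) * lib[j]
  }
  term <- function(y, mu) ifelse(y == 0, 0, y * log(y / mu))
  lr <- 2 * (sum(term(y, mu0)) - sum(term(y, mu1)))
  stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
}
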