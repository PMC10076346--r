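# Concordance classification, CLR distribution comparison and 2x2 tests.

de_row <- function(circ_id, log2fc, pvalue) {
  data.frame(circ_id = circ_id, log2fc = log2fc, pvalue = pvalue,
             stringsAsFactors = FALSE)
}

test_that("pair classification reproduces the category definitions", {
  id <- "chr1:101-200:+"
  cases <- list(
    list(c(1.2, 0.01), c(0.8, 0.02), "Concordant"),
    list(c(1.2, 0.01), c(0.1, 0.60), "DiscordantCirc"),
    list(c(1.2, 0.01), c(-0.9, 0.01), "DiscordantCirc"),  # opposite dir
    list(c(-0.1, 0.80), c(-2.0, 0.001), "DiscordantLin"),
    list(c(0.1, 0.90), c(0.2, 0.70), "Unaltered")
  )
  for (cs in cases) {
    got <- classify_pairs(de_row(id, cs[[1]][1], cs[[1]][2]),
                          de_row(id, cs[[2]][1], cs[[2]][2]))
    expect_equal(got$category, cs[[3]])
  }
})

test_that("classification partitions every sign/significance combination", {
  id <- "chr1:101-200:+"
  lfcs <- c(-1.5, 1.5)
  ps <- c(0.01, 0.5)
  for (cl in lfcs) for (cp in ps) for (ll in lfcs) for (lp in ps) {
    got <- classify_pairs(de_row(id, cl, cp), de_row(id, ll, lp))
    expect_true(got$category %in%
                  c("Concordant", "DiscordantCirc", "DiscordantLin",
                    "Unaltered"))
    expected <- if (cp < 0.05 && lp < 0.05 && sign(cl) == sign(ll)) {
      "Concordant"
    } else if (cp < 0.05) {
      "DiscordantCirc"
    } else if (lp < 0.05) {
      "DiscordantLin"
    } else {
      "Unaltered"
    }
    expect_equal(got$category, expected)
  }
  expect_error(classify_pairs(de_row("chr1:1-2:+", 0, 1),
                              de_row("chr2:1-2:+", 0, 1)),
               "no shared")
})

test_that("proportion test matches hypergeometric enumeration", {
  expect_equal(proportion_test(2, 0, 0, 2)$p, 1 / 3, tolerance = 1e-12)
  expect_equal(proportion_test(0, 5, 0, 7)$p, 1)
  sym <- proportion_test(10, 10, 10, 10)
  expect_equal(sym$p, 1)
  expect_equal(sym$odds_ratio, 1)
  set.seed(3)
  for (i in 1:25) {
    tab <- rbinom(4, size = 15, prob = 0.5)  # margins at most 30
    if (sum(tab[1:2]) == 0 || sum(tab[3:4]) == 0) next
    got <- proportion_test(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got$p, brute_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})

test_that("deregulation proportions are percentages of the deregulated", {
  p <- deregulation_proportions(410, 85)
  expect_equal(p$pct_down + p$pct_up, 100)
  expect_equal(p$pct_down, 100 * 410 / 495)
  expect_error(deregulation_proportions(0, 0))
})

test_that("KS comparison matches the brute-force ECDF sup difference", {
  expect_equal(clr_cdf_compare(c(1, 2), c(3, 4))$D, 1)
  expect_equal(clr_cdf_compare(1:4, 2:5)$D, 0.25)
  expect_equal(clr_cdf_compare(c(1, 2, 3), c(1, 2, 3))$D, 0)
  set.seed(5)
  for (i in 1:10) {
    x <- rlnorm(sample(5:50, 1))
    y <- rlnorm(sample(5:50, 1), meanlog = 0.3)
    expect_equal(clr_cdf_compare(x, y)$D, brute_ks_D(x, y),
                 tolerance = 1e-12)
  }
  expect_error(clr_cdf_compare(numeric(0), 1:3), "empty")
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(6)
  x <- rlnorm(40)
  y <- rlnorm(35, meanlog = 0.5)
  d0 <- clr_cdf_compare(x, y)$D
  expect_equal(clr_cdf_compare(log(x), log(y))$D, d0)
  expect_equal(clr_cdf_compare(x^3, y^3)$D, d0)
})

test_that("CLR values exclude zero-linear pairs and use condition means", {
  ids <- circ_id("chr1", c(100L, 300L), c(200L, 400L), "+")
  vals <- rbind(c(10, 20), c(5, 5),   # circ
                c(5, 5), c(0, 0))     # linear (second pair undefined)
  rownames(vals) <- c(paste0(ids, "|circ"), paste0(ids, "|linear"))
  m <- structure(list(
    values = vals,
    features = data.frame(feature_id = rownames(vals),
                          circ_id = rep(ids, 2),
                          kind = rep(c("circ", "linear"), each = 2),
                          stringsAsFactors = FALSE),
    samples = c("s1", "s2")), class = "CpmMatrix")
  colnames(m$values) <- m$samples
  v <- clr_values(m, c("s1", "s2"))
  expect_equal(v$circ_id, ids[1])
  expect_equal(v$clr, 15 / 5)
})

test_that("overlap test builds the membership table over the universe", {
  universe <- sprintf("c%03d", 1:100)
  a <- universe[1:2]
  res <- overlap_test(a, a, universe)
  expect_equal(res$overlap_pct, 100)
  expect_lt(res$p, 0.01)
  expect_equal(res$p, brute_fisher_p(2, 0, 0, 98), tolerance = 1e-9)
  dis <- overlap_test(universe[1:3], universe[4:6], universe)
  expect_equal(dis$overlap_count, 0L)
  full <- overlap_test(universe, universe[1:10], universe)
  expect_equal(full$p, 1)
  expect_true(is.finite(full$odds_ratio))
  # denominator conventions
  ab <- overlap_test(universe[1:10], universe[6:15], universe,
                     denominator = "setA")
  expect_equal(ab$overlap_pct, 50)
  expect_error(overlap_test("x", "x", character(0)), "empty universe")
})

test_that("binding-by-cutoff reports fractions and NA for empty strata", {
  one <- de_row("chr1:101-200:+", -2, 0.01)
  tab <- binding_by_cutoff(one, "chr1:101-200:+", cutoffs = 0.05)
  expect_equal(tab$fraction_bound[tab$direction == "down"], 1)
  expect_true(is.na(tab$fraction_bound[tab$direction == "up"]))
  expect_error(binding_by_cutoff(one[0, ], character(0)), "empty")
})

test_that("binding fraction rises with cutoff stringency for a planted link", {
  # planted monotone link: smaller p <=> larger effect <=> bound
  n <- 400
  lfc <- -seq(0.01, 4, length.out = n)
  p <- exp(-abs(lfc) * 2.5)
  ids <- sprintf("chr1:%d-%d:+", seq_len(n), seq_len(n) + 500L)
  bound <- abs(lfc) > 1
  de <- data.frame(circ_id = ids, log2fc = lfc, pvalue = p,
                   stringsAsFactors = FALSE)
  tab <- binding_by_cutoff(de, ids[bound], cutoffs = c(0.05, 0.01, 0.001))
  down <- tab[tab$direction == "down", ]
  expect_true(all(diff(down$fraction_bound) >= -1e-9))
  expect_true(all(down$n > 0))
})
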