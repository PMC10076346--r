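# Concordance classification of circular/linear isoform pairs, CLR
# statistics, proportion/overlap tests and the binding-vs-cutoff sweep.

#' Classify circular/linear isoform pairs into concordance categories
#'
#' For every circRNA tested together with its cognate linear junction:
#' `Concordant` when both isoforms are significantly deregulated in the same
#' direction; `DiscordantCirc` when the circular isoform is significant and
#' the linear is unaltered or significant in the opposite direction;
#' `DiscordantLin` when the linear isoform is significant and the circular
#' is unaltered; `Unaltered` when neither is significant. The four
#' categories are mutually exclusive and exhaustive.
#'
#' @param circ,lin Differential results ([nb_lrt()] rows, or any data.frame
#'   with `circ_id`, `log2fc`, `pvalue`) for the circular and linear
#'   features of the same junctions.
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return A data.frame with `circ_id`, `category`, `circ_log2fc`,
#'   `lin_log2fc`, `circ_p`, `lin_p`.
#' @export
classify_pairs <- function(circ, lin, alpha = 0.05) {
  common <- intersect(circ$circ_id, lin$circ_id)
  if (length(common) == 0) stop("no shared junction coordinates")
  ci <- circ[match(common, circ$circ_id), ]
  li <- lin[match(common, lin$circ_id), ]
  circ_sig <- ci$pvalue < alpha
  lin_sig <- li$pvalue < alpha
  same_dir <- sign(ci$log2fc) == sign(li$log2fc)
  category <- ifelse(
    circ_sig & lin_sig & same_dir, "Concordant",
    ifelse(circ_sig, "DiscordantCirc",
           ifelse(lin_sig, "DiscordantLin", "Unaltered"))
  )
  out <- data.frame(
    circ_id = common,
    category = category,
    circ_log2fc = ci$log2fc,
    lin_log2fc = li$log2fc,
    circ_p = ci$pvalue,
    lin_p = li$pvalue,
    stringsAsFactors = FALSE
  )
  if (!is.null(ci$gene_id)) out$gene_id <- ci$gene_id
  out
}

#' Two-tailed Fisher exact test on up/down proportions of two sets
#'
#' Compares the up/down split of two feature sets (e.g. linear RNAs versus
#' circRNAs) with the two-tailed Fisher exact test (summing hypergeometric
#' probabilities not exceeding that of the observed table). The odds ratio
#' is the sample odds ratio, with a Haldane-Anscombe 0.5 correction when any
#' cell is zero (reporting only; the p-value uses the uncorrected table).
#'
#' @param set1_up,set1_down,set2_up,set2_down Non-negative counts.
#' @return List with `odds_ratio` and `p`.
#' @export
proportion_test <- function(set1_up, set1_down, set2_up, set2_down) {
  stopifnot(all(c(set1_up, set1_down, set2_up, set2_down) >= 0))
  if (set1_up + set1_down == 0 || set2_up + set2_down == 0) {
    stop("both sets must be nonempty")
  }
  fisher_2x2(set1_up, set1_down, set2_up, set2_down)
}

#' Percentages of down- and upregulated features
#'
#' Summarizes deregulated feature counts as percentages of the deregulated
#' total, the form in which up/down proportions are reported alongside the
#' stacked-bar comparisons.
#'
#' @param n_down,n_up Counts of significantly down- and upregulated
#'   features.
#' @return List with `pct_down` and `pct_up` (0-100).
#' @export
deregulation_proportions <- function(n_down, n_up) {
  stopifnot(n_down >= 0, n_up >= 0, n_down + n_up > 0)
  list(pct_down = 100 * n_down / (n_down + n_up),
       pct_up = 100 * n_up / (n_down + n_up))
}

#' Circular-to-linear ratio (CLR) per circRNA
#'
#' CLR is the circular isoform's mean CPM over a condition's samples divided
#' by the linear isoform's. Pairs whose linear CPM is zero are excluded
#' (ratio undefined); a zero circular CPM yields CLR 0.
#'
#' @param m A `CpmMatrix` (see [cpm()]).
#' @param samples Sample ids of the condition.
#' @return A data.frame with `circ_id` and `clr`.
#' @export
clr_values <- function(m, samples) {
  stopifnot(inherits(m, "CpmMatrix"))
  cols <- match(samples, m$samples)
  stopifnot(!anyNA(cols))
  circ <- m$features$kind == "circ"
  ids <- m$features$circ_id[circ]
  circ_mean <- rowMeans(m$values[circ, cols, drop = FALSE])
  lin_rows <- match(paste0(ids, "|linear"), m$features$feature_id)
  lin_mean <- rowMeans(m$values[lin_rows, cols, drop = FALSE])
  keep <- !is.na(lin_mean) & lin_mean > 0
  data.frame(circ_id = ids[keep], clr = circ_mean[keep] / lin_mean[keep],
             stringsAsFactors = FALSE)
}

#' Compare two CLR distributions by the Kolmogorov-Smirnov test
#'
#' `D` is the supremum absolute difference of the two empirical CDFs; the
#' p-value is two-sided and asymptotic by default (exact optionally, for
#' small samples).
#'
#' @param clr_a,clr_b Numeric CLR vectors, or data.frames from
#'   [clr_values()].
#' @param exact Use the exact small-sample distribution (default `FALSE`).
#' @return List with `D` and `p`.
#' @export
clr_cdf_compare <- function(clr_a, clr_b, exact = FALSE) {
  if (is.data.frame(clr_a)) clr_a <- clr_a$clr
  if (is.data.frame(clr_b)) clr_b <- clr_b$clr
  clr_a <- clr_a[is.finite(clr_a)]
  clr_b <- clr_b[is.finite(clr_b)]
  if (length(clr_a) == 0 || length(clr_b) == 0) {
    stop("empty CLR sample after excluding undefined ratios")
  }
  kt <- suppressWarnings(stats::ks.test(clr_a, clr_b, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Overlap of two feature sets with Fisher significance
#'
#' Builds the 2x2 membership table of `a` and `b` over `universe` and
#' applies the two-tailed Fisher exact test. The overlap percentage is
#' reported, by default, relative to the union of the two sets
#' (Jaccard-style); `denominator` selects other conventions.
#'
#' @param a,b Id sets (subsets of `universe`).
#' @param universe Id universe over which membership is tabulated.
#' @param denominator One of `"union"`, `"setA"`, `"setB"`.
#' @return List with `overlap_count`, `overlap_pct`, `odds_ratio`, `p`.
#' @export
overlap_test <- function(a, b, universe,
                         denominator = c("union", "setA", "setB")) {
  denominator <- match.arg(denominator)
  if (length(universe) == 0) stop("empty universe")
  stopifnot(all(a %in% universe), all(b %in% universe))
  in_a <- universe %in% a
  in_b <- universe %in% b
  n11 <- sum(in_a & in_b)
  n10 <- sum(in_a & !in_b)
  n01 <- sum(!in_a & in_b)
  n00 <- sum(!in_a & !in_b)
  ft <- fisher_2x2(n11, n10, n01, n00)
  denom <- switch(denominator,
                  union = length(union(a, b)),
                  setA = length(a),
                  setB = length(b))
  list(overlap_count = n11,
       overlap_pct = if (denom > 0) 100 * n11 / denom else NA_real_,
       odds_ratio = ft$odds_ratio,
       p = ft$p)
}

#' Fraction of deregulated circRNAs bound by the protein, by p-value cutoff
#'
#' For each p-value cutoff, circRNAs significant at that cutoff with the
#' given direction of change are selected and the fraction that are
#' interactors (see [interactor_call()]) is reported. Empty strata are
#' reported as `NA` rather than zero.
#'
#' @param de Differential results for circular features (`circ_id`,
#'   `log2fc`, `pvalue`).
#' @param interactors Character vector of interactor circRNA ids.
#' @param cutoffs Decreasing p-value cutoffs (e.g. `c(0.05, 0.01, 0.001)`).
#' @return A data.frame with `cutoff`, `direction` (`down`/`up`), `n`
#'   (stratum size) and `fraction_bound`.
#' @export
binding_by_cutoff <- function(de, interactors,
                              cutoffs = c(0.05, 0.01, 0.001)) {
  if (nrow(de) == 0) stop("empty differential-expression input")
  stopifnot(!is.unsorted(rev(cutoffs)))
  rows <- lapply(cutoffs, function(cut) {
    lapply(c(down = -1, up = 1), function(s) {
      sel <- de$pvalue < cut & sign(de$log2fc) == s
      n <- sum(sel)
      data.frame(
        cutoff = cut,
        direction = if (s < 0) "down" else "up",
        n = n,
        fraction_bound = if (n == 0) NA_real_ else
          mean(de$circ_id[sel] %in% interactors),
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}
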