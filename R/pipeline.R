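# End-to-end orchestration: junction tables -> differential results ->
# concordance classes, and differential results + annotation + peaks ->
# meta-BSJ enrichment. Thin wrappers over the module functions, so the full
# analysis is reproducible in two calls.

#' Differential junction analysis from per-sample BSJ tables
#'
#' Runs the count stage end to end: cross-sample completion, expression
#' filtering (at least `min_count` counts in at least `min_samples`
#' samples), TMM normalization, the NB likelihood-ratio test on circular
#' and linear junction features jointly, CPM conversion, and concordance
#' classification of circular/linear pairs tested for both isoforms.
#'
#' @param records Per-sample list of BSJ record data.frames (see
#'   [parse_ciri2()]).
#' @param groups Two-level factor over the samples; the contrast is second
#'   level versus first.
#' @param linear_supplement Optional linear-count supplement for samples
#'   lacking a BSJ (see [complete_counts()]).
#' @param min_count,min_samples Expression-filter thresholds (defaults 2
#'   and 3).
#' @param dispersion NB dispersion or `"estimate"` (see [nb_lrt()]).
#' @param alpha Significance threshold on raw p-values (default 0.05).
#' @return List with the filtered `matrix`, TMM `factors`, full `de` table,
#'   `circ_de` and `lin_de` subsets, `cpm` matrix and the `pairs`
#'   classification.
#' @export
run_junction_de <- function(records, groups, linear_supplement = NULL,
                            min_count = 2L, min_samples = 3L,
                            dispersion = "estimate", alpha = 0.05) {
  m <- complete_counts(records, linear_supplement)
  mf <- expression_filter(m, min_count = min_count,
                          min_samples = min_samples)
  factors <- tmm_factors(mf)
  de <- nb_lrt(mf, groups, factors = factors, dispersion = dispersion,
               alpha = alpha)
  circ_de <- de[de$kind == "circ", , drop = FALSE]
  lin_de <- de[de$kind == "linear", , drop = FALSE]
  pairs <- classify_pairs(circ_de, lin_de, alpha = alpha)
  list(matrix = mf, factors = factors, de = de, circ_de = circ_de,
       lin_de = lin_de, cpm = cpm(mf, factors), pairs = pairs,
       alpha = alpha)
}

#' Meta-BSJ binding enrichment from differential results and peaks
#'
#' Builds the enrichment comparison behind the meta-BSJ heatmap: the
#' downregulated circRNAs (raw p below `alpha`, negative log2FC) are the
#' target set, the invariant circRNAs (p at or above `alpha`) the control
#' pool. Representative transcripts are selected, sliding windows placed
#' around both BSJ extremities, annotated with transcript-overlap
#' properties, matched `k`-to-1 from the invariant pool, and tested
#' per (extremity, offset) bin against each peak replicate.
#'
#' @param circ_de Circular differential results (`circ_id`, `log2fc`,
#'   `pvalue`) from [run_junction_de()].
#' @param circ_meta Coordinates per circRNA (`circ_id`, `chrom`, `start`,
#'   `end`, `strand`, optional `gene_id`); e.g. the `meta` element of the
#'   count matrix.
#' @param ann An `AnnotationModel`.
#' @param peaks Peak data.frame with `sample_id` replicates.
#' @param alpha Significance threshold defining down/invariant sets.
#' @param span,width,step Window geometry (see [make_windows()]).
#' @param k Matched controls per target window (default 2).
#' @return List with `bins` ([window_enrichment()] output), the annotated
#'   `target_windows` and `control_windows`, the `models` used, and the
#'   `down`/`invariant` id sets.
#' @export
meta_bsj_enrichment <- function(circ_de, circ_meta, ann, peaks,
                                alpha = 0.05, span = 1000L, width = 100L,
                                step = 10L, k = 2L) {
  down <- circ_de$circ_id[circ_de$pvalue < alpha & circ_de$log2fc < 0]
  invariant <- circ_de$circ_id[circ_de$pvalue >= alpha]
  if (length(down) == 0) stop("no downregulated circRNAs at alpha = ", alpha)
  if (length(invariant) == 0) stop("no invariant circRNAs to control with")
  meta <- circ_meta[match(c(down, invariant), circ_meta$circ_id), ,
                    drop = FALSE]
  if (anyNA(meta$chrom)) stop("circ_meta lacks coordinates for some ids")
  models <- lapply(seq_len(nrow(meta)), function(i) {
    representative_transcript(meta[i, ], ann)
  })
  names(models) <- meta$circ_id
  build <- function(ids) {
    w <- make_windows(meta[meta$circ_id %in% ids, , drop = FALSE],
                      span = span, width = width, step = step)
    window_props(w, models, ann)
  }
  target_windows <- build(down)
  control_pool <- build(invariant)
  control_windows <- match_controls(target_windows, control_pool, k = k)
  bins <- window_enrichment(target_windows, control_windows, peaks,
                            alpha = alpha)
  list(bins = bins, target_windows = target_windows,
       control_windows = control_windows, models = models,
       down = down, invariant = invariant)
}
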