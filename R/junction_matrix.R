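# Circular/linear junction count matrices: cross-sample completion,
# expression filtering, CPM conversion, top-expressed and high-confidence
# circRNA selection.

#' Build a complete circular/linear count matrix across samples
#'
#' The feature universe is the union of BSJs over all samples; every BSJ
#' contributes a circular feature (`<circ_id>|circ`, back-splicing junction
#' reads) and a paired linear feature (`<circ_id>|linear`, reads mapping
#' linearly over the same splice junctions). For a sample in which a BSJ was
#' not detected the circular count is 0 and the linear count is taken from
#' `linear_supplement` when provided (the linear-junction coverage recovered
#' by re-counting at those splice sites), otherwise 0. The result is dense:
#' no missing cells.
#'
#' @param per_sample_records A list of BSJ record data.frames (one per
#'   sample, see [parse_ciri2()]), or a single data.frame covering several
#'   samples (split on `sample_id`).
#' @param linear_supplement Optional data.frame (`circ_id`, `sample_id`,
#'   `linear_reads`) providing linear-junction counts for sample/BSJ
#'   combinations where the BSJ itself was not detected.
#' @return A `CountMatrix`: list with integer matrix `counts`
#'   (features x samples), data.frame `features` (`feature_id`, `circ_id`,
#'   `kind`), `samples`, and data.frame `meta` describing each circRNA
#'   (`circ_id`, `chrom`, `start`, `end`, `strand`, `gene_id`).
#' @export
complete_counts <- function(per_sample_records, linear_supplement = NULL) {
  if (is.data.frame(per_sample_records)) {
    per_sample_records <- split(per_sample_records,
                                per_sample_records$sample_id)
  }
  stopifnot(length(per_sample_records) >= 1)
  all_rec <- do.call(rbind, c(per_sample_records, list(make.row.names = FALSE)))
  samples <- unique(all_rec$sample_id)

  meta <- all_rec[!duplicated(all_rec$circ_id),
                  c("circ_id", "chrom", "start", "end", "strand", "gene_id")]
  meta <- meta[order(meta$circ_id), ]
  rownames(meta) <- NULL
  # strand consistency across samples: the id embeds chrom/start/end/strand,
  # so the same coordinates with differing strand yield distinct ids; detect
  # that situation explicitly.
  coord <- paste(meta$chrom, meta$start, meta$end)
  if (anyDuplicated(coord)) {
    stop("inconsistent strand across samples for coordinates: ",
         coord[duplicated(coord)][1])
  }

  n <- nrow(meta)
  circ <- matrix(0L, n, length(samples),
                 dimnames = list(meta$circ_id, samples))
  lin <- circ
  ri <- match(all_rec$circ_id, meta$circ_id)
  ci <- match(all_rec$sample_id, samples)
  circ[cbind(ri, ci)] <- all_rec$bsj_reads
  lin[cbind(ri, ci)] <- all_rec$linear_reads
  if (!is.null(linear_supplement) && nrow(linear_supplement) > 0) {
    si <- match(linear_supplement$circ_id, meta$circ_id)
    sj <- match(linear_supplement$sample_id, samples)
    keep <- !is.na(si) & !is.na(sj)
    idx <- cbind(si[keep], sj[keep])
    fill <- circ[idx] == 0L  # only samples lacking the BSJ are supplemented
    lin[idx[fill, , drop = FALSE]] <-
      as.integer(linear_supplement$linear_reads[keep][fill])
  }

  counts <- rbind(circ, lin)
  features <- data.frame(
    feature_id = c(paste0(meta$circ_id, "|circ"),
                   paste0(meta$circ_id, "|linear")),
    circ_id = rep(meta$circ_id, 2L),
    kind = rep(c("circ", "linear"), each = n),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- features$feature_id
  m <- list(counts = counts, features = features, samples = samples,
            meta = meta)
  class(m) <- "CountMatrix"
  m
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "features (",
      sum(x$features$kind == "circ"), "circ ) x",
      length(x$samples), "samples\n")
  invisible(x)
}

subset_count_matrix <- function(m, keep) {
  m$counts <- m$counts[keep, , drop = FALSE]
  m$features <- m$features[keep, , drop = FALSE]
  rownames(m$features) <- NULL
  m$meta <- m$meta[m$meta$circ_id %in% m$features$circ_id, , drop = FALSE]
  rownames(m$meta) <- NULL
  m
}

#' Filter features by minimum expression
#'
#' Keeps features having at least `min_count` counts in at least
#' `min_samples` samples. Circular and linear partners are filtered
#' independently: a circular junction can pass while its linear partner does
#' not, and vice versa. The operation is idempotent.
#'
#' @param m A `CountMatrix`.
#' @param min_count Minimum count per sample (default 2).
#' @param min_samples Minimum number of samples reaching `min_count`
#'   (default 3).
#' @param samples Optional subset of sample ids over which the rule is
#'   evaluated (default: all samples in `m`).
#' @return The filtered `CountMatrix`.
#' @export
expression_filter <- function(m, min_count = 2L, min_samples = 3L,
                              samples = NULL) {
  stopifnot(inherits(m, "CountMatrix"), min_count >= 0)
  cols <- if (is.null(samples)) seq_along(m$samples) else
    match(samples, m$samples)
  stopifnot(!anyNA(cols), min_samples <= length(cols))
  keep <- rowSums(m$counts[, cols, drop = FALSE] >= min_count) >= min_samples
  subset_count_matrix(m, keep)
}

#' Convert counts to counts per million
#'
#' Library size is the per-sample sum of counts over the whole junction
#' universe (circular plus linear features). When `factors` (e.g. from
#' [tmm_factors()]) is supplied the effective library size
#' `library x factor` is used instead.
#'
#' @param m A `CountMatrix`.
#' @param factors Optional named or positionally matched vector of
#'   per-sample normalization factors.
#' @return A `CpmMatrix`: same shape as `m` with numeric CPM values.
#' @export
cpm <- function(m, factors = NULL) {
  stopifnot(inherits(m, "CountMatrix"))
  lib <- colSums(m$counts)
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(m$samples[lib == 0], collapse = ", "))
  }
  if (!is.null(factors)) {
    if (!is.null(names(factors))) factors <- factors[m$samples]
    stopifnot(length(factors) == length(m$samples), all(factors > 0))
    lib <- lib * factors
  }
  out <- m
  out$values <- sweep(m$counts, 2L, lib, "/") * 1e6
  out$counts <- NULL
  class(out) <- "CpmMatrix"
  out
}

#' @export
print.CpmMatrix <- function(x, ...) {
  cat("CpmMatrix:", nrow(x$values), "features x", length(x$samples),
      "samples\n")
  invisible(x)
}

#' Select the top-expressed circular features
#'
#' Circular features are ranked by mean CPM over `samples` (default all) and
#' the top `ceiling(fraction * n)` are returned. Ties are broken by feature
#' id (lexicographically first kept).
#'
#' @param m A `CpmMatrix`.
#' @param fraction Fraction of circular features to keep (default 0.2).
#' @param samples Optional subset of sample ids defining the contrast.
#' @return Character vector of circRNA ids.
#' @export
top_expressed <- function(m, fraction = 0.2, samples = NULL) {
  stopifnot(inherits(m, "CpmMatrix"), fraction > 0, fraction <= 1)
  circ <- m$features$kind == "circ"
  if (!any(circ)) stop("no circular features in matrix")
  cols <- if (is.null(samples)) seq_along(m$samples) else
    match(samples, m$samples)
  stopifnot(!anyNA(cols))
  means <- rowMeans(m$values[circ, cols, drop = FALSE])
  ids <- m$features$circ_id[circ]
  ord <- order(-means, ids)
  ids[ord][seq_len(ceiling(fraction * length(ids)))]
}

#' High-confidence circRNAs: three-detector intersection
#'
#' A circRNA is high-confidence when called independently by all three
#' detection tools. With `slack = 0` the intersection is on exact
#' identifiers; with `slack > 0` calls match when chromosome and strand agree
#' and both junction coordinates differ by at most `slack` nt (detectors can
#' disagree on the exact junction base).
#'
#' @param ciri,tool2,tool3 Character vectors of circRNA ids (see
#'   [circ_id()]).
#' @param slack Coordinate slack in nt (0-2, default 0).
#' @return The ids from `ciri` supported by all three tools.
#' @export
high_confidence <- function(ciri, tool2, tool3, slack = 0L) {
  stopifnot(slack >= 0L, slack <= 2L)
  if (slack == 0L) {
    return(intersect(intersect(ciri, tool2), tool3))
  }
  supported <- function(ids, other) {
    if (length(ids) == 0 || length(other) == 0) return(character())
    a <- parse_circ_id(ids)
    b <- parse_circ_id(other)
    hit <- vapply(seq_len(nrow(a)), function(i) {
      any(b$chrom == a$chrom[i] & b$strand == a$strand[i] &
            abs(b$start - a$start[i]) <= slack &
            abs(b$end - a$end[i]) <= slack)
    }, logical(1))
    ids[hit]
  }
  supported(supported(ciri, tool2), tool3)
}

#' Write a count matrix as TSV
#'
#' Features x samples with a header row; first two columns `feature_id` and
#' `kind`, then one integer column per sample.
#'
#' @param m A `CountMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  out <- data.frame(feature_id = m$features$feature_id,
                    kind = m$features$kind,
                    m$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path TSV path.
#' @return A `CountMatrix` (without coordinate metadata: `meta` is derived
#'   from the circRNA ids).
#' @export
read_count_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("feature_id", "kind") %in% names(tab)))
  counts <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$feature_id
  circ_ids <- sub("\\|(circ|linear)$", "", tab$feature_id)
  meta <- parse_circ_id(unique(circ_ids))
  meta$gene_id <- NA_character_
  m <- list(counts = counts,
            features = data.frame(feature_id = tab$feature_id,
                                  circ_id = circ_ids, kind = tab$kind,
                                  stringsAsFactors = FALSE),
            samples = colnames(counts),
            meta = meta)
  class(m) <- "CountMatrix"
  m
}
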