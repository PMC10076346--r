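# Shared helpers: circRNA identifiers and 2x2 table statistics.

#' Build a circRNA identifier from coordinates
#'
#' The identifier follows the CIRI2 convention `chrom:start-end:strand` with a
#' 1-based inclusive start for readability, while all coordinate fields held
#' in package objects stay 0-based half-open.
#'
#' @param chrom Chromosome name.
#' @param start,end Internal (0-based half-open) interval.
#' @param strand `"+"` or `"-"`.
#' @return Character vector of identifiers.
#' @export
#' @examples
#' circ_id("chr1", 100L, 200L, "+")
circ_id <- function(chrom, start, end, strand) {
  stopifnot(all(start < end), all(strand %in% c("+", "-")))
  sprintf("%s:%d-%d:%s", chrom, as.integer(start) + 1L, as.integer(end), strand)
}

#' Parse circRNA identifiers back into coordinates
#'
#' @param id Identifiers produced by [circ_id()].
#' @return A data.frame with `circ_id`, `chrom`, `start`, `end`, `strand`
#'   (internal 0-based half-open coordinates).
#' @export
parse_circ_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+):([+-])$", id))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("malformed circRNA id: ", paste(utils::head(id[bad], 3L), collapse = ", "))
  }
  data.frame(
    circ_id = id,
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)) - 1L,
    end = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

# Sample odds ratio of a 2x2 table c(a, b, c, d) laid out by row.
# Haldane-Anscombe 0.5 correction applied when any cell is zero (reporting
# only; p-values are computed by the exact test on the uncorrected table).
sample_odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

# Two-sided Fisher exact test on a 2x2 table; returns the p-value and the
# sample odds ratio (not the conditional MLE).
fisher_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), nrow = 2L)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(odds_ratio = sample_odds_ratio(a, b, c, d), p = p)
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stream label
# so that each synthetic output has its own RNG stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1103L + h * 12289) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# sample() safe against the length-1 "sample from 1:x" surprise
sample1 <- function(x) x[sample.int(length(x), 1L)]
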