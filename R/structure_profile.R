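# Peak-summit metaprofiles of predicted folding free energy and GC content
# over summit-centered windows, with a pluggable folding backend.

#' Resolve overlapping peaks by keeping the longest
#'
#' Within each connected component of mutually overlapping peaks only the
#' longest peak survives; ties are broken by the lowest start. When a
#' `sample_id` column with several replicates is present, merging is done
#' within each replicate.
#'
#' @param peaks Peak data.frame ([parse_narrowpeak()]).
#' @return The reduced peak data.frame.
#' @export
merge_longest <- function(peaks) {
  if (nrow(peaks) <= 1) return(peaks)
  if (!is.null(peaks$sample_id) && length(unique(peaks$sample_id)) > 1) {
    out <- do.call(rbind, lapply(split(peaks, peaks$sample_id), merge_longest))
    rownames(out) <- NULL
    return(out)
  }
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(peaks)), peaks$chrom), function(i) {
    s <- peaks$start[i]; e <- peaks$end[i]
    run_max <- cummax(c(0L, e[-length(e)]))
    comp <- cumsum(s >= run_max | seq_along(i) == 1L)
    vapply(split(seq_along(i), comp), function(j) {
      len <- e[j] - s[j]
      i[j][order(-len, s[j])][1]
    }, integer(1))
  }), use.names = FALSE)
  out <- peaks[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GC fraction of sequences
#'
#' `(G + C) / (A + C + G + T/U)`; `N` bases are excluded from both numerator
#' and denominator. Sequences consisting only of `N` return `NA`.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  up <- toupper(seq)
  if (any(grepl("[^ACGUTN]", up))) stop("invalid characters in sequence")
  gc <- nchar(gsub("[^GC]", "", up))
  at <- nchar(gsub("[^AUT]", "", up))
  ifelse(gc + at == 0, NA_real_, gc / (gc + at))
}

#' Predicted minimum folding free energy of RNA sequences
#'
#' The builtin backend computes the optimal nested secondary structure under
#' a simplified base-pair energy model (GC = -3, AU = -2, GU = -1 kcal/mol,
#' minimum hairpin loop of 3 nt, no pseudoknots) by dynamic programming; a
#' structureless sequence scores 0. The external backend calls the
#' thermodynamic `RNAfold` engine when it is on the `PATH` and returns its
#' minimum free energy.
#'
#' @param seq Character vector of sequences over `A`, `C`, `G`, `U`/`T`,
#'   `N`.
#' @param backend `"builtin"` (default) or `"external"`.
#' @param min_loop Minimum hairpin loop length for the builtin model
#'   (default 3).
#' @return Numeric vector of folding energies (kcal/mol, all `<= 0`).
#' @export
fold_dG <- function(seq, backend = c("builtin", "external"), min_loop = 3L) {
  backend <- match.arg(backend)
  stopifnot(all(nchar(seq) >= 1))
  if (backend == "builtin") {
    return(.fold_energy_cpp(seq, min_loop))
  }
  if (Sys.which("RNAfold") == "") {
    stop("external folding backend requested but RNAfold is not on the PATH")
  }
  if (any(grepl("[^ACGUTNacgutn]", seq))) stop("invalid characters in sequence")
  out <- system2("RNAfold", args = c("--noPS"), input = seq, stdout = TRUE)
  mfe_lines <- grep("\\(\\s*-?[0-9.]+\\)$", out, value = TRUE)
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", mfe_lines))
}

#' Strand-oriented position-centered subsequences of a summit window
#'
#' For each summit-relative offset the `(2*flank + 1)` nt subsequence
#' centered on that position is extracted in the orientation of the
#' associated circRNA's strand (reverse-complemented for minus-strand).
#' Offsets whose full extent leaves the chromosome are skipped.
#'
#' @param summit Absolute summit coordinate (0-based).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"` (strand of the associated circRNA).
#' @param genome A `Biostrings::DNAStringSet` (or FASTA path).
#' @param offsets Summit-relative offsets (default `-250:249`, summit
#'   centered in a 500 nt window).
#' @param flank Flank on each side of the position (default 75, i.e. 151 nt
#'   subsequences).
#' @return Named character vector of subsequences (names = offsets).
#' @export
position_sequences <- function(summit, chrom, strand, genome,
                               offsets = -250:249, flank = 75L) {
  genome <- load_genome(genome)
  if (!chrom %in% names(genome)) stop("genome does not cover ", chrom)
  chrom_len <- Biostrings::width(genome[chrom])
  centers <- if (strand == "+") summit + offsets else summit - offsets
  ok <- centers - flank >= 0L & centers + flank < chrom_len
  centers <- centers[ok]
  if (length(centers) == 0) return(stats::setNames(character(0), character(0)))
  v <- Biostrings::Views(genome[[chrom]],
                         start = centers - flank + 1L,
                         end = centers + flank + 1L)
  seqs <- as.character(v)
  if (strand == "-") {
    seqs <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  }
  stats::setNames(seqs, offsets[ok])
}

load_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Metaprofile of folding energy and GC content around peak summits
#'
#' For each summit-relative offset, the mean predicted folding energy and
#' mean GC fraction of the position-centered subsequences
#' ([position_sequences()]) are averaged over all summit windows. Summit
#' windows span `-half_window .. half_window - 1` (summit at the center of
#' an even-length window).
#'
#' @param peaks Peak data.frame with `chrom` and `summit` columns plus a
#'   `strand` column (strand of the associated circRNA; defaults to `"+"`
#'   when absent). Overlapping peaks should be resolved first with
#'   [merge_longest()].
#' @param genome A `Biostrings::DNAStringSet` or FASTA path.
#' @param half_window Half-width of the summit window (default 250).
#' @param flank Flank of the per-position folding substrate (default 75).
#' @param stride Offset stride; `stride > 1` profiles every `stride`-th
#'   position (offset 0 is always included).
#' @param backend Folding backend passed to [fold_dG()].
#' @return A data.frame of profile points: `offset`, `mean_dG`, `mean_gc`,
#'   `n` (contributing windows). Offsets with no contributing window are
#'   omitted.
#' @export
metaprofile <- function(peaks, genome, half_window = 250L, flank = 75L,
                        stride = 1L, backend = "builtin") {
  stopifnot(nrow(peaks) >= 1)
  genome <- load_genome(genome)
  # stride-thinned offsets, always anchored so that offset 0 is profiled
  offsets <- sort(unique(c(seq.int(0L, -half_window, by = -stride),
                           seq.int(0L, half_window - 1L, by = stride))))
  strand <- peaks$strand %||% rep("+", nrow(peaks))
  acc <- list()
  for (i in seq_len(nrow(peaks))) {
    seqs <- position_sequences(peaks$summit[i], peaks$chrom[i], strand[i],
                               genome, offsets = offsets, flank = flank)
    if (length(seqs) == 0) next
    acc[[length(acc) + 1L]] <- data.frame(
      offset = as.integer(names(seqs)),
      dG = fold_dG(seqs, backend = backend),
      gc = gc_content(seqs)
    )
  }
  if (length(acc) == 0) stop("no summit window fits inside the genome")
  all <- do.call(rbind, acc)
  agg <- split(all, all$offset)
  out <- data.frame(
    offset = as.integer(names(agg)),
    mean_dG = vapply(agg, function(x) mean(x$dG), numeric(1)),
    mean_gc = vapply(agg, function(x) mean(x$gc, na.rm = TRUE), numeric(1)),
    n = vapply(agg, nrow, integer(1))
  )
  out <- out[order(out$offset), ]
  rownames(out) <- NULL
  out
}
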