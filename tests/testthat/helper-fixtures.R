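# Small in-code fixtures shared across tests.

# Annotation model built directly (no file round trip): one gene with
# configurable isoforms. `exons` is a list of matrices/data.frames with
# columns start, end (0-based half-open), one element per transcript.
make_ann <- function(exons, strand = "+", gene_biotype = "protein_coding",
                     tx_biotypes = NULL, chrom = "chr1",
                     gene_id = "G1", cds = list(), utr5 = list(),
                     utr3 = list()) {
  tx_ids <- sprintf("T%d", seq_along(exons))
  if (is.null(tx_biotypes)) tx_biotypes <- rep(gene_biotype, length(exons))
  exon_rows <- do.call(rbind, lapply(seq_along(exons), function(i) {
    e <- as.data.frame(exons[[i]])
    names(e) <- c("start", "end")
    e <- e[order(e$start, decreasing = strand == "-"), ]
    data.frame(transcript_id = tx_ids[i], exon_number = seq_len(nrow(e)),
               chrom = chrom, start = e$start, end = e$end, strand = strand,
               stringsAsFactors = FALSE)
  }))
  sub_rows <- function(lst) {
    if (length(lst) == 0) {
      return(data.frame(transcript_id = character(), chrom = character(),
                        start = integer(), end = integer()))
    }
    do.call(rbind, lapply(names(lst), function(t) {
      e <- as.data.frame(lst[[t]])
      names(e) <- c("start", "end")
      data.frame(transcript_id = t, chrom = chrom, start = e$start,
                 end = e$end, stringsAsFactors = FALSE)
    }))
  }
  ann <- list(
    genes = data.frame(gene_id = gene_id, biotype = gene_biotype,
                       chrom = chrom, strand = strand,
                       stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = tx_ids, gene_id = gene_id,
                             biotype = tx_biotypes, chrom = chrom,
                             strand = strand, stringsAsFactors = FALSE),
    exons = exon_rows,
    cds = sub_rows(cds), utr5 = sub_rows(utr5), utr3 = sub_rows(utr3)
  )
  class(ann) <- "AnnotationModel"
  ann
}

make_circ <- function(chrom = "chr1", start = 100L, end = 1000L,
                      strand = "+", gene_id = "G1",
                      bsj = 10L, lin = 20L, sample_id = "s1") {
  data.frame(circ_id = circ_id(chrom, start, end, strand),
             chrom = chrom, start = start, end = end, strand = strand,
             gene_id = gene_id, bsj_reads = bsj, linear_reads = lin,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

make_peaks <- function(start, end, sample_id = "rep1", chrom = "chr1",
                       summit = NULL, signal = 10) {
  if (is.null(summit)) summit <- (start + end) %/% 2L
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             summit = as.integer(summit), signal = signal,
             sample_id = sample_id, stringsAsFactors = FALSE)
}
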