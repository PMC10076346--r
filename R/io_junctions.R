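# Ingestion of CIRI2-style junction tables, GTF annotation and narrowPeak
# files into internal types. One coordinate convention everywhere: 0-based
# half-open. CIRI2 and GTF inputs (1-based inclusive) are converted exactly
# once, at parse time; writers emit the external convention again.

#' Parse a CIRI2-style back-splicing junction table
#'
#' Reads one sample's BSJ table in the tab-separated dialect used throughout
#' the package: header columns `circRNA_ID`, `chr`, `circRNA_start`,
#' `circRNA_end`, `strand`, `gene_id`, `junction_reads`, `linear_reads`, with
#' 1-based inclusive coordinates. `junction_reads` counts reads spanning the
#' back-splicing junction; `linear_reads` is the sum of reads mapping
#' linearly over both splice junctions involved in the back-splicing event.
#'
#' @param path Path to the table.
#' @param sample_id Sample identifier attached to every record.
#' @return A data.frame of BSJ records with columns `circ_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `gene_id`, `bsj_reads`,
#'   `linear_reads`, `sample_id`.
#' @export
parse_ciri2 <- function(path, sample_id) {
  req <- c("circRNA_ID", "chr", "circRNA_start", "circRNA_end", "strand",
           "gene_id", "junction_reads", "linear_reads")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
  names(tab) <- sub("^X\\.", "#", names(tab))
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    stop("CIRI2 table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    return(empty_bsj_records())
  }
  line_no <- seq_len(nrow(tab)) + 1L  # +1 for the header line
  bad_strand <- !(tab$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop("unknown strand symbol '", tab$strand[which(bad_strand)[1]],
         "' at line ", line_no[which(bad_strand)[1]], " of ", path)
  }
  start1 <- suppressWarnings(as.integer(tab$circRNA_start))
  end1 <- suppressWarnings(as.integer(tab$circRNA_end))
  bsj <- suppressWarnings(as.integer(tab$junction_reads))
  lin <- suppressWarnings(as.integer(tab$linear_reads))
  bad <- is.na(start1) | is.na(end1) | is.na(bsj) | is.na(lin) |
    start1 < 1L | start1 > end1 | bsj < 0L | lin < 0L
  if (any(bad)) {
    stop("malformed row at line ", line_no[which(bad)[1]], " of ", path)
  }
  rec <- data.frame(
    circ_id = circ_id(tab$chr, start1 - 1L, end1, tab$strand),
    chrom = tab$chr,
    start = start1 - 1L,
    end = end1,
    strand = tab$strand,
    gene_id = as.character(tab$gene_id),
    bsj_reads = bsj,
    linear_reads = lin,
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  rec$gene_id[rec$gene_id %in% c("", "n/a", "NA")] <- NA_character_
  multi <- grepl(",", rec$gene_id)
  if (any(multi)) {
    warning("multiple gene ids for ", sum(multi),
            " BSJ(s); keeping the first")
    rec$gene_id[multi] <- sub(",.*$", "", rec$gene_id[multi])
  }
  if (anyDuplicated(rec$circ_id)) {
    stop("duplicate BSJ in sample ", sample_id, ": ",
         rec$circ_id[duplicated(rec$circ_id)][1])
  }
  rownames(rec) <- NULL
  rec
}

empty_bsj_records <- function() {
  data.frame(
    circ_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), gene_id = character(),
    bsj_reads = integer(), linear_reads = integer(), sample_id = character(),
    stringsAsFactors = FALSE
  )
}

#' Write BSJ records to the CIRI2-style dialect
#'
#' Inverse of [parse_ciri2()]: internal 0-based half-open coordinates are
#' written back as 1-based inclusive, so a write/parse round trip reproduces
#' the records exactly.
#'
#' @param records BSJ record data.frame from [parse_ciri2()] (one sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ciri2 <- function(records, path) {
  out <- data.frame(
    circRNA_ID = records$circ_id,
    chr = records$chrom,
    circRNA_start = records$start + 1L,
    circRNA_end = records$end,
    strand = records$strand,
    gene_id = ifelse(is.na(records$gene_id), "n/a", records$gene_id),
    junction_reads = records$bsj_reads,
    linear_reads = records$linear_reads,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a GTF file into an annotation model
#'
#' Uses `rtracklayer` to read the GTF (Ensembl dialect) and assembles a
#' light-weight annotation model: genes with biotype, transcripts with
#' ordered exons (numbered 1..n in transcript 5'-to-3' order) and CDS/UTR
#' sub-features. Exon numbers are taken from the `exon_number` attribute when
#' present, otherwise derived by strand-aware sorting. All intervals are
#' converted to 0-based half-open coordinates.
#'
#' @param path Path to a GTF file.
#' @return An object of class `AnnotationModel`: a list with data.frames
#'   `genes` (`gene_id`, `biotype`, `chrom`, `strand`), `transcripts`
#'   (`transcript_id`, `gene_id`, `biotype`, `chrom`, `strand`), `exons`
#'   (`transcript_id`, `exon_number`, `chrom`, `start`, `end`, `strand`),
#'   `cds`, `utr5`, `utr3` (each `transcript_id`, `chrom`, `start`, `end`).
#' @export
parse_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    type = as.character(gr$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    stringsAsFactors = FALSE
  )
  df$transcript_id <- if ("transcript_id" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$transcript_id)
  } else {
    NA_character_
  }
  df$gene_biotype <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$gene_biotype)
  } else {
    NA_character_
  }
  df$transcript_biotype <-
    if ("transcript_biotype" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$transcript_biotype)
    } else {
      NA_character_
    }
  df$exon_number <- if ("exon_number" %in% names(S4Vectors::mcols(gr))) {
    suppressWarnings(as.integer(as.character(gr$exon_number)))
  } else {
    NA_integer_
  }

  is_exon <- df$type == "exon"
  if (any(is_exon & (is.na(df$transcript_id) | df$transcript_id == ""))) {
    stop("exon feature without transcript parent in ", path)
  }

  genes <- df[df$type == "gene", c("gene_id", "gene_biotype", "chrom", "strand")]
  names(genes)[2] <- "biotype"
  if (nrow(genes) == 0) {  # derive genes from child features
    src <- df[!is.na(df$gene_id), ]
    genes <- unique(src[, c("gene_id", "gene_biotype", "chrom", "strand")])
    names(genes)[2] <- "biotype"
  }
  genes <- genes[!duplicated(genes$gene_id), ]
  rownames(genes) <- NULL

  tx <- df[df$type == "transcript",
           c("transcript_id", "gene_id", "transcript_biotype", "chrom", "strand")]
  names(tx)[3] <- "biotype"
  ex <- df[is_exon, c("transcript_id", "exon_number", "chrom", "start", "end",
                      "strand", "gene_id", "transcript_biotype")]
  if (nrow(tx) == 0 && nrow(ex) > 0) {  # transcripts implied by exons
    tx <- unique(ex[, c("transcript_id", "gene_id", "transcript_biotype",
                        "chrom", "strand")])
    names(tx)[3] <- "biotype"
  }
  tx <- tx[!duplicated(tx$transcript_id), ]
  miss_bio <- is.na(tx$biotype)
  if (any(miss_bio)) {
    tx$biotype[miss_bio] <-
      genes$biotype[match(tx$gene_id[miss_bio], genes$gene_id)]
  }
  rownames(tx) <- NULL

  exons <- ex[, c("transcript_id", "exon_number", "chrom", "start", "end", "strand")]
  if (nrow(exons) > 0) {
    need_num <- tapply(is.na(exons$exon_number), exons$transcript_id, any)
    for (t in names(need_num)[need_num]) {
      i <- which(exons$transcript_id == t)
      ord <- order(exons$start[i],
                   decreasing = exons$strand[i][1] == "-")
      exons$exon_number[i[ord]] <- seq_along(i)
    }
    exons <- exons[order(exons$transcript_id, exons$exon_number), ]
    overlap_bad <- vapply(split(exons, exons$transcript_id), function(e) {
      e <- e[order(e$start), ]
      nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])
    }, logical(1))
    if (any(overlap_bad)) {
      stop("overlapping exons within transcript(s): ",
           paste(names(overlap_bad)[overlap_bad], collapse = ", "))
    }
  }
  rownames(exons) <- NULL

  sub_feature <- function(types) {
    s <- df[df$type %in% types, c("transcript_id", "chrom", "start", "end")]
    rownames(s) <- NULL
    s
  }
  model <- list(
    genes = genes,
    transcripts = tx,
    exons = exons,
    cds = sub_feature("CDS"),
    utr5 = sub_feature(c("five_prime_utr", "5UTR")),
    utr3 = sub_feature(c("three_prime_utr", "3UTR"))
  )
  class(model) <- "AnnotationModel"
  model
}

#' @export
print.AnnotationModel <- function(x, ...) {
  cat("AnnotationModel:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Parse an ENCODE narrowPeak file
#'
#' Reads a BED6+4 narrowPeak file and computes the absolute summit position
#' (`start + offset`). When the summit offset is `-1` (summit not called) the
#' interval midpoint is used instead.
#'
#' @param path Path to a narrowPeak file (no header).
#' @param sample_id Replicate identifier attached to every peak.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `summit` (absolute coordinate), `signal`, `sample_id`.
#' @export
parse_narrowpeak <- function(path, sample_id) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 10) {
    stop("narrowPeak file ", path, " has ", ncol(tab),
         " columns; 10 required")
  }
  start <- as.integer(tab[[2]])
  end <- as.integer(tab[[3]])
  offset <- as.integer(tab[[10]])
  if (any(is.na(start) | is.na(end) | start < 0L)) {
    stop("invalid peak interval at line ",
         which(is.na(start) | is.na(end) | start < 0L)[1], " of ", path)
  }
  if (any(start >= end)) {
    stop("empty peak interval at line ", which(start >= end)[1], " of ", path)
  }
  summit <- ifelse(offset >= 0L, start + offset, (start + end) %/% 2L)
  if (any(summit < start | summit >= end)) {
    stop("summit outside peak at line ",
         which(summit < start | summit >= end)[1], " of ", path)
  }
  data.frame(
    chrom = as.character(tab[[1]]),
    start = start,
    end = end,
    summit = as.integer(summit),
    signal = as.numeric(tab[[7]]),
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
}

#' Write peaks as narrowPeak
#'
#' @param peaks Peak data.frame as returned by [parse_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(
    chrom = peaks$chrom,
    start = peaks$start,
    end = peaks$end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = 0L,
    strand = ".",
    signalValue = peaks$signal,
    pValue = -1,
    qValue = -1,
    peak = peaks$summit - peaks$start,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
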