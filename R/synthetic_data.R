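# Synthetic study generator: a toy genome and annotation, per-sample
# junction tables with planted concordance categories and fold changes, and
# RIP-seq peak files with planted BSJ-proximal binding and GC-rich summits.
# Every stage of the pipeline can be scored against the emitted truth table.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' a two-condition design with 3 replicates per group, negative-binomial
#' junction counts (back-splicing mean 100, linear mean 300, dispersion
#' 0.1), planted effects of |log2FC| = 2 distributed over concordance
#' categories with a 0.8 down-fraction among deregulated circRNAs (the
#' helicase knock-down situation, where downregulation dominates), and
#' binding peaks planted within 100 nt of the 5' back-splice donor site of
#' downregulated circRNAs in at least 2 of 3 replicates, with GC-rich
#' 30 nt summit motifs.
#'
#' @param n_circ Number of circRNA-producing genes (one circRNA each).
#' @param n_extra_genes Additional genes without circRNAs.
#' @param exons_per_gene Integer range of exon counts per transcript.
#' @param circ_exons Integer range of exons included in a circRNA.
#' @param samples_per_group Replicates per condition.
#' @param category_fractions Named fractions over the four planted
#'   concordance categories (must sum to 1).
#' @param prop_down Fraction of deregulated circRNAs that are downregulated.
#' @param lfc Planted absolute log2 fold change.
#' @param bsj_mu,linear_mu Baseline NB means for back-splicing and linear
#'   junction counts.
#' @param dispersion NB dispersion.
#' @param dropout_fraction Fraction of circRNAs detected in only one
#'   group's samples (exercises cross-sample completion).
#' @param peak_rule `"near_bsj"` (peaks within `peak_max_dist` of the 5'
#'   donor site of downregulated circRNAs) or `"uniform"`.
#' @param peak_max_dist,peak_width Peak placement distance and width (nt).
#' @param n_replicates Number of peak replicates.
#' @param n_background_peaks Uniformly placed peaks added per replicate.
#' @param motif_gc,motif_len Peak GC fraction and extent of the summit
#'   motif planted into the genome (GC tapers linearly from `motif_gc` at
#'   the summit to the background at `motif_len/2` away);
#'   `plant_motif = FALSE` disables planting.
#' @param plant_motif Whether to write the summit motif into the genome.
#' @param lincRNA_fraction Fraction of genes with biotype `lincRNA`.
#' @param background_gc Genome background GC fraction.
#' @param exon_len,intron_len,intergenic Structural length ranges (nt).
#' @param chrom Chromosome name.
#' @return A `ScenarioConfig` list.
#' @export
scenario_config <- function(n_circ = 48L,
                            n_extra_genes = 8L,
                            exons_per_gene = c(3L, 6L),
                            circ_exons = c(1L, 3L),
                            samples_per_group = 3L,
                            category_fractions = c(Concordant = 0.15,
                                                   DiscordantCirc = 0.35,
                                                   DiscordantLin = 0.10,
                                                   Unaltered = 0.40),
                            prop_down = 0.8,
                            lfc = 2,
                            bsj_mu = 100,
                            linear_mu = 300,
                            dispersion = 0.1,
                            dropout_fraction = 0.1,
                            peak_rule = c("near_bsj", "uniform"),
                            peak_max_dist = 100L,
                            peak_width = 200L,
                            n_replicates = 3L,
                            n_background_peaks = 10L,
                            motif_gc = 0.9,
                            motif_len = 150L,
                            plant_motif = TRUE,
                            lincRNA_fraction = 0.15,
                            background_gc = 0.45,
                            exon_len = c(150L, 300L),
                            intron_len = c(400L, 900L),
                            intergenic = 3000L,
                            chrom = "chrS1") {
  stopifnot(abs(sum(category_fractions) - 1) < 1e-8,
            bsj_mu > 0, linear_mu > 0, dispersion >= 0)
  cfg <- as.list(environment())
  cfg$peak_rule <- match.arg(peak_rule)
  class(cfg) <- "ScenarioConfig"
  cfg
}

rand_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a toy genome and annotation
#'
#' Genes with multi-exonic transcripts (one transcript per gene) are tiled
#' along a single random-sequence chromosome. Protein-coding transcripts
#' carry 5'UTR/CDS/3'UTR sub-features (first half of the first exon and last
#' half of the last exon, in transcript orientation, are UTR); `lincRNA`
#' genes have exons only. Deterministic given the seed.
#'
#' @param cfg A `ScenarioConfig`.
#' @param seed Integer seed for this component's RNG stream.
#' @return List with `genome` (`DNAStringSet`) and `ann`
#'   (`AnnotationModel`).
#' @export
gen_genome_annotation <- function(cfg, seed = 1L) {
  set.seed(derive_seed(seed, "genome"))
  n_genes <- cfg$n_circ + cfg$n_extra_genes
  genes <- list(); exons <- list()
  pos <- cfg$intergenic
  for (g in seq_len(n_genes)) {
    gid <- sprintf("GENE%03d", g)
    tid <- sprintf("TX%03d", g)
    strand <- sample(c("+", "-"), 1L)
    biotype <- if (stats::runif(1) < cfg$lincRNA_fraction) "lincRNA" else
      "protein_coding"
    n_ex <- sample1(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]))
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    p <- pos
    for (e in seq_len(n_ex)) {
      w <- sample1(seq(cfg$exon_len[1], cfg$exon_len[2]))
      ex_start[e] <- p
      ex_end[e] <- p + w
      p <- ex_end[e] +
        if (e < n_ex) sample1(seq(cfg$intron_len[1], cfg$intron_len[2]))
        else 0L
    }
    genes[[g]] <- data.frame(gene_id = gid, transcript_id = tid,
                             biotype = biotype, chrom = cfg$chrom,
                             strand = strand, stringsAsFactors = FALSE)
    num <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    exons[[g]] <- data.frame(transcript_id = tid, exon_number = num,
                             chrom = cfg$chrom, start = ex_start,
                             end = ex_end, strand = strand,
                             stringsAsFactors = FALSE)
    pos <- p + cfg$intergenic
  }
  gene_tab <- do.call(rbind, genes)
  exon_tab <- do.call(rbind, exons)
  exon_tab <- exon_tab[order(exon_tab$transcript_id, exon_tab$exon_number), ]
  rownames(exon_tab) <- NULL

  # CDS/UTR: in transcript orientation, the first half of exon 1 is 5'UTR
  # and the last half of the terminal exon is 3'UTR; the rest is CDS.
  cds <- list(); utr5 <- list(); utr3 <- list()
  for (t in unique(exon_tab$transcript_id)) {
    bt <- gene_tab$biotype[gene_tab$transcript_id == t]
    if (bt != "protein_coding") next
    e <- exon_tab[exon_tab$transcript_id == t, ]
    e <- e[order(e$exon_number), ]
    n <- nrow(e)
    plus <- e$strand[1] == "+"
    first <- e[1, ]; last <- e[n, ]
    mid5 <- first$start + (first$end - first$start) %/% 2L
    mid3 <- last$start + (last$end - last$start) %/% 2L
    if (plus) {
      utr5[[t]] <- data.frame(transcript_id = t, chrom = first$chrom,
                              start = first$start, end = mid5)
      utr3[[t]] <- data.frame(transcript_id = t, chrom = last$chrom,
                              start = mid3, end = last$end)
      cds_rows <- rbind(
        data.frame(transcript_id = t, chrom = first$chrom,
                   start = mid5, end = first$end),
        if (n > 2) data.frame(transcript_id = t, chrom = e$chrom[2:(n - 1)],
                              start = e$start[2:(n - 1)],
                              end = e$end[2:(n - 1)]),
        data.frame(transcript_id = t, chrom = last$chrom,
                   start = last$start, end = mid3))
    } else {
      utr5[[t]] <- data.frame(transcript_id = t, chrom = first$chrom,
                              start = mid5, end = first$end)
      utr3[[t]] <- data.frame(transcript_id = t, chrom = last$chrom,
                              start = last$start, end = mid3)
      cds_rows <- rbind(
        data.frame(transcript_id = t, chrom = first$chrom,
                   start = first$start, end = mid5),
        if (n > 2) data.frame(transcript_id = t, chrom = e$chrom[2:(n - 1)],
                              start = e$start[2:(n - 1)],
                              end = e$end[2:(n - 1)]),
        data.frame(transcript_id = t, chrom = last$chrom,
                   start = mid3, end = last$end))
    }
    cds[[t]] <- cds_rows[cds_rows$end > cds_rows$start, ]
  }
  bind_or_empty <- function(lst) {
    if (length(lst) == 0) {
      return(data.frame(transcript_id = character(), chrom = character(),
                        start = integer(), end = integer()))
    }
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }

  chrom_len <- max(exon_tab$end) + cfg$intergenic
  seq <- rand_seq(chrom_len, cfg$background_gc)
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, cfg$chrom))

  ann <- list(
    genes = data.frame(gene_id = gene_tab$gene_id,
                       biotype = gene_tab$biotype,
                       chrom = gene_tab$chrom, strand = gene_tab$strand,
                       stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = gene_tab$transcript_id,
                             gene_id = gene_tab$gene_id,
                             biotype = gene_tab$biotype,
                             chrom = gene_tab$chrom,
                             strand = gene_tab$strand,
                             stringsAsFactors = FALSE),
    exons = exon_tab,
    cds = bind_or_empty(cds),
    utr5 = bind_or_empty(utr5),
    utr3 = bind_or_empty(utr3)
  )
  class(ann) <- "AnnotationModel"
  list(genome = genome, ann = ann)
}

plant_category <- function(cfg, n) {
  counts <- round(cfg$category_fractions * n)
  counts[1] <- counts[1] + n - sum(counts)  # absorb rounding drift
  rep(names(cfg$category_fractions), counts)
}

#' Generate per-sample junction tables with planted truth
#'
#' One circRNA per circ-host gene, with BSJ boundaries on exon junctions.
#' Back-splicing and linear junction counts are drawn from NB distributions
#' with group means scaled by the planted log2 fold changes of each
#' concordance category (condition vs control); linear counts of
#' `DiscordantCirc` circRNAs are drawn at log2FC 0. A configurable fraction
#' of circRNAs is "detected" only in the group with higher circular
#' expression: their BSJ rows are dropped from the other group's tables and
#' the linear-junction coverage at those splice sites is reported in a
#' supplement table, exercising [complete_counts()].
#'
#' @param cfg A `ScenarioConfig`.
#' @param world Output of [gen_genome_annotation()].
#' @param seed Integer seed for this component's RNG stream.
#' @return List with `records` (per-sample list of BSJ record data.frames),
#'   `linear_supplement`, `truth` (per circRNA: planted category and
#'   log2FCs), `samples` and `groups`.
#' @export
gen_counts <- function(cfg, world, seed = 1L) {
  set.seed(derive_seed(seed, "counts"))
  ann <- world$ann
  circ_genes <- ann$genes$gene_id[seq_len(cfg$n_circ)]
  samples <- c(sprintf("ctrl_%d", seq_len(cfg$samples_per_group)),
               sprintf("cond_%d", seq_len(cfg$samples_per_group)))
  groups <- factor(rep(c("control", "condition"),
                       each = cfg$samples_per_group),
                   levels = c("control", "condition"))

  categories <- sample(plant_category(cfg, cfg$n_circ))
  signs <- ifelse(stats::runif(cfg$n_circ) < cfg$prop_down, -1, 1)

  truth <- vector("list", cfg$n_circ)
  rec <- vector("list", cfg$n_circ)
  for (i in seq_len(cfg$n_circ)) {
    g <- circ_genes[i]
    tx <- ann$transcripts$transcript_id[ann$transcripts$gene_id == g]
    e <- ann$exons[ann$exons$transcript_id == tx, ]
    e <- e[order(e$exon_number), ]
    k <- sample1(seq(cfg$circ_exons[1], min(cfg$circ_exons[2], nrow(e))))
    first <- sample1(seq_len(nrow(e) - k + 1L))
    inc <- e[first:(first + k - 1L), ]
    start <- min(inc$start); end <- max(inc$end)
    strand <- e$strand[1]
    cid <- circ_id(e$chrom[1], start, end, strand)
    cat_i <- categories[i]
    circ_lfc <- switch(cat_i, Concordant = signs[i] * cfg$lfc,
                       DiscordantCirc = signs[i] * cfg$lfc,
                       DiscordantLin = 0, Unaltered = 0)
    lin_lfc <- switch(cat_i, Concordant = signs[i] * cfg$lfc,
                      DiscordantCirc = 0,
                      DiscordantLin = signs[i] * cfg$lfc, Unaltered = 0)
    cond <- groups == "condition"
    circ_mu <- cfg$bsj_mu * 2^(circ_lfc * cond)
    lin_mu <- cfg$linear_mu * 2^(lin_lfc * cond)
    draw <- function(mu) {
      if (cfg$dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
      } else {
        stats::rpois(length(mu), mu)
      }
    }
    truth[[i]] <- data.frame(
      circ_id = cid, gene_id = g, category = cat_i,
      circ_log2fc = circ_lfc, lin_log2fc = lin_lfc,
      chrom = e$chrom[1], start = start, end = end, strand = strand,
      exon_count = k, dropout = FALSE, stringsAsFactors = FALSE)
    rec[[i]] <- data.frame(
      circ_id = cid, chrom = e$chrom[1], start = start, end = end,
      strand = strand, gene_id = g,
      bsj_reads = draw(circ_mu), linear_reads = draw(lin_mu),
      sample_id = samples, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  all_rec <- do.call(rbind, rec)

  # dropout circRNAs: BSJ rows removed from the lower-expression group
  n_drop <- round(cfg$dropout_fraction * cfg$n_circ)
  supplement <- data.frame(circ_id = character(), sample_id = character(),
                           linear_reads = integer(),
                           stringsAsFactors = FALSE)
  dereg <- truth$circ_id[truth$circ_log2fc != 0]  # detection dropout hits
  n_drop <- min(n_drop, length(dereg))            # the low-expression group
  if (n_drop > 0) {
    drop_ids <- sample(dereg, n_drop)
    truth$dropout <- truth$circ_id %in% drop_ids
    for (cid in drop_ids) {
      lfc_i <- truth$circ_log2fc[truth$circ_id == cid]
      drop_group <- if (lfc_i < 0) "condition" else "control"
      drop_samples <- samples[groups == drop_group]
      sel <- all_rec$circ_id == cid & all_rec$sample_id %in% drop_samples
      supplement <- rbind(supplement, data.frame(
        circ_id = cid, sample_id = all_rec$sample_id[sel],
        linear_reads = all_rec$linear_reads[sel], stringsAsFactors = FALSE))
      all_rec <- all_rec[!sel, , drop = FALSE]
    }
  }
  records <- split(all_rec, all_rec$sample_id)[samples]
  records <- lapply(records, function(x) {
    rownames(x) <- NULL
    x
  })
  list(records = records, linear_supplement = supplement, truth = truth,
       samples = samples, groups = groups)
}

#' Generate replicate peak files with planted placement
#'
#' Under the `near_bsj` rule, each downregulated circRNA receives a peak
#' centered within `peak_max_dist` nt of its 5' donor splice site in at
#' least 2 of the replicates (so every target is an interactor by
#' construction); background peaks are placed uniformly. Under the
#' `uniform` rule, all peaks are placed uniformly over the gene-bearing
#' span of the chromosome.
#'
#' @param cfg A `ScenarioConfig`.
#' @param world Output of [gen_genome_annotation()].
#' @param truth Truth table from [gen_counts()].
#' @param seed Integer seed for this component's RNG stream.
#' @return List with `peaks` (data.frame over all replicates, carrying the
#'   strand of the associated circRNA where applicable) and `truth` with a
#'   `target` column appended.
#' @export
gen_peaks <- function(cfg, world, truth, seed = 1L) {
  set.seed(derive_seed(seed, "peaks"))
  chrom_len <- Biostrings::width(world$genome)[1]
  span_lo <- min(world$ann$exons$start)
  span_hi <- max(world$ann$exons$end)
  half <- cfg$peak_width %/% 2L
  truth$target <- FALSE
  peaks <- list()
  add_peak <- function(center, rep_id, strand) {
    data.frame(chrom = cfg$chrom,
               start = max(0L, as.integer(center) - half),
               end = min(chrom_len, as.integer(center) + half),
               summit = as.integer(center),
               signal = round(stats::runif(1, 5, 50), 2),
               strand = strand, sample_id = rep_id,
               stringsAsFactors = FALSE)
  }
  if (cfg$peak_rule == "near_bsj") {
    targets <- which(truth$circ_log2fc < 0)
    truth$target[targets] <- TRUE
    for (i in targets) {
      site5 <- if (truth$strand[i] == "+") truth$end[i] else truth$start[i]
      n_rep <- sample1(2:cfg$n_replicates)
      reps <- sort(sample(seq_len(cfg$n_replicates), n_rep))
      for (r in reps) {
        # strictly inside +-max_dist so the peak always overlaps the span
        center <- site5 +
          sample1(seq(-cfg$peak_max_dist + 1L, cfg$peak_max_dist - 1L))
        peaks[[length(peaks) + 1L]] <-
          add_peak(center, sprintf("rep%d", r), truth$strand[i])
      }
    }
    for (r in seq_len(cfg$n_replicates)) {
      for (b in seq_len(cfg$n_background_peaks)) {
        center <- sample1(seq(span_lo + half, span_hi - half))
        peaks[[length(peaks) + 1L]] <-
          add_peak(center, sprintf("rep%d", r), "+")
      }
    }
  } else {
    n_per_rep <- sum(truth$circ_log2fc < 0) + cfg$n_background_peaks
    for (r in seq_len(cfg$n_replicates)) {
      for (b in seq_len(n_per_rep)) {
        center <- sample1(seq(span_lo + half, span_hi - half))
        peaks[[length(peaks) + 1L]] <-
          add_peak(center, sprintf("rep%d", r), "+")
      }
    }
  }
  peaks <- do.call(rbind, peaks)
  rownames(peaks) <- NULL
  list(peaks = peaks, truth = truth)
}

# GC enrichment concentrated at the summit with a linear taper to the
# background on both sides, so summit-centered metaprofiles have a single
# maximum at offset 0 rather than a plateau.
plant_summit_motifs <- function(cfg, genome, peaks, seed = 1L) {
  set.seed(derive_seed(seed, "motif"))
  seq <- as.character(genome[[cfg$chrom]])
  half <- cfg$motif_len %/% 2L
  rel <- seq.int(-half, half - 1L)
  gc_at <- cfg$background_gc +
    (cfg$motif_gc - cfg$background_gc) * (1 - abs(rel) / half)
  for (s in unique(peaks$summit)) {
    motif <- paste(vapply(gc_at, function(p) {
      sample(c("A", "C", "G", "T"), 1L,
             prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2))
    }, character(1)), collapse = "")
    lo <- s - half + 1L  # 1-based substring bounds
    hi <- lo + cfg$motif_len - 1L
    if (lo < 1L || hi > nchar(seq)) next
    substr(seq, lo, hi) <- motif
  }
  Biostrings::DNAStringSet(stats::setNames(seq, cfg$chrom))
}

#' Run the full synthetic scenario
#'
#' Generates genome and annotation, junction tables with planted truth, and
#' peak replicates; when motif planting is enabled the GC-rich summit motifs
#' are written into the genome sequence. One RNG stream per component is
#' derived from the master seed, so regenerating one component never shifts
#' the others. Fully deterministic given `(cfg, seed)`.
#'
#' @param cfg A `ScenarioConfig` (default [scenario_config()]).
#' @param seed Master seed.
#' @return List with `genome`, `ann`, `records`, `linear_supplement`,
#'   `truth`, `peaks`, `samples`, `groups`, `cfg`.
#' @export
simulate_scenario <- function(cfg = scenario_config(), seed = 1L) {
  world <- gen_genome_annotation(cfg, seed)
  cnt <- gen_counts(cfg, world, seed)
  pk <- gen_peaks(cfg, world, cnt$truth, seed)
  genome <- world$genome
  if (isTRUE(cfg$plant_motif) && !is.null(cfg$motif_gc)) {
    genome <- plant_summit_motifs(cfg, genome, pk$peaks, seed)
  }
  list(genome = genome, ann = world$ann, records = cnt$records,
       linear_supplement = cnt$linear_supplement, truth = pk$truth,
       peaks = pk$peaks, samples = cnt$samples, groups = cnt$groups,
       cfg = cfg)
}

#' Write a simulated scenario to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, one CIRI2-style TSV per sample,
#' one narrowPeak file per replicate, `linear_supplement.tsv` and
#' `truth.tsv`. All formats re-parse cleanly through the package's readers.
#'
#' @param sim Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$ann, file.path(dir, "annotation.gtf"))
  for (s in names(sim$records)) {
    write_ciri2(sim$records[[s]], file.path(dir, sprintf("%s.ciri.tsv", s)))
  }
  for (r in unique(sim$peaks$sample_id)) {
    write_narrowpeak(sim$peaks[sim$peaks$sample_id == r, ],
                     file.path(dir, sprintf("%s.narrowPeak", r)))
  }
  utils::write.table(sim$linear_supplement,
                     file.path(dir, "linear_supplement.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an annotation model as GTF
#'
#' Emits gene, transcript, exon (with `exon_number`), CDS and UTR features
#' in the Ensembl GTF dialect (1-based inclusive coordinates).
#'
#' @param ann An `AnnotationModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "AnnotationModel"))
  lines <- character(0)
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tcircseam\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start + 1L, end, strand, attrs)
  }
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    tx <- ann$transcripts[ann$transcripts$gene_id == g$gene_id, ]
    ex_all <- ann$exons[ann$exons$transcript_id %in% tx$transcript_id, ]
    if (nrow(ex_all) > 0) {
      g_start <- min(ex_all$start); g_end <- max(ex_all$end)
    } else {
      g_start <- 0L; g_end <- 1L
    }
    lines <- c(lines, fmt(g$chrom, "gene", g_start, g_end, g$strand,
                          sprintf('gene_id "%s"; gene_biotype "%s";',
                                  g$gene_id, g$biotype)))
    for (j in seq_len(nrow(tx))) {
      t <- tx[j, ]
      ex <- ann$exons[ann$exons$transcript_id == t$transcript_id, ]
      ex <- ex[order(ex$exon_number), ]
      base <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; transcript_biotype "%s";',
        g$gene_id, t$transcript_id, g$biotype, t$biotype)
      if (nrow(ex) > 0) {
        lines <- c(lines, fmt(t$chrom, "transcript", min(ex$start),
                              max(ex$end), t$strand, base))
        for (e in seq_len(nrow(ex))) {
          lines <- c(lines, fmt(ex$chrom[e], "exon", ex$start[e], ex$end[e],
                                ex$strand[e],
                                paste0(base, sprintf(' exon_number "%d";',
                                                     ex$exon_number[e]))))
        }
      }
      for (sub in list(c("cds", "CDS"), c("utr5", "five_prime_utr"),
                       c("utr3", "three_prime_utr"))) {
        f <- ann[[sub[1]]]
        f <- f[f$transcript_id == t$transcript_id, , drop = FALSE]
        for (e in seq_len(nrow(f))) {
          lines <- c(lines, fmt(f$chrom[e], sub[2], f$start[e], f$end[e],
                                t$strand, base))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
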