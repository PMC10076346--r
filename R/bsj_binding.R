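# Meta-BSJ binding enrichment: representative transcript selection,
# exon/intron region labeling, sliding windows around BSJ splice sites,
# window annotation properties, matched-control selection from invariant
# circRNAs, per-offset and per-region Fisher enrichment, interactor calling
# and balance checks.

exon_class_of <- function(exon_count) {
  ifelse(exon_count >= 4L, "4+", as.character(exon_count))
}

to_granges <- function(df) {
  GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Select the representative transcript of a circRNA
#'
#' When the circularized region overlaps several isoforms of the host gene,
#' one representative transcript is chosen by lexicographic priority:
#' (1) transcript biotype equal to the gene biotype, (2) both BSJ boundaries
#' strictly coincident with annotated exon junctions, (3) fewest exons
#' within the circularized span, (4) lowest exon number of the first exon
#' included in the circRNA; remaining ties are broken by transcript id.
#'
#' @param circ One BSJ record (a one-row data.frame with `circ_id`, `chrom`,
#'   `start`, `end`, `strand` and optionally `gene_id`).
#' @param ann An `AnnotationModel` from [parse_gtf()].
#' @return A `CircModel`: list with `circ_id`, coordinates, `gene_id`,
#'   `host_biotype`, `transcript_id`, `exon_count` (exons within the span),
#'   `boundaries_on_exons`, `exon_class` and the included `exons`
#'   data.frame (transcript 5'-to-3' order).
#' @export
representative_transcript <- function(circ, ann) {
  stopifnot(inherits(ann, "AnnotationModel"))
  tx <- ann$transcripts
  cand <- tx[tx$chrom == circ$chrom & tx$strand == circ$strand, , drop = FALSE]
  if (!is.null(circ$gene_id) && !is.na(circ$gene_id) &&
      circ$gene_id %in% cand$gene_id) {
    cand <- cand[cand$gene_id == circ$gene_id, , drop = FALSE]
  }
  if (nrow(cand) > 0) {
    score <- lapply(seq_len(nrow(cand)), function(i) {
      e <- ann$exons[ann$exons$transcript_id == cand$transcript_id[i], ,
                     drop = FALSE]
      inc <- e[e$start < circ$end & e$end > circ$start, , drop = FALSE]
      if (nrow(inc) == 0) return(NULL)
      gene_bt <- ann$genes$biotype[match(cand$gene_id[i], ann$genes$gene_id)]
      list(
        transcript_id = cand$transcript_id[i],
        gene_id = cand$gene_id[i],
        biotype_match = isTRUE(cand$biotype[i] == gene_bt),
        boundaries = any(e$start == circ$start) && any(e$end == circ$end),
        n_exons = nrow(inc),
        first_exon = min(inc$exon_number),
        exons = inc[order(inc$exon_number), , drop = FALSE]
      )
    })
    score <- Filter(Negate(is.null), score)
  } else {
    score <- list()
  }
  if (length(score) == 0) stop("unannotated circRNA: ", circ$circ_id)
  ord <- order(
    !vapply(score, `[[`, TRUE, "biotype_match"),
    !vapply(score, `[[`, TRUE, "boundaries"),
    vapply(score, `[[`, 1L, "n_exons"),
    vapply(score, `[[`, 1L, "first_exon"),
    vapply(score, `[[`, "", "transcript_id")
  )
  best <- score[[ord[1]]]
  gene_bt <- ann$genes$biotype[match(best$gene_id, ann$genes$gene_id)]
  model <- list(
    circ_id = circ$circ_id,
    chrom = circ$chrom,
    start = circ$start,
    end = circ$end,
    strand = circ$strand,
    gene_id = best$gene_id,
    host_biotype = gene_bt,
    transcript_id = best$transcript_id,
    exon_count = best$n_exons,
    boundaries_on_exons = best$boundaries,
    exon_class = exon_class_of(best$n_exons),
    exons = best$exons,
    regions = NULL
  )
  class(model) <- "CircModel"
  model
}

#' @export
print.CircModel <- function(x, ...) {
  cat("CircModel", x$circ_id, "->", x$transcript_id,
      sprintf("(%d exon(s), boundaries_on_exons=%s)\n",
              x$exon_count, x$boundaries_on_exons))
  invisible(x)
}

#' Label exons and introns of the circularized span
#'
#' Regions inside the circular span are labeled in transcript 5'-to-3'
#' order: the exon and intron most proximal to the 5' back-splicing
#' extremity are `Ex_A` and `Intr_A`, those proximal to the 3' extremity
#' `Intr_Z` and `Ex_Z`, and medial regions `Ex_M` / `Intr_M`. A single-exon
#' circRNA has only `Ex_A`; a bi-exonic circRNA has one intron, proximal to
#' both extremities, which is labeled `Intr_A`.
#'
#' @param model A `CircModel` with `boundaries_on_exons = TRUE`.
#' @return The model with a `regions` data.frame (`label`, `chrom`,
#'   `start`, `end`) in transcript order.
#' @export
label_regions <- function(model) {
  stopifnot(inherits(model, "CircModel"))
  if (!model$boundaries_on_exons) {
    stop("not labelable: BSJ boundaries of ", model$circ_id,
         " do not coincide with exon junctions")
  }
  ex <- model$exons  # transcript 5'->3' order
  n <- nrow(ex)
  exon_labels <- if (n == 1) "Ex_A" else
    c("Ex_A", rep("Ex_M", max(0L, n - 2L)), "Ex_Z")
  intron_labels <- if (n <= 1) character(0) else if (n == 2) "Intr_A" else
    c("Intr_A", rep("Intr_M", n - 3L), "Intr_Z")
  rows <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) {
    rows[[2L * i - 1L]] <- data.frame(
      label = exon_labels[i], chrom = ex$chrom[i],
      start = ex$start[i], end = ex$end[i], stringsAsFactors = FALSE)
    if (i < n) {
      if (model$strand == "+") {
        s <- ex$end[i]; e <- ex$start[i + 1L]
      } else {
        s <- ex$end[i + 1L]; e <- ex$start[i]
      }
      rows[[2L * i]] <- data.frame(
        label = intron_labels[i], chrom = ex$chrom[i],
        start = s, end = e, stringsAsFactors = FALSE)
    }
  }
  model$regions <- do.call(rbind, rows)
  rownames(model$regions) <- NULL
  model
}

#' Sliding windows around the BSJ splice sites
#'
#' For each extremity of the back-splicing junction (the 5' donor and the 3'
#' acceptor splice site) windows of `width` nt are placed every `step` nt
#' from `span` nt upstream to `span` nt downstream, in the orientation of
#' the circRNA's strand (negative offsets are upstream in transcript
#' orientation). At the defaults there are `(2*span - width)/step + 1 = 191`
#' windows per extremity.
#'
#' @param circs A data.frame of circRNAs (`circ_id`, `chrom`, `start`,
#'   `end`, `strand`) or a single `CircModel`.
#' @param span Flanking span in nt (default 1000).
#' @param width Window width in nt (default 100).
#' @param step Progression step in nt (default 10).
#' @param chrom_sizes Optional named vector of chromosome lengths; windows
#'   extending past the bounds are dropped with a warning.
#' @return A data.frame of windows: `circ_id`, `extremity`
#'   (`five_prime_ss`/`three_prime_ss`), `offset` (window start relative to
#'   the splice site, strand-oriented), `chrom`, `start`, `end`, `strand`.
#' @export
make_windows <- function(circs, span = 1000L, width = 100L, step = 10L,
                         chrom_sizes = NULL) {
  if (inherits(circs, "CircModel")) {
    circs <- data.frame(circ_id = circs$circ_id, chrom = circs$chrom,
                        start = circs$start, end = circs$end,
                        strand = circs$strand, stringsAsFactors = FALSE)
  }
  stopifnot(span >= width, (2L * span - width) %% step == 0L)
  offsets <- seq.int(-span, span - width, by = step)
  n_c <- nrow(circs)
  n_o <- length(offsets)
  plus <- circs$strand == "+"
  site5 <- ifelse(plus, circs$end, circs$start)    # 5' donor splice site
  site3 <- ifelse(plus, circs$start, circs$end)    # 3' acceptor splice site
  build <- function(site, extremity) {
    site_r <- rep(site, each = n_o)
    off_r <- rep(offsets, times = n_c)
    plus_r <- rep(plus, each = n_o)
    ws <- ifelse(plus_r, site_r + off_r, site_r - off_r - width)
    data.frame(
      circ_id = rep(circs$circ_id, each = n_o),
      extremity = extremity,
      offset = off_r,
      chrom = rep(circs$chrom, each = n_o),
      start = as.integer(ws),
      end = as.integer(ws + width),
      strand = rep(circs$strand, each = n_o),
      stringsAsFactors = FALSE
    )
  }
  w <- rbind(build(site5, "five_prime_ss"), build(site3, "three_prime_ss"))
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[w$chrom]
    drop <- w$start < 0L | (!is.na(lim) & w$end > lim)
    if (any(drop)) {
      warning(sum(drop), " window(s) beyond chromosome bounds dropped")
      w <- w[!drop, , drop = FALSE]
    }
  } else if (any(w$start < 0L)) {
    warning(sum(w$start < 0L), " window(s) beyond chromosome bounds dropped")
    w <- w[w$start >= 0L, , drop = FALSE]
  }
  rownames(w) <- NULL
  w
}

#' Annotate windows with transcript-overlap properties
#'
#' For each window the percentage of nucleotides overlapping the
#' representative transcript's exons, 5'UTR, CDS and 3'UTR intervals is
#' computed, and the host-gene biotype and circRNA exon-number class
#' (`1`, `2`, `3`, `4+`) of the window's circRNA are attached.
#'
#' @param windows Window data.frame from [make_windows()].
#' @param models Named list of `CircModel` objects keyed by `circ_id`.
#' @param ann An `AnnotationModel`.
#' @return `windows` with columns `pct_exon`, `pct_5utr`, `pct_cds`,
#'   `pct_3utr`, `host_biotype`, `exon_class` appended.
#' @export
window_props <- function(windows, models, ann) {
  stopifnot(inherits(ann, "AnnotationModel"))
  prop_cols <- c(pct_exon = "exons", pct_5utr = "utr5", pct_cds = "cds",
                 pct_3utr = "utr3")
  for (p in names(prop_cols)) windows[[p]] <- 0
  windows$host_biotype <- NA_character_
  windows$exon_class <- NA_character_
  for (cid in unique(windows$circ_id)) {
    mod <- models[[cid]]
    if (is.null(mod)) stop("no CircModel for ", cid)
    idx <- which(windows$circ_id == cid)
    wr <- IRanges::IRanges(start = windows$start[idx] + 1L,
                           end = windows$end[idx])
    for (p in names(prop_cols)) {
      feat <- ann[[prop_cols[[p]]]]
      feat <- feat[feat$transcript_id == mod$transcript_id, , drop = FALSE]
      if (nrow(feat) == 0) next
      fr <- IRanges::reduce(IRanges::IRanges(start = feat$start + 1L,
                                             end = feat$end))
      ov <- IRanges::findOverlaps(wr, fr)
      if (length(ov) == 0) next
      wid <- IRanges::width(IRanges::pintersect(
        wr[S4Vectors::queryHits(ov)], fr[S4Vectors::subjectHits(ov)]))
      tot <- tapply(wid, S4Vectors::queryHits(ov), sum)
      j <- as.integer(names(tot))
      windows[[p]][idx[j]] <- 100 * as.numeric(tot) / IRanges::width(wr[j])
    }
    windows$host_biotype[idx] <- mod$host_biotype
    windows$exon_class[idx] <- mod$exon_class
  }
  windows
}

#' Match control windows to target windows
#'
#' For every target window, `k` control windows are selected from the pool
#' of invariant-circRNA windows at the same extremity and relative offset.
#' The pool is first restricted to the same host-gene biotype and exon-number
#' class; the `k` windows minimizing the Euclidean distance on the
#' annotation-overlap properties (`pct_exon`, `pct_5utr`, `pct_cds`,
#' `pct_3utr`) are then taken without replacement (within a target), with
#' ties broken by circRNA id. If the restricted pool has fewer than `k`
#' windows, the exon-class constraint and then the biotype constraint are
#' relaxed; a target whose pool is empty even after relaxation is excluded
#' from testing. Controls may be reused across different targets.
#'
#' @param target_windows,pool_windows Window data.frames from
#'   [window_props()]; the pool comes from invariant circRNAs.
#' @param k Controls per target window (default 2).
#' @return The selected control windows, one block of up to `k` rows per
#'   target window, with `target_circ_id` prepended. Excluded targets are
#'   recorded in the `excluded` attribute.
#' @export
match_controls <- function(target_windows, pool_windows, k = 2L) {
  stopifnot(nrow(pool_windows) > 0)
  props <- c("pct_exon", "pct_5utr", "pct_cds", "pct_3utr")
  pool_split <- split(seq_len(nrow(pool_windows)),
                      paste(pool_windows$extremity, pool_windows$offset))
  out <- vector("list", nrow(target_windows))
  excluded <- character(0)
  relaxations <- 0L
  for (i in seq_len(nrow(target_windows))) {
    t <- target_windows[i, ]
    cand_idx <- pool_split[[paste(t$extremity, t$offset)]]
    if (is.null(cand_idx)) {
      excluded <- c(excluded, t$circ_id)
      next
    }
    cand <- pool_windows[cand_idx, , drop = FALSE]
    sel <- cand$host_biotype == t$host_biotype &
      cand$exon_class == t$exon_class
    if (sum(sel) < k) {
      relaxations <- relaxations + 1L
      sel <- cand$host_biotype == t$host_biotype
    }
    if (sum(sel) < k) sel <- rep(TRUE, nrow(cand))
    cand <- cand[sel, , drop = FALSE]
    if (nrow(cand) == 0) {
      excluded <- c(excluded, t$circ_id)
      next
    }
    d <- sqrt(rowSums(sweep(as.matrix(cand[, props]), 2L,
                            as.numeric(t[, props]))^2))
    pick <- order(d, cand$circ_id)[seq_len(min(k, nrow(cand)))]
    block <- cand[pick, , drop = FALSE]
    out[[i]] <- cbind(target_circ_id = t$circ_id, block,
                      stringsAsFactors = FALSE)
  }
  if (relaxations > 0) {
    message(relaxations, " target window(s) required constraint relaxation")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- cbind(target_circ_id = character(0), target_windows[0, ],
                 stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "excluded") <- unique(excluded)
  res
}

windows_hit_peaks <- function(windows, peaks) {
  if (nrow(peaks) == 0) return(rep(FALSE, nrow(windows)))
  GenomicRanges::countOverlaps(to_granges(windows), to_granges(peaks)) > 0
}

#' Per-offset Fisher enrichment of peaks in target versus control windows
#'
#' For each peak replicate (after within-replicate longest-peak merging,
#' see [merge_longest()]) and each (extremity, offset) bin, the numbers of
#' target and control windows containing or not containing a peak (any
#' overlap of at least 1 nt) form a 2x2 table tested with the two-tailed
#' Fisher exact test.
#'
#' @param target_windows Windows of the deregulated circRNA set.
#' @param control_windows Matched control windows ([match_controls()]).
#' @param peaks Peak data.frame covering one or more replicates
#'   (`sample_id` column).
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05).
#' @return A data.frame of bins: `replicate`, `extremity`, `offset`, counts
#'   `a`, `b`, `c`, `d` (target with/without, control with/without peak),
#'   `odds_ratio` (0.5-corrected when any cell is zero), `pvalue`,
#'   `significant`.
#' @export
window_enrichment <- function(target_windows, control_windows, peaks,
                              alpha = 0.05) {
  bins <- unique(target_windows[, c("extremity", "offset")])
  bins <- bins[order(bins$extremity, bins$offset), ]
  out <- lapply(unique(peaks$sample_id), function(rep_id) {
    pk <- merge_longest(peaks[peaks$sample_id == rep_id, , drop = FALSE])
    t_hit <- windows_hit_peaks(target_windows, pk)
    c_hit <- windows_hit_peaks(control_windows, pk)
    t_key <- paste(target_windows$extremity, target_windows$offset)
    c_key <- paste(control_windows$extremity, control_windows$offset)
    res <- bins
    res$replicate <- rep_id
    stats <- vapply(seq_len(nrow(bins)), function(i) {
      key <- paste(bins$extremity[i], bins$offset[i])
      a <- sum(t_hit[t_key == key]); b <- sum(t_key == key) - a
      cc <- sum(c_hit[c_key == key]); d <- sum(c_key == key) - cc
      ft <- fisher_2x2(a, b, cc, d)
      c(a, b, cc, d, ft$odds_ratio, ft$p)
    }, numeric(6))
    res$a <- stats[1, ]; res$b <- stats[2, ]
    res$c <- stats[3, ]; res$d <- stats[4, ]
    res$odds_ratio <- stats[5, ]
    res$pvalue <- stats[6, ]
    res$significant <- res$pvalue < alpha
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("replicate", "extremity", "offset", "a", "b", "c", "d",
          "odds_ratio", "pvalue", "significant")]
}

#' Per-region Fisher enrichment between deregulated and invariant circRNAs
#'
#' Only circRNAs whose BSJ boundaries coincide with exon junctions are
#' evaluated, grouped by exon-number class (`2`, `3`, `4+`). Within each
#' group and labeled region type (`Ex_A`, `Intr_A`, `Ex_M`, `Intr_M`,
#' `Intr_Z`, `Ex_Z`), the numbers of regions containing or not containing a
#' peak among the deregulated versus the invariant set are compared by the
#' two-tailed Fisher exact test, per peak replicate. Group/region
#' combinations with no invariant region are skipped with a warning.
#'
#' @param down_models,invariant_models Lists of labeled `CircModel` objects
#'   (see [label_regions()]).
#' @param peaks Peak data.frame with `sample_id` replicates.
#' @param alpha Significance threshold (default 0.05).
#' @return A data.frame: `replicate`, `exon_class`, `label`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `pvalue`, `significant`.
#' @export
region_enrichment <- function(down_models, invariant_models, peaks,
                              alpha = 0.05) {
  collect <- function(models) {
    rows <- lapply(models, function(m) {
      if (!m$boundaries_on_exons || m$exon_count < 2L || is.null(m$regions)) {
        return(NULL)
      }
      cbind(m$regions, exon_class = m$exon_class, circ_id = m$circ_id,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  down <- collect(down_models)
  inv <- collect(invariant_models)
  if (is.null(down) || is.null(inv)) stop("no labelable circRNAs in a set")
  out <- list()
  for (rep_id in unique(peaks$sample_id)) {
    pk <- merge_longest(peaks[peaks$sample_id == rep_id, , drop = FALSE])
    down$hit <- windows_hit_peaks(down, pk)
    inv$hit <- windows_hit_peaks(inv, pk)
    for (g in intersect(c("2", "3", "4+"), unique(down$exon_class))) {
      dg <- down[down$exon_class == g, , drop = FALSE]
      ig <- inv[inv$exon_class == g, , drop = FALSE]
      if (nrow(ig) == 0) {
        warning("no invariant circRNAs in exon-class group ", g,
                "; group skipped")
        next
      }
      for (lab in unique(dg$label)) {
        dl <- dg[dg$label == lab, , drop = FALSE]
        il <- ig[ig$label == lab, , drop = FALSE]
        if (nrow(il) == 0) {
          warning("region ", lab, " absent from invariant group ", g,
                  "; skipped")
          next
        }
        a <- sum(dl$hit); b <- nrow(dl) - a
        cc <- sum(il$hit); d <- nrow(il) - cc
        ft <- fisher_2x2(a, b, cc, d)
        out[[length(out) + 1L]] <- data.frame(
          replicate = rep_id, exon_class = g, label = lab,
          a = a, b = b, c = cc, d = d,
          odds_ratio = ft$odds_ratio, pvalue = ft$p,
          significant = ft$p < alpha, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call protein-interactor circRNAs from replicate peak sets
#'
#' A circRNA is an interactor when its genomic span overlaps at least one
#' peak in at least `min_samples` replicates.
#'
#' @param circs Data.frame of circRNAs (`circ_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param peaks Peak data.frame with a `sample_id` replicate column, or a
#'   list of per-replicate peak data.frames.
#' @param min_samples Minimum number of supporting replicates (default 2).
#' @return A data.frame with `circ_id`, `n_replicates_bound`, `interactor`.
#' @export
interactor_call <- function(circs, peaks, min_samples = 2L) {
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- do.call(rbind, peaks)
  }
  reps <- unique(peaks$sample_id)
  hits <- vapply(reps, function(rep_id) {
    windows_hit_peaks(circs, peaks[peaks$sample_id == rep_id, , drop = FALSE])
  }, logical(nrow(circs)))
  n_bound <- if (nrow(circs) == 1L) sum(hits) else rowSums(hits)
  data.frame(circ_id = circs$circ_id,
             n_replicates_bound = as.integer(n_bound),
             interactor = n_bound >= min_samples,
             stringsAsFactors = FALSE)
}

#' Check that target and control window properties are balanced
#'
#' Each continuous window property is dichotomized at the pooled median and
#' tested target-versus-control with the two-tailed Fisher exact test;
#' host-gene biotype and exon-number class are tested per category against
#' the rest.
#'
#' @param target_windows,control_windows Window data.frames from
#'   [window_props()].
#' @return A data.frame: `property`, `level`, `odds_ratio`, `p`.
#' @export
balance_check <- function(target_windows, control_windows) {
  stopifnot(nrow(target_windows) > 0, nrow(control_windows) > 0)
  out <- list()
  for (p in c("pct_exon", "pct_5utr", "pct_cds", "pct_3utr")) {
    pooled <- c(target_windows[[p]], control_windows[[p]])
    med <- stats::median(pooled)
    a <- sum(target_windows[[p]] > med)
    b <- nrow(target_windows) - a
    cc <- sum(control_windows[[p]] > med)
    d <- nrow(control_windows) - cc
    ft <- fisher_2x2(a, b, cc, d)
    out[[length(out) + 1L]] <- data.frame(
      property = p, level = sprintf("> %.3g", med),
      odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
  }
  for (p in c("host_biotype", "exon_class")) {
    for (lev in unique(c(target_windows[[p]], control_windows[[p]]))) {
      a <- sum(target_windows[[p]] == lev)
      b <- nrow(target_windows) - a
      cc <- sum(control_windows[[p]] == lev)
      d <- nrow(control_windows) - cc
      ft <- fisher_2x2(a, b, cc, d)
      out[[length(out) + 1L]] <- data.frame(
        property = p, level = lev,
        odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
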