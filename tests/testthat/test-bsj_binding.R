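# Representative transcripts, region labels, BSJ windows, matched controls
# and enrichment statistics.

# Gene with two isoforms: T1's exons align with the circRNA boundaries,
# T2's do not. Exons at [1000,1200), [2000,2200), [3000,3200), [4000,4200).
two_isoform_ann <- function(strand = "+") {
  make_ann(list(
    T1 = cbind(c(1000L, 2000L, 3000L, 4000L),
               c(1200L, 2200L, 3200L, 4200L)),
    T2 = cbind(c(900L, 2050L, 3000L), c(1200L, 2200L, 3150L))
  ), strand = strand)
}

test_that("representative transcript prefers exact boundary isoforms", {
  ann <- two_isoform_ann()
  circ <- make_circ(start = 2000L, end = 3200L)
  model <- representative_transcript(circ, ann)
  expect_equal(model$transcript_id, "T1")
  expect_true(model$boundaries_on_exons)
  expect_equal(model$exon_count, 2L)
  expect_equal(model$exon_class, "2")
})

test_that("representative transcript minimizes included exons", {
  # both isoforms have boundary-coincident exons; T2 spans fewer exons
  ann <- make_ann(list(
    T1 = cbind(c(1000L, 1500L, 2000L), c(1200L, 1700L, 2200L)),
    T2 = cbind(c(1000L, 2000L), c(1200L, 2200L))
  ))
  circ <- make_circ(start = 1000L, end = 2200L)
  expect_equal(representative_transcript(circ, ann)$transcript_id, "T2")
  # single-isoform gene: chosen trivially
  solo <- make_ann(list(T1 = cbind(1000L, 2200L)))
  expect_equal(representative_transcript(circ, solo)$transcript_id, "T1")
  # no overlapping transcript
  far <- make_circ(start = 900000L, end = 901000L, gene_id = "GX")
  expect_error(representative_transcript(far, make_ann(list(
    T1 = cbind(1000L, 2200L)))), "unannotated")
})

test_that("biotype-matching isoforms outrank non-matching ones", {
  ann <- make_ann(list(
    T1 = cbind(c(1000L, 2000L), c(1200L, 2200L)),
    T2 = cbind(c(1000L, 2000L), c(1200L, 2200L))
  ), tx_biotypes = c("retained_intron", "protein_coding"))
  circ <- make_circ(start = 1000L, end = 2200L)
  expect_equal(representative_transcript(circ, ann)$transcript_id, "T2")
})

test_that("region labels follow the proximity scheme for any exon count", {
  lab_for <- function(n, strand = "+") {
    starts <- seq(1000L, by = 1000L, length.out = n)
    ann <- make_ann(list(T1 = cbind(starts, starts + 200L)), strand = strand)
    circ <- make_circ(start = 1000L, end = starts[n] + 200L,
                      strand = strand)
    model <- label_regions(representative_transcript(circ, ann))
    model$regions$label
  }
  expect_equal(lab_for(1), "Ex_A")
  expect_equal(lab_for(2), c("Ex_A", "Intr_A", "Ex_Z"))
  expect_equal(lab_for(3), c("Ex_A", "Intr_A", "Ex_M", "Intr_Z", "Ex_Z"))
  expect_equal(lab_for(5),
               c("Ex_A", "Intr_A", "Ex_M", "Intr_M", "Ex_M", "Intr_M",
                 "Ex_M", "Intr_Z", "Ex_Z"))
  # minus strand: same label order in transcript orientation
  expect_equal(lab_for(3, strand = "-"),
               c("Ex_A", "Intr_A", "Ex_M", "Intr_Z", "Ex_Z"))
})

test_that("minus-strand Ex_A is the genomically rightmost exon", {
  starts <- c(1000L, 2000L, 3000L)
  ann <- make_ann(list(T1 = cbind(starts, starts + 200L)), strand = "-")
  circ <- make_circ(start = 1000L, end = 3200L, strand = "-")
  model <- label_regions(representative_transcript(circ, ann))
  ex_a <- model$regions[model$regions$label == "Ex_A", ]
  expect_equal(ex_a$start, 3000L)
  intr_a <- model$regions[model$regions$label == "Intr_A", ]
  expect_equal(c(intr_a$start, intr_a$end), c(2200L, 3000L))
})

test_that("unlabelable circRNAs are rejected", {
  ann <- two_isoform_ann()
  circ <- make_circ(start = 2100L, end = 3100L)  # off every exon junction
  model <- representative_transcript(circ, ann)
  expect_false(model$boundaries_on_exons)
  expect_error(label_regions(model), "not labelable")
})

test_that("window geometry: 191 windows per extremity at defaults", {
  circ <- make_circ(start = 10000L, end = 20000L)
  w <- make_windows(circ)
  expect_equal(sum(w$extremity == "five_prime_ss"), 191L)
  expect_equal(sum(w$extremity == "three_prime_ss"), 191L)
  expect_true(all(w$end - w$start == 100L))
  expect_equal(sort(unique(w$offset)), seq(-1000L, 900L, 10L))
  w2 <- make_windows(circ, span = 100L, width = 100L, step = 10L)
  expect_equal(sum(w2$extremity == "five_prime_ss"), 11L)
})

test_that("windows are strand-oriented and clipped at chromosome bounds", {
  plus <- make_windows(make_circ(start = 10000L, end = 20000L))
  # plus strand: 5' donor site at the span end; offset 0 window starts there
  w0 <- plus[plus$extremity == "five_prime_ss" & plus$offset == 0, ]
  expect_equal(w0$start, 20000L)
  minus <- make_windows(make_circ(start = 10000L, end = 20000L,
                                  strand = "-"))
  # minus strand: 5' donor at span start; upstream = higher coordinates
  up <- minus[minus$extremity == "five_prime_ss" & minus$offset == -1000, ]
  expect_equal(up$start, 10900L)
  expect_equal(up$end, 11000L)
  expect_warning(
    clipped <- make_windows(make_circ(start = 100L, end = 20000L)),
    "dropped")
  expect_true(all(clipped$start >= 0))
})

test_that("window properties measure transcript-feature overlap", {
  ann <- make_ann(
    list(T1 = cbind(c(1000L, 3000L), c(2000L, 4000L))),
    cds = list(T1 = cbind(c(1000L, 3000L), c(2000L, 4000L)))
  )
  circ <- make_circ(start = 1000L, end = 4000L)
  model <- representative_transcript(circ, ann)
  w <- data.frame(circ_id = circ$circ_id, extremity = "five_prime_ss",
                  offset = c(0L, 0L, 0L), chrom = "chr1",
                  start = c(1100L, 2200L, 1950L),
                  end = c(1200L, 2300L, 2050L), strand = "+",
                  stringsAsFactors = FALSE)
  props <- window_props(w, setNames(list(model), circ$circ_id), ann)
  expect_equal(props$pct_exon, c(100, 0, 50))
  expect_equal(props$pct_cds, c(100, 0, 50))
  expect_equal(props$pct_5utr, c(0, 0, 0))
  expect_equal(props$host_biotype, rep("protein_coding", 3))
})

window_row <- function(circ_id, pct, extremity = "five_prime_ss",
                       offset = 0L, biotype = "protein_coding",
                       exon_class = "2") {
  data.frame(circ_id = circ_id, extremity = extremity, offset = offset,
             chrom = "chr1", start = 0L, end = 100L, strand = "+",
             pct_exon = pct[1], pct_5utr = pct[2], pct_cds = pct[3],
             pct_3utr = pct[4], host_biotype = biotype,
             exon_class = exon_class, stringsAsFactors = FALSE)
}

test_that("control matching picks property-nearest pool windows", {
  target <- window_row("t1", c(100, 0, 100, 0))
  pool <- rbind(window_row("c1", c(100, 0, 100, 0)),
                window_row("c2", c(0, 0, 0, 0)),
                window_row("c3", c(50, 0, 50, 0)))
  got <- match_controls(target, pool, k = 2L)
  expect_equal(got$circ_id, c("c1", "c3"))
  # exact duplicate is always selected first
  expect_equal(got$circ_id[1], "c1")
})

test_that("control matching relaxes constraints on scarce pools", {
  target <- window_row("t1", c(100, 0, 100, 0), exon_class = "3")
  pool <- rbind(window_row("c1", c(90, 0, 90, 0), exon_class = "3"),
                window_row("c2", c(80, 0, 80, 0), exon_class = "2"))
  expect_message(got <- match_controls(target, pool, k = 2L), "relaxation")
  expect_equal(sort(got$circ_id), c("c1", "c2"))
  # offset absent from the pool: target excluded
  lone <- window_row("t2", c(0, 0, 0, 0), offset = 500L)
  got2 <- suppressMessages(match_controls(lone, pool, k = 2L))
  expect_true("t2" %in% attr(got2, "excluded"))
})

test_that("window enrichment matches enumeration in the planted extreme", {
  targets <- do.call(rbind, lapply(1:6, function(i) {
    window_row(sprintf("t%d", i), c(100, 0, 100, 0))
  }))
  targets$start <- seq(1000L, by = 1000L, length.out = 6)
  targets$end <- targets$start + 100L
  controls <- do.call(rbind, lapply(1:12, function(i) {
    window_row(sprintf("c%d", i), c(100, 0, 100, 0))
  }))
  controls$start <- seq(100000L, by = 1000L, length.out = 12)
  controls$end <- controls$start + 100L
  peaks <- make_peaks(targets$start, targets$end)  # only targets covered
  bins <- window_enrichment(targets, controls, peaks)
  expect_equal(bins$a, 6)
  expect_equal(bins$c, 0)
  expect_gt(bins$odds_ratio, 1)
  expect_equal(bins$pvalue, brute_fisher_p(6, 0, 0, 12), tolerance = 1e-9)
  # identical overlap rates: p = 1
  bins_same <- window_enrichment(targets, targets, peaks)
  expect_equal(bins_same$pvalue, 1)
  # no peaks at all: nothing significant
  empty <- window_enrichment(targets, controls,
                             make_peaks(900000L, 900100L))
  expect_false(any(empty$significant))
})

test_that("region enrichment flags only the planted region", {
  starts <- c(1000L, 2000L, 3000L)
  models <- function(prefix, base) {
    lapply(1:6, function(i) {
      off <- base + i * 10000L
      ann <- make_ann(list(T1 = cbind(starts + off, starts + off + 200L)),
                      gene_id = sprintf("%s%d", prefix, i))
      circ <- make_circ(start = 1000L + off, end = 3200L + off,
                        gene_id = sprintf("%s%d", prefix, i))
      label_regions(representative_transcript(circ, ann))
    })
  }
  down <- models("D", 0L)
  inv <- models("I", 1000000L)
  # peaks inside Ex_A of the down set only
  ex_a <- do.call(rbind, lapply(down, function(m) {
    m$regions[m$regions$label == "Ex_A", ]
  }))
  peaks <- make_peaks(ex_a$start + 50L, ex_a$start + 150L)
  res <- region_enrichment(down, inv, peaks)
  expect_true(res$significant[res$label == "Ex_A"])
  expect_false(any(res$significant[res$label != "Ex_A"]))
})

test_that("interactor calls require peaks in enough replicates", {
  circ <- rbind(make_circ(start = 1000L, end = 2000L),
                make_circ(start = 9000L, end = 10000L))
  peaks <- rbind(make_peaks(1500L, 1600L, "rep1"),
                 make_peaks(1500L, 1600L, "rep3"),
                 make_peaks(9500L, 9600L, "rep2"))
  res <- interactor_call(circ, peaks)
  expect_equal(res$interactor, c(TRUE, FALSE))   # 2 of 3 vs 1 of 3
  res1 <- interactor_call(circ, peaks, min_samples = 1L)
  expect_equal(res1$interactor, c(TRUE, TRUE))
})

test_that("balance check accepts matched sets and flags planted imbalance", {
  t_w <- do.call(rbind, lapply(1:10, function(i) {
    window_row(sprintf("t%d", i), c(100, 0, 100, 0))
  }))
  balanced <- balance_check(t_w, t_w)
  expect_true(all(balanced$p == 1))
  c_w <- do.call(rbind, lapply(1:10, function(i) {
    window_row(sprintf("c%d", i), c(0, 0, 0, 0))
  }))
  imbalanced <- balance_check(t_w, c_w)
  expect_lt(min(imbalanced$p[imbalanced$property == "pct_exon"]), 0.01)
  single <- balance_check(t_w[1, ], t_w[1, ])
  expect_true(all(single$p == 1))
})
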