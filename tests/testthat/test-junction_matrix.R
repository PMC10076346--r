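# Count-matrix construction, filtering, CPM and circRNA set selection.

test_that("cross-sample completion fills missing BSJs with supplement", {
  a <- make_circ(bsj = 7L, lin = 20L, sample_id = "A")
  b <- make_circ(start = 5000L, end = 6000L, bsj = 3L, lin = 9L,
                 sample_id = "B")
  supp <- data.frame(circ_id = a$circ_id, sample_id = "B",
                     linear_reads = 15L)
  m <- complete_counts(list(A = a, B = b), linear_supplement = supp)
  expect_equal(m$counts[paste0(a$circ_id, "|circ"), ], c(A = 7L, B = 0L))
  expect_equal(m$counts[paste0(a$circ_id, "|linear"), ], c(A = 20L, B = 15L))
  expect_equal(m$counts[paste0(b$circ_id, "|circ"), ], c(A = 0L, B = 3L))
  expect_false(anyNA(m$counts))
})

test_that("completion produces a dense union matrix", {
  s1 <- do.call(rbind, lapply(1:2, function(i) {
    make_circ(start = i * 1000L, end = i * 1000L + 500L, sample_id = "s1")
  }))
  s2 <- do.call(rbind, lapply(3:5, function(i) {
    make_circ(start = i * 1000L, end = i * 1000L + 500L, sample_id = "s2")
  }))
  m <- complete_counts(list(s1 = s1, s2 = s2))
  expect_equal(sum(m$features$kind == "circ"), 5L)
  expect_equal(dim(m$counts), c(10L, 2L))
  expect_false(anyNA(m$counts))

  single <- complete_counts(list(s1 = s1))
  expect_equal(unname(single$counts[paste0(s1$circ_id, "|circ"), 1]),
               s1$bsj_reads)

  flipped <- make_circ(strand = "-", sample_id = "s2")
  expect_error(
    complete_counts(list(s1 = make_circ(sample_id = "s1"), s2 = flipped)),
    "inconsistent strand")
})

test_that("expression filter applies the min-count rule and is idempotent", {
  counts <- rbind(
    kept = c(2L, 2L, 2L, 0L, 0L, 0L),
    dropped = c(2L, 2L, 0L, 0L, 0L, 0L)
  )
  m <- structure(list(
    counts = counts,
    features = data.frame(feature_id = rownames(counts),
                          circ_id = rownames(counts),
                          kind = "circ", stringsAsFactors = FALSE),
    samples = paste0("s", 1:6),
    meta = data.frame()), class = "CountMatrix")
  colnames(m$counts) <- m$samples
  f <- expression_filter(m)
  expect_equal(f$features$feature_id, "kept")
  expect_equal(expression_filter(f)$counts, f$counts)   # idempotent
  expect_equal(expression_filter(m, min_count = 0)$counts, m$counts)
})

test_that("CPM uses junction-universe library sizes and TMM factors", {
  a <- make_circ(bsj = 10L, lin = 990L, sample_id = "A")
  b <- make_circ(bsj = 10L, lin = 990L, sample_id = "B")
  m <- complete_counts(list(A = a, B = b))
  v <- cpm(m)
  expect_equal(unname(v$values[paste0(a$circ_id, "|circ"), "A"]), 10000)
  expect_equal(unname(colSums(v$values)), c(1e6, 1e6))
  # a TMM factor of 2 halves the CPM (effective library doubled)
  v2 <- cpm(m, factors = c(A = 2, B = 1))
  expect_equal(unname(v2$values[paste0(a$circ_id, "|circ"), "A"]), 5000)
  expect_equal(v2$values[1, "B"], v$values[1, "B"] * sqrt(1))
})

test_that("top-expressed selection ranks circ features with ties by id", {
  ids <- sprintf("chr1:%d-%d:+", 1:10, 1001:1010)
  vals <- matrix(rep(10 - (1:10), 2), ncol = 2,
                 dimnames = list(paste0(ids, "|circ"), c("s1", "s2")))
  m <- structure(list(
    values = vals,
    features = data.frame(feature_id = rownames(vals), circ_id = ids,
                          kind = "circ", stringsAsFactors = FALSE),
    samples = c("s1", "s2")), class = "CpmMatrix")
  expect_equal(top_expressed(m, 0.2), ids[1:2])
  expect_equal(length(top_expressed(m, 1.0)), 10L)
  m$values[] <- 1  # all tied: lexicographically first ceil(0.2 n)
  expect_equal(top_expressed(m, 0.2), sort(ids)[1:2])
  expect_equal(length(top_expressed(m, 0.25)), ceiling(0.25 * 10))
})

test_that("high-confidence intersection honours coordinate slack", {
  a <- circ_id("chr1", c(100L, 300L), c(200L, 400L), "+")
  b <- circ_id("chr1", c(100L, 700L), c(200L, 800L), "+")
  c3 <- circ_id("chr1", 100L, 200L, "+")
  expect_equal(high_confidence(a, b, c3), a[1])
  expect_equal(high_confidence(a, character(0), c3), character(0))
  expect_equal(high_confidence(a, a, a), a)
  # 1 nt disagreement only matches with slack
  shifted <- circ_id("chr1", 101L, 200L, "+")
  expect_equal(high_confidence(a, shifted, shifted), character(0))
  expect_equal(high_confidence(a, shifted, shifted, slack = 1L), a[1])
})

test_that("count matrix TSV round trip preserves counts and kinds", {
  recs <- list(
    s1 = rbind(make_circ(sample_id = "s1"),
               make_circ(start = 5000L, end = 6000L, sample_id = "s1")),
    s2 = rbind(make_circ(sample_id = "s2", bsj = 2L))
  )
  m <- complete_counts(recs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  back <- read_count_matrix(path)
  expect_equal(back$counts, m$counts)
  expect_equal(back$features$kind, m$features$kind)
})
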