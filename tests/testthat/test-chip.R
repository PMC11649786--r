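test_that("overlap partition: intersection, boundary, merging", {
  A <- peak_set(data.frame(chrom = "c", start = 100L, end = 200L), "A")
  B <- peak_set(data.frame(chrom = "c", start = 150L, end = 250L), "B")
  ov <- overlap_peak_sets(A, B)
  expect_equal(ov$n_co_bound, 1L)
  expect_equal(ov$co_bound$start, 100L)
  expect_equal(ov$co_bound$end, 250L)
  # half-open: touching intervals do not overlap
  B2 <- peak_set(data.frame(chrom = "c", start = 200L, end = 300L), "B")
  ov2 <- overlap_peak_sets(A, B2)
  expect_equal(ov2$n_co_bound, 0L)
  expect_equal(ov2$n_a_only, 1L)
  expect_equal(ov2$n_b_only, 1L)
})

test_that("overlap partition matches the all-pairs oracle and is symmetric", {
  for (seed in c(2, 7)) {
    withr::with_seed(seed, {
      pa <- random_peaks(400)
      pb <- random_peaks(400)
    })
    A <- peak_set(pa, "A"); B <- peak_set(pb, "B")
    ov <- overlap_peak_sets(A, B)
    want <- oracle_overlap(pa, pb)
    expect_equal(sort(ov$a_only), want$a_only)
    expect_equal(sort(ov$b_only), want$b_only)
    swap <- overlap_peak_sets(B, A)
    expect_equal(swap$n_co_bound, ov$n_co_bound)
    expect_equal(swap$n_a_only, ov$n_b_only)
    # partition bookkeeping: every peak is a-only or overlapping
    expect_lte(ov$n_a_only, nrow(pa))
    expect_equal(ov$n_a_only + (nrow(pa) - length(want$a_only)), nrow(pa))
  }
})

test_that("promoter-bound gene sets respect the strand-aware window", {
  pipe <- toy_pipeline()
  m <- pipe$genes[[3]]
  at <- function(d) {
    a <- if (m$strand == "+") m$tss - d else m$tss + d
    peak_set(data.frame(chrom = m$chrom, start = a - 20L, end = a + 20L,
                        summit_offset = 20L), "x")
  }
  expect_true(m$gene_id %in% promoter_bound_genes(at(300L), pipe$genes))
  expect_false(m$gene_id %in% promoter_bound_genes(at(1500L), pipe$genes))
})

test_that("planted co-binding structure is recovered from ChIP fixtures", {
  pipe <- toy_pipeline()
  chip <- sim_chip(pipe$cfg, pipe$genes)
  pa <- read_peaks(chip$peaks_a, "narrowPeak", "A")
  pb <- read_peaks(chip$peaks_b, "narrowPeak", "B")
  ov <- overlap_peak_sets(pa, pb)
  expect_equal(ov$n_co_bound, sum(chip$truth$co_bound))
  ga <- promoter_bound_genes(pa, pipe$genes)
  expect_setequal(ga, chip$truth$gene_id[chip$truth$bound_a])
  gb <- promoter_bound_genes(pb, pipe$genes)
  expect_setequal(gb, chip$truth$gene_id[chip$truth$bound_b])
  # zero co-binding config -> no co-bound regions
  cfg0 <- sim_config(seed = 5, co_binding_fraction = 0)
  chip0 <- sim_chip(cfg0, pipe$genes)
  ov0 <- overlap_peak_sets(read_peaks(chip0$peaks_a, "narrowPeak", "A"),
                           read_peaks(chip0$peaks_b, "narrowPeak", "B"))
  expect_equal(ov0$n_co_bound, 0L)
})

test_that("peak-burden comparison: medians and rank test", {
  counts <- c(a = 2L, b = 2L, c = 4L, d = 1L, e = 1L, f = 3L)
  r <- compare_peak_burden(c("a", "b", "c"), c("d", "e", "f"), counts)
  expect_equal(r$median_a, 2)
  expect_equal(r$median_b, 1)
  # identical multisets -> p ~ 1
  counts2 <- c(p = 1L, q = 2L, r = 3L, x = 1L, y = 2L, z = 3L)
  r2 <- compare_peak_burden(c("p", "q", "r"), c("x", "y", "z"), counts2)
  expect_gte(r2$p_value, 0.99)
  expect_error(compare_peak_burden(c("a"), c("a", "b"), counts), "disjoint")
  expect_error(compare_peak_burden(c("nope"), c("d"), counts), "count")
})

test_that("planted burden difference is detected", {
  withr::with_seed(12, {
    ca <- rpois(300, 2.5); cb <- rpois(300, 1.2)
  })
  counts <- c(stats::setNames(ca, sprintf("A%03d", 1:300)),
              stats::setNames(cb, sprintf("B%03d", 1:300)))
  r <- compare_peak_burden(sprintf("A%03d", 1:300), sprintf("B%03d", 1:300),
                           counts)
  expect_gt(r$median_a, r$median_b)
  expect_lt(r$p_value, 0.01)
})

test_that("signal matrix: constant field, indicator block, missing chrom", {
  flat <- coverage_track(data.frame(chrom = "c", start = 0L, end = 100000L,
                                    value = 3))
  anchors <- data.frame(chrom = "c", pos = c(5000L, 20000L), strand = c("+", "-"))
  sm <- signal_matrix(flat, anchors, flank = 1000L, bin_width = 50L)
  expect_true(all(abs(sm$matrix - 3) < 1e-12))
  expect_length(sm$profile, 40L)
  # one rectangular block covering exactly one bin
  blk <- coverage_track(data.frame(chrom = "c", start = 5000L, end = 5050L,
                                   value = 7))
  sm2 <- signal_matrix(blk, data.frame(chrom = "c", pos = 5000L),
                       flank = 1000L, bin_width = 50L)
  expect_equal(sm2$matrix[1, 21], 7)
  expect_equal(sum(sm2$matrix != 0), 1L)
  # absent chromosome -> zero row plus warning
  expect_warning(
    sm3 <- signal_matrix(blk, data.frame(chrom = c("c", "zz"),
                                         pos = c(5000L, 100L)),
                         flank = 1000L, bin_width = 50L),
    "absent")
  expect_true(all(sm3$matrix[2, ] == 0))
  expect_equal(attr(sm3$matrix, "n_missing_chrom"), 1L)
  expect_error(signal_matrix(blk, anchors, flank = 1001L, bin_width = 50L),
               "multiple")
})

test_that("minus-strand rows are reversed into 5'->3' orientation", {
  tr <- coverage_track(data.frame(chrom = "c", start = 5200L, end = 5400L,
                                  value = 2))
  plus <- signal_matrix(tr, data.frame(chrom = "c", pos = 5000L, strand = "+"),
                        flank = 1000L, bin_width = 100L)
  minus <- signal_matrix(tr, data.frame(chrom = "c", pos = 5000L, strand = "-"),
                         flank = 1000L, bin_width = 100L)
  expect_equal(minus$matrix[1, ], rev(plus$matrix[1, ]))
})

test_that("signal matrix is translation-equivariant", {
  pipe <- toy_pipeline()
  chip <- sim_chip(pipe$cfg, pipe$genes)
  tr <- read_bedgraph(chip$track_a)
  bound <- chip$truth[chip$truth$bound_a, ][1:20, ]
  anchors <- data.frame(chrom = bound$chrom, pos = bound$tss,
                        strand = bound$strand)
  sm <- signal_matrix(tr, anchors, flank = 1000L, bin_width = 50L)
  shift <- 12345L
  iv <- as.data.frame(tr$intervals)
  iv$start <- iv$start + shift; iv$end <- iv$end + shift
  anchors2 <- anchors; anchors2$pos <- anchors2$pos + shift
  sm2 <- signal_matrix(coverage_track(iv), anchors2,
                       flank = 1000L, bin_width = 50L)
  expect_equal(sm2$matrix, sm$matrix, tolerance = 1e-12)
})

test_that("planted promoter bumps peak at the center bin", {
  pipe <- toy_pipeline()
  chip <- sim_chip(pipe$cfg, pipe$genes)
  tr <- read_bedgraph(chip$track_b)
  bound <- chip$truth[chip$truth$bound_b, ]
  anchors <- data.frame(chrom = bound$chrom, pos = bound$tss,
                        strand = bound$strand)
  sm <- signal_matrix(tr, anchors, flank = 1000L, bin_width = 50L)
  amax <- which.max(sm$profile)
  expect_true(abs(amax - 20.5) <= 1.5)  # center of 40 bins
})

test_that("bedGraph reading: zeros off-track and parse validation", {
  tr <- read_bedgraph(c("c\t100\t200\t5", "c\t300\t400\t2"))
  expect_equal(nrow(tr$intervals), 2L)
  sm <- signal_matrix(tr, data.frame(chrom = "c", pos = 250L),
                      flank = 50L, bin_width = 50L)
  expect_equal(unname(sm$matrix[1, ]), c(0, 0))
  expect_error(read_bedgraph("c\t1\t2"), "4 columns")
  expect_error(coverage_track(data.frame(chrom = "c", start = c(0L, 50L),
                                         end = c(100L, 150L), value = 1)),
               "overlapping")
})
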