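test_that("gap-merging follows the strict `gap < max_gap` rule", {
  # gap 700 < 1000 merges
  expect_equal(
    merge_with_gap(intervals("chr1", c(100, 900), c(200, 1000)), 1000),
    intervals("chr1", 100, 1000))
  # gap exactly 1000 does not merge
  expect_equal(
    merge_with_gap(intervals("chr1", c(0, 1100), c(100, 1200)), 1000),
    intervals("chr1", c(0, 1100), c(100, 1200)))
  # different chromosomes never merge
  expect_equal(
    nrow(merge_with_gap(intervals(c("chr1", "chr2"), c(0, 0),
                                  c(100, 100)), 1e9)),
    2L)
  # book-ended intervals merge even at max_gap = 0
  expect_equal(
    merge_with_gap(intervals("chr1", c(0, 100), c(100, 200)), 0),
    intervals("chr1", 0, 200))
})

test_that("intersection returns per-base AND of the two sets", {
  a <- intervals("chr1", 0, 1000)
  b <- intervals("chr1", c(100, 800), c(200, 900))
  expect_equal(intersect_intervals(a, b), b)
  expect_equal(nrow(intersect_intervals(a, intervals("chr2", 0, 100))), 0L)
  an <- normalize_intervals(intervals("chr1", c(0, 500), c(100, 700)))
  expect_equal(intersect_intervals(an, an), an)
})

test_that("reciprocal overlap pairing applies the fraction to both sides", {
  a <- intervals("chr1", 0, 100)
  expect_equal(nrow(reciprocal_overlap_pairs(a, intervals("chr1", 5, 100),
                                             0.9)), 1L)
  expect_equal(nrow(reciprocal_overlap_pairs(a, intervals("chr1", 50, 150),
                                             0.9)), 0L)
  expect_equal(nrow(reciprocal_overlap_pairs(a, a, 1)), 1L)
  expect_error(reciprocal_overlap_pairs(a, a, 0),
               class = "ceatlas_param_error")
  expect_error(reciprocal_overlap_pairs(a, a, 1.2),
               class = "ceatlas_param_error")
})

test_that("exclusive keeps only zero-overlap records, half-open", {
  a <- intervals("chr1", 0, 100)
  expect_equal(nrow(exclusive_intervals(a, intervals("chr1", 99, 200))), 0L)
  expect_equal(exclusive_intervals(a, intervals("chr1", 100, 200)), a)
  expect_equal(exclusive_intervals(a, empty_b <- a[0, ]), a)
})

test_that("nearest TSS distance uses the floored midpoint and min distance", {
  tss <- tibble::tibble(chrom = "chr1", pos = 8000)
  d <- nearest_tss_distance(intervals("chr1", 10000, 11000), tss)
  expect_equal(d$distance, 2500)
  expect_equal(as.character(d$bin), "0-5 kb")
  # midpoint equal to a TSS
  d0 <- nearest_tss_distance(intervals("chr1", 7500, 8500), tss)
  expect_equal(d0$distance, 0)
  # nearer of two TSSs wins; verified by exhaustive min
  tss2 <- tibble::tibble(chrom = "chr1", pos = c(8000, 13100))
  d2 <- nearest_tss_distance(intervals("chr1", 10000, 11000), tss2)
  expect_equal(d2$distance, min(abs(10500 - tss2$pos)))
  # no TSS on the chromosome -> unassigned, not an error
  du <- nearest_tss_distance(intervals("chr9", 0, 1000), tss)
  expect_true(is.na(du$distance))
  expect_equal(as.character(du$bin), "unassigned")
})

test_that("coordinate validation rejects invalid and out-of-bounds intervals", {
  g <- genome_info("chr1", 1000)
  expect_error(validate_intervals(intervals("chr1", 200, 100)),
               class = "ceatlas_coord_error")
  expect_error(merge_with_gap(intervals("chr1", 900, 1100), 0, genome = g),
               regexp = "chr1", class = "ceatlas_coord_error")
  expect_error(validate_intervals(intervals("chrX", 0, 10), genome = g),
               class = "ceatlas_coord_error")
})

test_that("chromosome-name styles can be harmonised before matching", {
  x <- intervals(c("1", "chr2", "chrMT"), 0, 10)
  expect_equal(normalize_chrom_names(x, "chr")$chrom,
               c("chr1", "chr2", "chrMT"))
  expect_equal(normalize_chrom_names(x, "plain")$chrom, c("1", "2", "MT"))
  expect_error(normalize_chrom_names(tibble::tibble(a = 1)),
               class = "ceatlas_schema_error")
})

test_that("set operations agree with the per-base bitmap oracle", {
  glen <- 1e5
  withr::local_seed(42)
  for (rep in 1:40) {
    a <- random_interval_set(glen = glen)
    b <- random_interval_set(glen = glen)
    gap <- sample(c(0, 1, 10, 500, 1000, 5000), 1)
    expect_equal(merge_with_gap(a, gap), oracle_merge_gap(a, gap, glen))
    expect_equal(intersect_intervals(a, b), oracle_intersect(a, b, glen))
    expect_equal(exclusive_intervals(a, b), oracle_exclusive(a, b, glen))
    frac <- sample(c(0.1, 0.5, 0.9, 1), 1)
    got <- reciprocal_overlap_pairs(a, b, frac)
    want <- oracle_reciprocal_pairs(a, b, frac)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$a_idx, got$b_idx), paste(want$a_idx, want$b_idx))
  }
})

test_that("gap-merging matches IRanges::reduce as an independent engine", {
  skip_if_not_installed("IRanges")
  withr::local_seed(7)
  for (rep in 1:10) {
    x <- random_interval_set(glen = 1e5, chroms = "chrA")
    got <- merge_with_gap(x, 1000)
    ir <- IRanges::reduce(IRanges::IRanges(x$start + 1, x$end),
                          min.gapwidth = 1000)
    expect_equal(got$start, IRanges::start(ir) - 1)
    expect_equal(got$end, as.numeric(IRanges::end(ir)))
  }
})

test_that("merging is idempotent and translation-invariant", {
  withr::local_seed(11)
  for (rep in 1:10) {
    x <- random_interval_set(glen = 1e5)
    m <- merge_with_gap(x, 750)
    expect_equal(merge_with_gap(m, 750), m)
    shifted <- dplyr::mutate(x, start = start + 1e6, end = end + 1e6)
    ms <- merge_with_gap(shifted, 750)
    expect_equal(ms$start, m$start + 1e6)
    expect_equal(ms$end, m$end + 1e6)
  }
})

test_that("intersection length is bounded and pair counts shrink with frac", {
  withr::local_seed(13)
  for (rep in 1:10) {
    a <- random_interval_set(glen = 1e5)
    b <- random_interval_set(glen = 1e5)
    expect_lte(covered_bp(intersect_intervals(a, b)),
               min(covered_bp(a), covered_bp(b)))
    counts <- vapply(c(0.1, 0.5, 0.9),
                     function(f) nrow(reciprocal_overlap_pairs(a, b, f)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
    # pair membership is symmetric
    ab <- reciprocal_overlap_pairs(a, b, 0.5)
    ba <- reciprocal_overlap_pairs(b, a, 0.5)
    expect_setequal(paste(ab$a_idx, ab$b_idx), paste(ba$b_idx, ba$a_idx))
  }
})

test_that("exclusive and overlap-positive records partition the query set", {
  withr::local_seed(17)
  for (rep in 1:10) {
    a <- random_interval_set(glen = 1e5)
    b <- random_interval_set(glen = 1e5)
    excl <- exclusive_intervals(a, b)
    hit <- unique(ceatlas:::overlap_join(a, b)$a_idx)
    expect_equal(nrow(excl) + length(hit), nrow(a))
  }
})
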