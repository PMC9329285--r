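test_that("promoter masks are clamped, merged windows around TSSs", {
  g <- genome_info("chr1", 1e6)
  expect_equal(promoter_mask(tibble::tibble(chrom = "chr1", pos = 5000),
                             1000, g),
               intervals("chr1", 4000, 6000))
  expect_equal(promoter_mask(tibble::tibble(chrom = "chr1", pos = 400),
                             1000, g),
               intervals("chr1", 0, 1400))
  # overlapping windows merge into one
  expect_equal(promoter_mask(tibble::tibble(chrom = "chr1",
                                            pos = c(5000, 5500)), 1000, g),
               intervals("chr1", 4000, 6500))
  expect_error(promoter_mask(tibble::tibble(chrom = "chr1", pos = 2e6),
                             1000, g),
               class = "ceatlas_coord_error")
})

test_that("promoter filtering removes whole peaks on >= 1 bp overlap", {
  mask <- intervals("chr1", 4000, 6000)
  expect_equal(nrow(filter_promoter_peaks(intervals("chr1", 3900, 4100),
                                          mask)), 0L)
  # book-ended peak survives (half-open coordinates share no base)
  kept <- filter_promoter_peaks(intervals("chr1", 6000, 6500), mask)
  expect_equal(nrow(kept), 1L)
  peaks <- intervals("chr1", c(100, 5000), c(300, 5200))
  expect_equal(filter_promoter_peaks(peaks, peaks[0, ]), peaks)
})

test_that("conservation filtering intersects then gap-merges sub-blocks", {
  peak <- intervals("chr1", 0, 1000)
  cons <- intervals("chr1", c(100, 800), c(200, 900))
  # two conserved fragments 600 bp apart merge across the non-conserved gap
  expect_equal(conserved_merged_regions(peak, cons, 1000),
               intervals("chr1", 100, 900))
  # peak fully inside one block passes unchanged
  expect_equal(conserved_merged_regions(peak, intervals("chr1", 0, 5000),
                                        1000), peak)
  # peak with no conserved base is dropped
  expect_equal(nrow(conserved_merged_regions(peak,
                                             intervals("chr1", 5000, 6000),
                                             1000)), 0L)
  expect_warning(out <- conserved_merged_regions(peak, peak[0, ], 1000),
                 regexp = "empty")
  expect_equal(nrow(out), 0L)
})

test_that("state classification spans overlap components of the two marks", {
  # overlapping marks -> one strongly-active union span
  ces <- classify_states(intervals("chr1", 0, 500),
                         intervals("chr1", 400, 800), "A")
  expect_equal(ces$state, "strongly_active")
  expect_equal(c(ces$start, ces$end), c(0, 800))
  # disjoint marks -> active + poised
  ces2 <- classify_states(intervals("chr1", 0, 500),
                          intervals("chr1", 1000, 1500), "A")
  expect_equal(sort(ces2$state), c("active", "poised"))
  # chained overlap closes transitively into one component
  ces3 <- classify_states(intervals("chr1", c(0, 700), c(500, 900)),
                          intervals("chr1", 400, 800), "A")
  expect_equal(nrow(ces3), 1L)
  expect_equal(c(ces3$start, ces3$end, ces3$state),
               c("0", "900", "strongly_active"))
  # book-ended marks do NOT join (>= 1 bp overlap required)
  ces4 <- classify_states(intervals("chr1", 0, 500),
                          intervals("chr1", 500, 800), "A")
  expect_equal(sort(ces4$state), c("active", "poised"))
})

test_that("state sets partition the union of the two conserved mark sets", {
  withr::local_seed(23)
  for (rep in 1:8) {
    k27 <- normalize_intervals(random_interval_set(30, 5e4))
    k4 <- normalize_intervals(random_interval_set(30, 5e4))
    ces <- classify_states(k27, k4, "T")
    by_state <- split(ces, ces$state)
    # pairwise disjoint
    for (pair in utils::combn(names(by_state), 2, simplify = FALSE)) {
      expect_equal(nrow(ceatlas:::overlap_join(by_state[[pair[1]]],
                                               by_state[[pair[2]]])), 0L)
    }
    # union of states covers exactly the union of the inputs
    expect_equal(covered_bp(ces), covered_bp(dplyr::bind_rows(k27, k4)))
  }
})

test_that("atlas construction composes the stages and records provenance", {
  atlas <- tiny_atlas()
  ces <- tidy(atlas)
  expect_s3_class(atlas, "ce_atlas")
  expect_equal(nrow(ces), 5L)
  expect_equal(as.integer(table(ces$state)[c("strongly_active", "active",
                                             "poised")]),
               c(2L, 1L, 2L))
  # A's strongly-active spans the union of its two overlapping mark peaks
  sa <- ces[ces$tissue == "A" & ces$state == "strongly_active", ]
  expect_equal(c(sa$start, sa$end), c(10000, 11200))
  expect_named(atlas$provenance$stage_counts,
               c("A/H3K27ac", "A/H3K4me1", "B/H3K27ac", "B/H3K4me1"))
  g <- glance(atlas)
  expect_equal(sum(g$count), 5L)
})

test_that("atlas construction demands the full tissue-by-mark grid", {
  peaks <- tiny_peaks()
  expect_error(
    build_atlas(peaks[peaks$mark == "H3K27ac", ], tiny_tss(),
                tiny_conservation(), tiny_genome()),
    regexp = "H3K27ac", class = "ceatlas_config_error")
})

test_that("an all-promoter peak input yields an empty atlas with a warning", {
  peaks <- tiny_peaks()
  tss_on_peaks <- tibble::tibble(chrom = "chr1",
                                 pos = c(10500, 20200, 30200))
  expect_warning(atlas <- build_atlas(peaks, tss_on_peaks,
                                      tiny_conservation(), tiny_genome()),
                 regexp = "empty")
  expect_equal(nrow(tidy(atlas)), 0L)
})

test_that("CE count never grows when the merge gap is enlarged", {
  withr::local_seed(29)
  peaks <- dplyr::bind_rows(lapply(c("A", "B"), function(ti) {
    dplyr::bind_rows(lapply(c("H3K27ac", "H3K4me1"), function(mk) {
      dplyr::mutate(random_interval_set(40, 5e5, "chr1"),
                    tissue = ti, mark = mk)
    }))
  }))
  cons <- intervals("chr1", 0, 1e6)
  tssf <- tibble::tibble(chrom = "chr1", pos = 999000)
  counts <- vapply(c(0, 200, 1000, 5000), function(gp) {
    nrow(tidy(build_atlas(peaks, tssf, cons, tiny_genome(),
                          params = atlas_params(merge_gap = gp))))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("motif regions are recentred fixed-width windows, clamped at ends", {
  g <- genome_info("chr1", 1e6)
  expect_equal(prepare_motif_regions(intervals("chr1", 10000, 10300),
                                     1000, g),
               intervals("chr1", 9650, 10650))
  expect_equal(prepare_motif_regions(intervals("chr1", 100, 300), 1000, g),
               intervals("chr1", 0, 700))
  expect_equal(prepare_motif_regions(intervals("chr1", 10, 20), 1, g),
               intervals("chr1", 15, 16))
})

test_that("background sampling is seeded, uniform, and honors exclusions", {
  g <- genome_info("chr1", 1e7)
  expect_equal(nrow(sample_background_regions(g, 0, 1000)), 0L)
  r1 <- sample_background_regions(g, 200, 1000, seed = 5)
  r2 <- sample_background_regions(g, 200, 1000, seed = 5)
  expect_identical(r1, r2)
  r3 <- sample_background_regions(g, 1000, 1000, seed = 6)
  ks <- suppressWarnings(
    stats::ks.test(r3$start / (1e7 - 1000 + 1), "punif"))
  expect_gt(ks$p.value, 0.01)
  excl <- intervals("chr1", 0, 9.5e6)
  r4 <- sample_background_regions(g, 50, 1000, seed = 7, exclude = excl)
  expect_true(all(r4$start >= 9.5e6))
  expect_error(sample_background_regions(g, 50, 1000, seed = 8,
                                         exclude = intervals("chr1", 0, 1e7),
                                         max_tries = 500),
               class = "ceatlas_runtime_error")
})
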