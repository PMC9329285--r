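test_that("DEG selection is strict at both thresholds", {
  de <- tibble::tibble(
    gene_id = c("RUNX2", "at_lfc", "at_padj", "down", "flat"),
    log2fc = c(2.5, 0.5, 1.2, -0.8, 0.1),
    padj = c(4.5e-23, 1e-10, 0.05, 1e-4, 0.9))
  sel <- select_degs(de)
  expect_equal(sel$direction,
               c("up_a", "ns", "ns", "up_b", "ns"))
  # thresholds are parameters
  expect_equal(select_degs(de, lfc_min = 0.09, padj_max = 0.95)$direction,
               c("up_a", "up_a", "up_a", "up_b", "up_a"))
  expect_error(select_degs(de[, c("gene_id", "padj")]),
               regexp = "log2fc", class = "ceatlas_schema_error")
})

mk_degs <- function(gene_id, chrom, tss) {
  tibble::tibble(gene_id = gene_id, chrom = chrom, tss = tss)
}

test_that("TAD-resident genes pair with every CE overlapping their TADs", {
  tads <- intervals("chr1", 0, 2e6, name = "T1")
  ces <- intervals("chr1", 100000, 101000, id = "ce1")
  asg <- assign_ces_to_degs(ces, mk_degs("g1", "chr1", 5e5), tads)
  expect_equal(nrow(asg), 1L)
  expect_equal(asg$mechanism, "tad")
  expect_equal(asg$tad_id, "T1")
  expect_equal(asg$distance_bp, abs(100500 - 5e5))
  # two DEGs in one TAD share the CE -> two pairs
  asg2 <- assign_ces_to_degs(ces, mk_degs(c("g1", "g2"), "chr1",
                                          c(5e5, 1.5e6)), tads)
  expect_equal(nrow(asg2), 2L)
  expect_setequal(asg2$gene_id, c("g1", "g2"))
  # a CE merely *overlapping* the TAD boundary still pairs by default ...
  straddle <- intervals("chr1", 1999000, 2001000, id = "ce2")
  expect_equal(nrow(assign_ces_to_degs(straddle,
                                       mk_degs("g1", "chr1", 5e5), tads)),
               1L)
  # ... but not under strict containment
  expect_equal(nrow(assign_ces_to_degs(straddle,
                                       mk_degs("g1", "chr1", 5e5), tads,
                                       containment = TRUE)),
               0L)
})

test_that("genes outside all TADs fall back to the 1 Mb window", {
  tads <- intervals("chr1", 0, 1e6, name = "T1")
  degs <- mk_degs("g1", "chr1", 5e6)  # in no TAD
  near <- intervals("chr1", 5.9e6, 5.901e6, id = "near")   # 0.9 Mb away
  far <- intervals("chr1", 6.2e6, 6.201e6, id = "far")     # 1.2 Mb away
  asg <- assign_ces_to_degs(dplyr::bind_rows(near, far), degs, tads)
  expect_equal(asg$ce_id, "near")
  expect_equal(asg$mechanism, "window")
  expect_true(is.na(asg$tad_id))
  # nested/overlapping TADs: CEs of all TADs holding the TSS are used
  nested <- intervals("chr1", c(0, 4e5), c(1e6, 6e5),
                      name = c("outer", "inner"))
  ces <- intervals("chr1", c(1e5, 4.5e5), c(1.01e5, 4.51e5),
                   id = c("in_outer", "in_inner"))
  asg2 <- assign_ces_to_degs(ces, mk_degs("g1", "chr1", 5e5), nested)
  expect_setequal(asg2$ce_id, c("in_outer", "in_inner"))
  # genes without TSS are skipped with a warning
  expect_warning(
    asg3 <- assign_ces_to_degs(ces, mk_degs(c("g1", "g2"), "chr1",
                                            c(5e5, NA)), nested),
    regexp = "g2")
  expect_setequal(unique(asg3$gene_id), "g1")
})

test_that("every assignment satisfies its mechanism's invariant", {
  study <- cached_study("noisy")
  tads <- study$inputs$tads
  degs <- study$degs
  for (ti in study$truth$tissues) {
    asg <- study$assignments[[ti]]
    expect_gt(nrow(asg), 0)
    ces <- exclusive_ces(study$atlas, ti)
    for (i in seq_len(nrow(asg))) {
      ce <- ces[ces$id == asg$ce_id[[i]], ]
      gene <- degs[degs$gene_id == asg$gene_id[[i]], ]
      if (asg$mechanism[[i]] == "tad") {
        tad <- tads[tads$tad_id == asg$tad_id[[i]], ]
        expect_true(ce$start < tad$end && ce$end > tad$start)
        expect_true(gene$tss >= tad$start && gene$tss < tad$end)
      } else {
        in_any_tad <- any(tads$chrom == gene$chrom &
                            tads$start <= gene$tss & gene$tss < tads$end)
        expect_false(in_any_tad)
        gap_to_ce <- max(ce$start - (gene$tss + 1), gene$tss - ce$end, 0)
        expect_lte(gap_to_ce, 1e6)
      }
    }
  }
})

test_that("genome-tiling TADs leave no work for the window fallback", {
  tads <- intervals("chr1", c(0, 5e5), c(5e5, 1e6))
  ces <- intervals("chr1", 1e5, 1.01e5, id = "ce1")
  degs <- mk_degs(c("g1", "g2"), "chr1", c(1e3, 9e5))
  asg <- assign_ces_to_degs(ces, degs, tads)
  expect_true(all(asg$mechanism == "tad"))
})

test_that("SNP membership in CEs is half-open", {
  ces <- tibble::tibble(chrom = "chr1", start = 100, end = 200,
                        id = "ce1", state = "strongly_active",
                        tissue = "A")
  snps <- tibble::tibble(rsid = c("rs1", "rs2", "rs3"), chrom = "chr1",
                         pos = c(150, 200, 100),
                         trait = c("OA", "OA", "height"))
  hits <- snps_in_ces(snps, ces)
  expect_setequal(hits$rsid, c("rs1", "rs3"))  # pos 200 == end is outside
  expect_equal(hits$trait[hits$rsid == "rs1"], "OA")
  expect_equal(unique(hits$state), "strongly_active")
})

test_that("planted SNPs inside enhancers are all and only recovered", {
  study <- cached_study("clean")
  truth <- study$truth
  hits <- study$snp_overlaps
  inside <- truth$snps[truth$snps$inside, ]
  # every inside SNP is found; no outside SNP is
  expect_setequal(intersect(hits$rsid, inside$rsid), inside$rsid)
  expect_equal(nrow(dplyr::filter(hits,
                                  .data$rsid %in%
                                    truth$snps$rsid[!truth$snps$inside])),
               0L)
  # exhaustive membership check row by row
  ces <- tidy(study$atlas)
  for (i in seq_len(min(nrow(hits), 50))) {
    ce <- ces[ces$id == hits$ce_id[[i]], ]
    expect_true(ce$start <= hits$pos[[i]] && hits$pos[[i]] < ce$end)
  }
})
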