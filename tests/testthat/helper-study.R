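# Lazily cached end-to-end synthetic studies shared across test files
# (the study conditions: 50 enhancers per category on a 20 Mb two-
# chromosome genome, seed 1; noise off or at defaults).

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(which = c("clean", "noisy")) {
  which <- match.arg(which)
  if (is.null(.study_cache[[which]])) {
    noise <- if (which == "clean") no_noise() else noise_params()
    .study_cache[[which]] <- suppressWarnings(
      run_synthetic_study(sim_params(), noise = noise, seed = 1))
  }
  .study_cache[[which]]
}

tiny_genome <- function() genome_info("chr1", 1e6)

# A minimal hand-built two-tissue atlas: tissue A has one strongly-active
# (both marks at 10k-11k), one active (20k-20.5k) and one poised
# (30k-30.4k) enhancer; tissue B shares the strongly-active region,
# carries only H3K4me1 at 10k-11k is not used -- see the peak table below.
tiny_peaks <- function() {
  dplyr::bind_rows(
    tibble::tibble(tissue = "A", mark = "H3K27ac",
                   chrom = "chr1", start = c(10000, 20000),
                   end = c(11000, 20500)),
    tibble::tibble(tissue = "A", mark = "H3K4me1",
                   chrom = "chr1", start = c(10200, 30000),
                   end = c(11200, 30400)),
    tibble::tibble(tissue = "B", mark = "H3K27ac",
                   chrom = "chr1", start = 10000, end = 11000),
    tibble::tibble(tissue = "B", mark = "H3K4me1",
                   chrom = "chr1", start = c(10200, 30000),
                   end = c(11200, 30400)))
}

tiny_tss <- function() tibble::tibble(chrom = "chr1", pos = 500000)

tiny_conservation <- function() {
  tibble::tibble(chrom = "chr1", start = 0, end = 1e6)
}

tiny_atlas <- function() {
  build_atlas(tiny_peaks(), tiny_tss(), tiny_conservation(), tiny_genome())
}
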