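Package: ceatlas
Title: Candidate Enhancer Atlases from Two-Mark Histone ChIP-Seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds conservation-filtered candidate enhancer (CE) atlases from
    H3K27ac and H3K4me1 ChIP-seq peak sets for two tissues, classifying each
    element as strongly-active (both marks), active (H3K27ac only) or poised
    (H3K4me1 only). Provides a self-contained genomic interval algebra
    (gap-aware merging, per-base intersection, reciprocal-fraction and
    exclusive overlap), cross-tissue comparison of consensus, tissue-exclusive
    and state-switching enhancers, TSS-distance profiling, TAD-bounded
    assignment of enhancers to differentially expressed genes with a +/- 1 Mb
    fallback window, SNP-in-enhancer annotation, motif-region preparation, and
    a synthetic two-tissue epigenome generator with known ground truth for
    end-to-end validation. All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    IRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
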