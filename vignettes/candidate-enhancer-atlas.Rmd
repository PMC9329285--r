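---
title: "Methods: candidate-enhancer atlas construction and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-enhancer atlas construction and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A candidate enhancer (CE) in this package is a promoter-distal,
evolutionarily conserved genomic region carrying enhancer-associated
histone marks. Two marks are used: H3K27ac (active regulatory chromatin)
and H3K4me1 (primed/poised enhancers). The atlas is peak-set-driven: the
inputs are replicate-merged peak calls per tissue and mark, not signal
tracks, so every decision reduces to interval algebra. The classification
itself is a three-state rule on the mark combination of a region —
strongly-active (both marks), active (H3K27ac only), poised (H3K4me1
only). The biological premise, which the package takes as given rather
than tests, is that strongly-active elements are the ones enriched near
lineage-specific genes, and that a strongly-active-to-poised switch
between two tissues flags regulatory elements of tissue identity.

The pipeline per tissue and mark is:

1. **Promoter filtering.** TSS ± `promoter_flank` windows are built,
   merged, and every peak overlapping the mask by ≥ 1 bp is removed
   *whole*. Removal (rather than subtraction of the overlapping span) is
   the default because a peak straddling a promoter is most plausibly a
   promoter signal; `filter_promoter_peaks(trim = TRUE)` provides the
   subtractive alternative.
2. **Gap merging.** Peaks separated by a gap strictly smaller than
   `merge_gap` are unioned. Book-ended intervals (gap 0 under half-open
   coordinates) always merge — the convention of interval-reduction
   engines with a minimum gap width — including at `merge_gap = 0`.
3. **Conservation selection.** The merged peaks are intersected per base
   with conservation blocks, and the conserved fragments re-merged at the
   same `merge_gap`. A consequence worth knowing: a CE may contain
   non-conserved spacer between conserved sub-blocks. Conservation enters
   as a pre-computed block set in reference coordinates; deriving it from
   alignment chains is out of scope.
4. **State classification.** The two marks' conserved region sets are
   combined through their ≥ 1 bp overlap graph. Each connected component
   containing both marks yields one strongly-active CE; single-mark
   components yield active or poised CEs. Within a normalized set no two
   same-mark regions overlap, so a single-mark component is always a
   single region.

Marks are intersected with conservation *before* classification, so that
both marks' contributions are individually conserved; classifying first
and filtering afterwards would let a non-conserved mark upgrade a region's
state.

### Geometry of a strongly-active call

Whether a both-marks region should span the union or the intersection of
the two marks' intervals is genuinely open: the union maximizes
concordance with the merged-CE framing (a regulatory element whose two
marks are offset is still one element), while the intersection is the
conservative "enriched for both" reading. The package defaults to the
union span and exposes `geometry = "intersection"` in `build_atlas()` /
`classify_states()`. Under the union choice the three state sets
partition the union of the two conserved mark sets exactly — an invariant
the tests verify — which would not hold under the intersection.

## Cross-tissue comparisons

* **Consensus** CEs pair same-state regions of the two tissues at a
  reciprocal overlap fraction (`consensus_frac`, default 0.9 of *both*
  members).
* **Tissue-exclusive** CEs use the zero-overlap criterion (not even 1 bp)
  against the other tissue's same-state set. Note that a state-switching
  enhancer is, by this definition, also exclusive: it is strongly-active
  in one tissue only. The stricter any-state exclusion is available via
  `any_state = TRUE`.
* **State switches** report strongly-active CEs of one tissue overlapping
  ≥ 1 poised CE of the other. No reciprocal fraction is imposed by
  default because none is implied by the definition; the reciprocal
  variant is computed alongside in `compare_tissues()` for transparency.

## Regulatory landscapes

DEG selection is strict at both thresholds (`log2fc > 0.5`,
`padj < 0.05`): a gene sitting exactly on a threshold is not selected.
CE→gene assignment follows the TAD-first rule: a DEG whose TSS lies in
one or more TADs is paired with every CE overlapping any of those TADs
(nested/overlapping TADs contribute the union of their CEs); only a DEG
in no TAD falls back to a ±1 Mb window around its TSS, reflecting that
TAD annotations do not tile whole genomes. CE–TAD association is ≥ 1 bp
overlap rather than containment — merged CEs can straddle TAD boundaries
and containment would silently drop them — with `containment = TRUE` as
the strict variant. Both choices are recorded in the output so users can
see which rule produced a pair.

SNP positions are matched half-open (`start ≤ pos < end`). Their
coordinate convention (0- vs 1-based) must be declared explicitly at read
time (`read_snps(coords = )`); it is never guessed from the data.

## Tunable parameters

| parameter        | unit | default | rationale                                  |
|------------------|------|---------|--------------------------------------------|
| `promoter_flank` | bp   | 1000    | 1 kb each side of the TSS defines promoter-proximal |
| `merge_gap`      | bp   | 1000    | peaks/fragments < 1 kb apart are one element |
| `consensus_frac` | —    | 0.9     | reciprocal 90% overlap for cross-tissue consensus |
| `motif_width`    | bp   | 1000    | fixed-width recentred windows for motif scanning |
| assignment `window` | bp | 1e6   | ± 1 Mb regulatory reach for TAD-less genes |
| TSS distance bins | bp  | 5e3 / 5e4 / 5e5 | makes the "> 5 kb from the TSS" property directly readable |

## Numerical conventions

* Coordinates are 0-based half-open throughout; GTF input is converted on
  read (TSS of a `+` feature = start − 1; of a `−` feature = end − 1).
* Midpoints use `floor((start + end) / 2)`; a tie between equidistant
  TSSs resolves to the smaller coordinate, making distances
  deterministic.
* Distance bins are right-closed: a CE exactly 5 kb from a TSS falls in
  the 0–5 kb bin.
* Intervals extending past a chromosome end are *rejected*, not clipped,
  so annotation/genome-build mismatches surface immediately. The only
  operations that clamp are window constructions (promoter masks, motif
  regions, assignment windows), where the window is a derived object.
* Degenerate inputs: an empty conservation set warns and yields an empty
  atlas rather than failing; a tissue × mark grid with missing cells is a
  configuration error naming what was found.

## The synthetic epigenome

`simulate_truth()` plants enhancers of seven categories — three shared
states, two tissue-unique, two state-switching, `n_per_category` each
(default 50) — on a 20 Mb two-chromosome genome, together with TADs,
genes, and SNPs. Layout guarantees make the truth unambiguous under the
pipeline's rules:

* planted enhancers are pairwise > 2 × `merge_gap` apart, so merging can
  never fuse two planted elements;
* every enhancer keeps ≥ `promoter_flank` + 500 bp clear of every TSS, so
  promoter filtering never touches a planted element (the 500 bp margin
  absorbs peak-endpoint jitter);
* a `pairing_frac` fraction (default 0.6) of each tissue's unique
  enhancers shares a dedicated TAD with exactly one DEG upregulated in
  that tissue, and the remaining DEGs sit in enhancer-free TADs, so the
  planted CE–gene map is exactly the set of assignments a correct
  pipeline must output. Pairing is TAD-based only: making the ±1 Mb
  window mechanism exact as well would demand > 2 Mb of isolation per
  pair, which a 20 Mb study genome cannot afford; the window rule is
  exercised by dedicated unit tests instead.

`emit_observed_inputs()` renders the truth into observable data. Each
enhancer-mark emits one full-span peak, or with probability `split_prob`
two *overlapping* peaks each covering ~70% of the region. The overlap is
deliberate: a dropped member of a split pair then still leaves ≥ 50%
coverage, so a false-negative peak truncates a call rather than
obliterating it — mirroring how real peak callers fragment broad
enrichment. Endpoints are jittered Normal(0, `jitter_sd`), peaks are
dropped at `fn_rate`, and spurious peaks appear at `spurious_per_mb`.
Conservation covers a `conservation_coverage` fraction of each enhancer
at a uniformly random offset, plus background blocks. DE effect sizes for
planted DEGs are ±(1 + |Normal(0, 0.5)|) with adjusted p of 10^−U(5, 30);
null genes draw log2FC ~ Normal(0, 0.2) with adjusted p ~ U(0.2, 1). The
defaults (jitter 20 bp, 5% dropout, 0.1 spurious peaks/Mb, 90%
conservation coverage) were fixed at design time to echo the regime of a
real two-tissue study — hundreds of DEGs, thousands-scale CE sets scaled
down to desk size — not to match any particular dataset's counts.

What the simulator deliberately does **not** emulate: read-level ChIP-seq
(no fastq/BAM, no fragment-length artefacts), replicate-to-replicate peak
variability (inputs are replicate-merged by definition), sequence content
(motif scanning itself is out of scope), and correlated noise between the
two marks. Passing the recovery tests therefore shows the *logic* of the
pipeline is correct under realistic interval-level noise; it does not
certify performance on any real dataset's peak-caller idiosyncrasies.

### Recovery scoring

A planted enhancer counts as recovered when a same-tissue, same-state
atlas CE overlaps it reciprocally at ≥ 0.5 — loose enough to tolerate the
~70% truncation a single dropped split-peak causes, strict enough that a
neighbouring element cannot masquerade as a match (elements are > 2 kb
apart). In the noise-free limit the pipeline must reproduce the truth
*exactly* — region sets, exclusive and switch sets, CE–gene pairs — and
the test suite asserts this as set identities, not via the scoring
tolerance.

## Problem sizes

The test suite and the acceptance script run the full study at 50
enhancers per category (350 planted elements, 300 genes, 100 TADs, 300
SNPs) on the 20 Mb genome, with 200 random instances of ≤ 50 intervals on
≤ 100 kb genomes for the bitmap-oracle equivalence checks — sizes chosen
so the whole suite completes in about two minutes while every code path,
including the rejection-sampling feasibility errors, is exercised.

## Known limitations

* The interval engine is designed for desk-scale genomes (up to millions
  of intervals, not billions); there are no interval trees, just sorted
  sweeps and binary searches.
* Set operations ignore strand (enhancer regions are unstranded); strand
  is carried as metadata only.
* Chromosome names are matched as exact strings; mixing `chr1`/`1`
  conventions between inputs is the user's responsibility to normalise.
* The two-tissue comparison is hard-wired to exactly two tissues; a
  multi-tissue generalisation would need a different consensus/exclusive
  formulation.
* `padj` values are taken as given from the DE table; the package applies
  thresholds but does not recompute multiple-testing corrections.
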