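# ceatlas

Tools for building and interrogating **candidate enhancer (CE) atlases**
from two-mark histone ChIP-seq peak data, in the two-tissue comparative
setting typical of developmental epigenomics (the package's vocabulary
follows the embryonic synovial-joint case: an *interzone* tissue compared
with the adjacent *phalange* cartilage).

## What it computes

Enhancers carry characteristic histone modifications: H3K27ac marks active
regulatory chromatin, H3K4me1 marks primed/poised enhancers. Given
replicate-merged peak calls for both marks in two tissues, `ceatlas`:

1. removes promoter-proximal peaks (any peak overlapping a ±1 kb window
   around a TSS),
2. merges nearby peaks (separated by < 1 kb),
3. keeps only evolutionarily conserved sequence (per-base intersection with
   conservation blocks, then re-merging fragments < 1 kb apart), and
4. classifies each resulting region by its mark combination:

   | marks present        | CE state        |
   |----------------------|-----------------|
   | H3K27ac ∧ H3K4me1    | strongly-active |
   | H3K27ac only         | active          |
   | H3K4me1 only         | poised          |

Downstream, the package compares the two tissues' atlases — consensus CEs
(reciprocal overlap ≥ 0.9, the `bedtools intersect -f 0.9 -r` criterion),
tissue-exclusive CEs (zero overlap), and state switches (strongly-active in
one tissue, poised in the other) — profiles CE distance to the nearest TSS,
assigns tissue-exclusive strongly-active CEs to differentially expressed
genes (log2FC > 0.5, adjusted p < 0.05, both strict) within shared TADs,
falling back to a ±1 Mb window around the TSS of genes in no TAD, prepares
fixed-width recentred regions for motif scanning, and annotates SNPs lying
inside CEs.

All coordinates are 0-based half-open (BED convention). The interval
algebra underneath (gap-merging, per-base intersection, reciprocal-fraction
and exclusive overlap, nearest-TSS distances) is implemented in the package
on plain tibbles, and is validated in the test suite against per-base
bitmap oracles and against `IRanges::reduce()` as an independent engine.

Because the real study's inputs are large external datasets, the package
ships a synthetic two-tissue epigenome generator (`simulate_truth()`,
`emit_observed_inputs()`) that plants enhancers of known category —
shared, tissue-unique, and state-switching — together with TADs, DEGs,
conservation and SNPs, so the whole pipeline is verifiable end to end
against a known ground truth (`score_recovery()`).

## Worked example

```r
library(ceatlas)

study <- run_synthetic_study(sim_params(), noise_params(), seed = 1)
glance(study$atlas)
#> # A tibble: 6 × 4
#>   tissue    state           count total_bp
#>   <chr>     <chr>           <int>    <dbl>
#> 1 interzone active             53    41436
#> 2 interzone poised            102    86709
#> 3 interzone strongly_active   145   124479
#> 4 phalange  active             53    41452
#> 5 phalange  poised            100    86495
#> 6 phalange  strongly_active   144   124397
```

The simulation planted 50 enhancers per category (so each tissue carries
150 strongly-active, 50 active and 100 poised enhancers); under the default
observation noise (peak-endpoint jitter, 5% peak dropout, spurious peaks,
90% conservation coverage) the atlas recovers them with per-state F1 of
0.96–0.99:

```r
study$recovery$state_f1[, c("state", "precision", "recall", "f1")]
#>   state           precision recall    f1
#> 1 active              0.934  0.99  0.961
#> 2 poised              0.980  0.99  0.985
#> 3 strongly_active     1      0.963 0.981

study$comparison$summary
#> # A tibble: 7 × 3
#>   quantity                                state               n
#> 1 consensus_pairs                         strongly_active    44
#> 2 exclusive_interzone                     strongly_active   100
#> 3 exclusive_phalange                      strongly_active    99
#> 4 switch_interzone_to_phalange            strongly_active    48
#> 5 switch_phalange_to_interzone            strongly_active    50
#> 6 switch_reciprocal_interzone_to_phalange strongly_active    44
#> 7 switch_reciprocal_phalange_to_interzone strongly_active    49
```

100 unique + 50 switching enhancers were planted per tissue, so the
exclusive sets (100 / 99) and switch sets (48 / 50) sit within a few
percent of truth. TAD-bounded CE→gene assignment recovers the planted
enhancer–DEG pairs:

```r
head(study$assignments$interzone, 3)
#>   ce_id                             gene_id  mechanism tad_id distance_bp
#> 1 interzone:chrSim1:250855-251679   gene0003 tad       tad003       23802
#> 2 interzone:chrSim1:661571-662398   gene0007 tad       tad007        5248
#> 3 interzone:chrSim1:1119897-1120485 gene0012 tad       tad012        5048
```

Real data enters through `read_bed()` / `read_narrowpeak()`,
`read_tss()` (GTF/GFF3 or BED), `read_de_table()` and `read_snps()`, and
results leave through `write_atlas()` / `write_report_tsv()`;
`autoplot()` and `plot_tss_distance_profile()` give quick ggplot2 views.

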