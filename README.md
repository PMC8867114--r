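# peakscape

Downstream analysis of transcription-factor ChIP-seq with unequal-quality
replicates, for the common design where two related factors are profiled
and the question is which promoters each one occupies and whether bound
genes are more highly expressed.

The package picks up where the peak caller stops. It consumes MACS2
narrowPeak files, tagAlign/BED6 alignments, a GENCODE-style GTF and an
ENCODE blacklist, and provides:

* **Replicate-consensus peak filtering.** After blacklist removal, the
  best-signal replicate is thresholded at peak p ≤ 0.01 and the other
  replicate(s) at p ≤ 0.05; a best-replicate peak enters the final list
  iff it overlaps (≥ 1 bp) peaks called in the other replicate(s). The
  final peaks keep the best replicate's coordinates, summits and
  p-values.
* **Nearest-TSS annotation** into seven categories — upstream
  (−5 kb, −1 kb of the TSS), promoter (−1 kb, +0.5 kb), exon, intron,
  TES (−0.5 kb, +1 kb of the TES), downstream (+1 kb, +5 kb),
  intergenic — with a fixed precedence so every peak gets exactly one.
* **Normalized signal tracks and TSS metaprofiles.** Tags are
  deduplicated, replaced by 200 bp fragments extended 3′-ward from their
  5′ ends, piled up per base, scaled to a 10 M-tag library and averaged
  in 10 bp bins; metaprofiles average that coverage over TSS ± 2.5 kb of
  all usable genes, strand-aware.
* **Merged-region Venn counts** for 2–3 peak sets (pool, merge with
  ≥ 1 bp chaining, count merged regions per membership combination).
* **Expression stratification.** Genes shorter than 200 bp (union-exon
  model), rRNA biotypes and chrY genes are removed; per replicate
  FPKM<sub>g,r</sub> = c<sub>g,r</sub> · 10⁹ / (L<sub>g</sub> · T<sub>r</sub>)
  (c = fragment count, L = union-exon length, T = library total over
  retained genes), averaged over replicates; genes are labeled
  nonbound / dual / A-only / B-only by promoter binding and compared
  with a two-sided Welch t test on log₂(FPKM + 1).
* **A seeded synthetic-data generator** (`simulate_dataset()`) that
  produces a complete toy study — genome, gene models, planted binding
  truth, per-replicate tags and peak calls, count tables, blacklist — so
  the whole pipeline is testable offline. See the methods vignette
  (`vignettes/consensus-binding-analysis.Rmd`) for what it emulates.

All coordinates inside the package are 0-based half-open (BED
convention); GTF input is converted at the boundary. Data structures are
plain tibbles, so results compose with dplyr.

## A worked example

```r
library(peakscape)

cfg <- pipeline_config()
sim <- simulate_dataset(sim_config(), seed = 7)   # the default toy study

final_a <- consensus_pipeline(sim$peaks_a, best = 1,
                              blacklist = sim$blacklist, cfg = cfg)
final_a$report$n_final
#> [1] 75

gd <- genomic_distribution(final_a$peaks, sim$genes, cfg)
subset(gd$distribution, count > 0)
#>   category count fraction
#> 2 promoter    75        1

final_b <- consensus_pipeline(sim$peaks_b, best = 1,
                              blacklist = sim$blacklist, cfg = cfg)
venn_counts(list(A = final_a$peaks, B = final_b$peaks))
#> <venn_result> 78 merged regions from 2 sets
#> input peaks: A=75, B=44
#>   A            34
#>   B            3
#>   A&B          41

expr <- expression_pipeline(sim$counts, sim$genes,
                            final_a$peaks, final_b$peaks, cfg)
expr$comparisons
#> # A tibble: 3 × 7
#>   group_a  group_b   n_a   n_b statistic    df  p_value
#>   <chr>    <chr>   <int> <int>     <dbl> <dbl>    <dbl>
#> 1 nonbound dual      104    41    -19.0  124.  1.23e-38
#> 2 nonbound A_only    104    34    -15.7   87.1 3.55e-27
#> 3 dual     A_only     41    34      1.31  66.4 1.95e- 1
```

Reading the output: of the 86+79 per-replicate calls for factor A, 75
survive blacklist, thresholds and cross-replicate confirmation, and all
75 sit in promoter windows (the simulator plants binding at promoters;
replicate-specific noise peaks are filtered out). Merging both factors'
final peaks yields 41 shared regions — the planted dual targets — and
the planted 4× expression shift of bound genes shows up as
p ≈ 10⁻³⁸/10⁻²⁷ for dual/A-only versus nonbound, while dual and A-only
do not differ (p = 0.195), as constructed.

A thin CLI over the same functions is installed at
`<library>/peakscape/exec/peakscape` with subcommands `simulate`,
`consensus`, `annotate`, `extract-seq`, `pileup`, `metaprofile`, `venn`
and `expression`.

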