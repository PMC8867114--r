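---
title: "Consensus ChIP-seq peaks, promoter annotation and expression stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ChIP-seq peaks, promoter annotation and expression stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakscape)
```

## The analysis

peakscape implements the downstream analysis of a transcription-factor
ChIP-seq study with replicates of unequal quality, together with the
RNA-seq stratification that asks whether promoter-bound genes are more
highly expressed. The pipeline assumes peak calling itself has already
been done (MACS2 narrowPeak files are consumed, not produced) and read
alignment is upstream of the package (tags arrive as tagAlign/BED6).

Five analysis stages are exposed as plain functions over tibbles:

1. **Replicate consensus** (`consensus_pipeline()`): per replicate,
   peaks overlapping a blacklist are removed; the replicate designated
   as "best signal" is thresholded at peak p-value <= 0.01 and the other
   replicate(s) at p <= 0.05; a best-replicate peak is kept iff it
   overlaps (>= 1 bp) peaks of the other replicate(s). The final list
   keeps the best replicate's coordinates, summits and p-values.
2. **Annotation** (`genomic_distribution()`): each final peak is reduced
   to an anchor point, assigned to the gene with the nearest TSS, and
   classified into one of seven categories: upstream (-5 kb, -1 kb of
   the TSS), promoter (-1 kb, +0.5 kb), exon, intron, TES (-0.5 kb,
   +1 kb of the TES), downstream (+1 kb, +5 kb) or intergenic.
3. **Signal** (`pileup()`, `tss_metaprofile()`): tags are deduplicated,
   replaced by 200 bp fragments anchored at their 5' ends, piled up per
   base, normalized to 10 M tags and averaged over 10 bp bins; the
   metaprofile averages the same normalized coverage over
   TSS +/- 2.5 kb windows of all usable genes.
4. **Set comparison** (`venn_counts()`): peaks of 2-3 sets are pooled and
   merged with >= 1 bp chaining; each merged region is counted under the
   combination of sets that contributed peaks to it.
5. **Expression** (`expression_pipeline()`): genes shorter than 200 bp
   (union-exon length), rRNA biotypes and chrY genes are removed; FPKM
   is computed per replicate over the retained genes and averaged;
   genes are labeled nonbound / dual / A-only / B-only by promoter
   binding; groups are compared with a two-sided t test.

## Coordinate conventions

All intervals inside the package are **0-based half-open** (BED
convention); GTF input is converted on read. Consequences worth knowing:

* two intervals overlap iff they share >= 1 base; touching intervals
  (`a$end == b$start`) do not overlap and are never merged;
* the 5' position of a minus-strand BED record is `end - 1`;
* the TSS of a minus-strand gene is its highest transcribed coordinate;
  all windows ("-1 kb to +0.5 kb of the TSS", etc.) are half-open in
  stranded gene coordinates and mirrored on the minus strand.

Gene models are collapsed to gene level: the TSS is the 5'-most base over
all transcripts and the exon set is the per-gene union. Which transcript
TSS a multi-transcript gene "should" use is genuinely ambiguous at gene
level; the 5'-most convention is the default and the only one the
simulator generates (its genes have one transcript).

## Parameters that matter

All numeric conventions live in `pipeline_config()`:

| parameter | default | meaning |
|---|---|---|
| `extsize` | 200 bp | fragment length for 3'-ward tag extension |
| `norm_target_reads` | 1e7 | library size tracks are scaled to |
| `track_bin` | 10 bp | bin width for tracks and metaprofiles |
| `metaprofile_flank` | 2500 bp | TSS metaprofile half-window |
| `p_best`, `p_other` | 0.01, 0.05 | asymmetric replicate thresholds |
| `promoter_window` | (-1000, 500) | stranded window, also the binding definition |
| `summit_flank` | 500 bp | summit sequence windows for motif input |
| `min_gene_length` | 200 bp | union-exon length filter |

Choices that were genuinely open, and how they were settled:

* **Anchor point.** A peak is classified by a single point - its summit
  when present, otherwise the floored midpoint - so each peak gets
  exactly one category. Classifying by any-overlap would let one peak
  inhabit several categories and break the partition.
* **Window precedence.** For short genes the windows of one gene can
  overlap; precedence promoter > TES > upstream > downstream > exon >
  intron makes the classification a function. Promoter-proximal classes
  win because the promoter window is the analysis' operative definition
  of binding.
* **"Extended by 200 bp to its 3' end"** is implemented as *replace the
  read by a 200 bp fragment from its 5' end* (MACS2 `--extsize`
  semantics, consistent with the extension size equalling the peak
  caller's setting). The literal alternative - append 200 bp after the
  3' terminus, giving 250 bp fragments for 50 bp reads - is available
  as `extension_mode = "append"`.
* **Consensus with three replicates.** "Overlaps the peaks called in the
  other replicate(s)" is ambiguous between *every* other replicate and
  *any* other replicate; with only two replicates the readings coincide.
  The stricter `consensus_mode = "all"` is the default, `"any"` is a
  switch.
* **Best replicate.** The best-signal replicate is designated by the
  caller; `replicate_frip()` reports fraction-of-tags-in-peaks to guide
  the choice but nothing is auto-selected, because no selection metric
  is part of the method's definition.
* **Dedup key.** Duplicate removal keys on (chromosome, 5' position,
  strand): collapsing across strands would halve true coverage at
  symmetric sites.
* **t test form.** The group comparison defaults to Welch's t test on
  `log2(FPKM + 1)`: FPKM is heavy-tailed and group variances differ by
  construction. Raw-scale and pooled-variance variants are config
  switches (`log_fpkm`, `pooled_variance`).
* **Binding definition.** A gene is "promoter-bound" when any final peak
  overlaps its promoter window, which also counts peaks assigned (by
  nearest TSS) to a neighboring gene. The alternative - category of the
  assigned gene - is `binding_def = "assigned-category"`.
* **Library size.** FPKM totals are computed over the retained genes
  (filter first, then quantify); `prefilter_library_size = TRUE` uses
  pre-filter totals instead.

## Numerical details and degenerate inputs

* Thresholding works in -log10 space with a 1e-9 guard so p = 0.01
  exactly is kept regardless of decimal round-off.
* Track bins at a chromosome's end are averaged over the full bin width
  with positions past the end counting as zero, so the mass identity
  `sum(value) * bin_size = n_fragments * extsize * scale_factor` holds
  exactly for unclipped fragments.
* Nearest-TSS ties are broken by the lexicographically smaller gene id;
  annotation is therefore order-invariant and platform-stable.
* Peaks on chromosomes without genes become `intergenic` with an `NA`
  gene rather than an error; an empty peak set *is* an error for
  `genomic_distribution()` (fractions would be undefined).
* Chromosome names are matched by exact string equality everywhere;
  `check_chrom_namespaces()` warns when peak and gene namespaces are
  disjoint (the classic `"1"` vs `"chr1"` failure).
* Metaprofile windows that cross a chromosome boundary are dropped and
  counted; minus-strand windows are mirrored before averaging so that
  increasing bin index means downstream of the TSS.

## What the simulator emulates - and what it does not

`simulate_dataset()` generates the complete study from one seed: a
random ACGT genome; ~200 non-overlapping multi-exon genes on three
chromosomes (including chrY, rRNA and sub-200 bp genes so the filters
have something to remove); planted promoter binding with 30% of eligible
genes dual-bound, 15% A-exclusive and 2% B-exclusive (largest-remainder
rounding makes group sizes exact); summits at TSS + round(N(0, 50 bp))
clipped into the promoter window; per-replicate tags (uniform background
of ~20 tags/kb, 100 enrichment tags per bound site placed so extended
fragments cover the summit, 10% injected PCR duplicates); per-replicate
peak calls where each true site is detected with the replicate's
sensitivity (1.0/0.9 for factor A) and false peaks fall in intergenic
space at 5/Mb with capped significance; and a 2-replicate
negative-binomial count table with bound genes at 4x the unbound mean
(log2 fold change 2, dispersion 0.3).

Replicate peak calls are simulated directly rather than by running a
peak caller on the simulated tags: the consensus logic is what needs
testing, and direct simulation gives exact truth labels. Gene spacing
guarantees >= 5.5 kb clearance, so annotation windows of neighboring
genes cannot collide by construction.

Deliberately not emulated: realistic sequence composition, mappability
or GC bias, paired-end reads, multi-transcript genes, overlapping genes,
and enhancer (distal) binding. Passing tests therefore demonstrate the
*arithmetic* of the pipeline - coordinate handling, filtering rules,
normalization identities, test calibration - not robustness to the
artifacts of real libraries.

Problem sizes were chosen so the whole suite runs in about a minute: a
~2 Mb genome, 200 genes, ~50 k tags per sample, 500-1000 Monte-Carlo
replicates for the t-test calibration. These are the package's test
conditions, not method limits; every size is a `sim_config()` argument.

## Known limitations

* Consensus recall is bounded by the weakest replicate's sensitivity:
  with detection probability s in the other replicate, the expected
  recall of an all-mode consensus is s. High precision is the rule's
  design goal; sites missing from any required replicate are
  unrecoverable by construction.
* The genomic-distribution percentages depend on the anchor convention
  (summit vs midpoint vs any-overlap) by a percent or two on real data;
  the package fixes summit-with-midpoint-fallback.
* FPKM is within-sample normalization only; cross-condition differential
  expression should use a count-based model instead of t tests on FPKM.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config()
sim <- simulate_dataset(sim_config(), seed = 7, dir = "simdir")

final_a <- consensus_pipeline(sim$peaks_a, best = 1,
                              blacklist = sim$blacklist, cfg = cfg)
final_b <- consensus_pipeline(sim$peaks_b, best = 1,
                              blacklist = sim$blacklist, cfg = cfg)

genomic_distribution(final_a$peaks, sim$genes, cfg)$distribution
venn_counts(list(A = final_a$peaks, B = final_b$peaks))

profile <- tss_metaprofile_pair(sim$tags$chip[[1]], sim$tags$input,
                                sim$genes, sim$chrom_lengths, cfg)
expr <- expression_pipeline(sim$counts, sim$genes,
                            final_a$peaks, final_b$peaks, cfg,
                            labels = c("A", "B"))
expr$comparisons
```
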