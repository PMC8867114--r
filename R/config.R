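#' Analysis pipeline configuration
#'
#' Collects every numeric convention the pipeline uses in one place. The
#' defaults reproduce a standard single-end TF ChIP-seq workflow: reads are
#' replaced by 200 bp fragments anchored at their 5' ends (MACS2 `--extsize`
#' semantics), coverage is scaled to a 10 M-read library and averaged in
#' 10 bp bins, metaprofiles span TSS +/- 2.5 kb, the best replicate is
#' thresholded at p <= 0.01 and the remaining replicates at p <= 0.05, and
#' peaks are classified against genes using the windows
#' upstream (-5 kb, -1 kb) / promoter (-1 kb, +0.5 kb) around the TSS and
#' TES (-0.5 kb, +1 kb) / downstream (+1 kb, +5 kb) around the TES, all in
#' stranded gene coordinates. Expression analysis removes genes shorter than
#' 200 bp (union-exon length), rRNA biotypes and chrY genes.
#'
#' @param extsize Fragment length in bp used when extending tags 3'-ward.
#' @param norm_target_reads Library size that coverage tracks are scaled to.
#' @param track_bin Bin width in bp for signal tracks and metaprofiles.
#' @param metaprofile_flank Half-width in bp of the TSS metaprofile window.
#' @param summit_flank Half-width in bp of summit sequence windows.
#' @param p_best,p_other Peak p-value cutoffs (not -log10) for the best and
#'   the other replicates.
#' @param consensus_mode `"all"` requires a best-replicate peak to overlap
#'   every other replicate, `"any"` at least one.
#' @param upstream_window,promoter_window,tes_window,downstream_window
#'   Length-2 integer vectors, half-open windows in stranded gene
#'   coordinates relative to the TSS (first two) or TES (last two).
#' @param min_gene_length Minimum union-exon length (bp) kept by
#'   [filter_genes()].
#' @param excluded_chroms Chromosomes removed by [filter_genes()].
#' @param excluded_biotypes Biotype substrings removed by [filter_genes()]
#'   (matched with `grepl`, so `"rRNA"` also removes `"rRNA_pseudogene"`).
#' @param orient_metaprofile_by_strand Reverse minus-strand TSS windows so
#'   increasing bin index always points downstream of the TSS.
#' @param extension_mode `"extsize"` replaces each read by an `extsize` bp
#'   fragment from its 5' end; `"append"` keeps the read and appends
#'   `extsize` bp past its 3' terminus.
#' @param binding_def How "promoter-bound" is decided by [bound_genes()]:
#'   overlap of any final peak with the gene's promoter window
#'   (`"promoter-overlap"`) or promoter category of the peak's assigned
#'   nearest-TSS gene (`"assigned-category"`).
#' @param log_fpkm Compare groups on `log2(FPKM + 1)` rather than raw FPKM.
#' @param pooled_variance Use the pooled-variance t test instead of Welch.
#' @param prefilter_library_size Compute FPKM library sizes over the
#'   pre-filter count table instead of the retained genes.
#' @param random_seed Optional seed recorded for provenance.
#'
#' @return A list with class `"peakscape_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$promoter_window
pipeline_config <- function(extsize = 200L,
                            norm_target_reads = 1e7,
                            track_bin = 10L,
                            metaprofile_flank = 2500L,
                            summit_flank = 500L,
                            p_best = 0.01,
                            p_other = 0.05,
                            consensus_mode = c("all", "any"),
                            upstream_window = c(-5000L, -1000L),
                            promoter_window = c(-1000L, 500L),
                            tes_window = c(-500L, 1000L),
                            downstream_window = c(1000L, 5000L),
                            min_gene_length = 200L,
                            excluded_chroms = "chrY",
                            excluded_biotypes = "rRNA",
                            orient_metaprofile_by_strand = TRUE,
                            extension_mode = c("extsize", "append"),
                            binding_def = c("promoter-overlap",
                                            "assigned-category"),
                            log_fpkm = TRUE,
                            pooled_variance = FALSE,
                            prefilter_library_size = FALSE,
                            random_seed = NULL) {
  consensus_mode <- match.arg(consensus_mode)
  extension_mode <- match.arg(extension_mode)
  binding_def <- match.arg(binding_def)
  stopifnot(
    extsize > 0, norm_target_reads > 0, track_bin > 0,
    metaprofile_flank > 0, metaprofile_flank %% track_bin == 0,
    summit_flank > 0,
    p_best > 0, p_best <= 1, p_other > 0, p_other <= 1,
    length(upstream_window) == 2, length(promoter_window) == 2,
    length(tes_window) == 2, length(downstream_window) == 2,
    upstream_window[1] < upstream_window[2],
    promoter_window[1] < promoter_window[2],
    tes_window[1] < tes_window[2],
    downstream_window[1] < downstream_window[2],
    min_gene_length >= 0
  )
  structure(
    list(
      extsize = as.integer(extsize),
      norm_target_reads = norm_target_reads,
      track_bin = as.integer(track_bin),
      metaprofile_flank = as.integer(metaprofile_flank),
      summit_flank = as.integer(summit_flank),
      p_best = p_best,
      p_other = p_other,
      consensus_mode = consensus_mode,
      upstream_window = as.integer(upstream_window),
      promoter_window = as.integer(promoter_window),
      tes_window = as.integer(tes_window),
      downstream_window = as.integer(downstream_window),
      min_gene_length = as.integer(min_gene_length),
      excluded_chroms = excluded_chroms,
      excluded_biotypes = excluded_biotypes,
      orient_metaprofile_by_strand = isTRUE(orient_metaprofile_by_strand),
      extension_mode = extension_mode,
      binding_def = binding_def,
      log_fpkm = isTRUE(log_fpkm),
      pooled_variance = isTRUE(pooled_variance),
      prefilter_library_size = isTRUE(prefilter_library_size),
      random_seed = random_seed
    ),
    class = "peakscape_config"
  )
}

#' @export
print.peakscape_config <- function(x, ...) {
  cat("<peakscape pipeline config>\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = ", "), character(1))
  for (nm in names(flat)) cat(sprintf("  %-28s %s\n", nm, flat[[nm]]))
  invisible(x)
}
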