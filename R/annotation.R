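#' Peak-to-gene annotation
#'
#' Each peak is reduced to a single anchor point (its summit when present,
#' otherwise the interval midpoint), assigned to the gene with the nearest
#' TSS on the same chromosome, and classified into exactly one of seven
#' location categories - upstream, promoter, exon, intron, TES, downstream,
#' intergenic - using half-open windows in stranded gene coordinates. When
#' a short gene's windows overlap, categories are resolved by the fixed
#' precedence promoter > TES > upstream > downstream > exon > intron.
#'
#' @name annotation
NULL

# Ordered category levels (also the precedence order used for reporting).
annotation_categories <- function() {
  c("upstream", "promoter", "exon", "intron", "TES", "downstream",
    "intergenic")
}

#' Anchor point of a peak
#'
#' The absolute genomic position representing the peak: `start +
#' summit_offset` when a summit is present, else the floored midpoint.
#'
#' @param peaks Peak tibble.
#' @return A numeric vector of 0-based positions.
#' @export
anchor_point <- function(peaks) {
  check_intervals(peaks, "peaks")
  summit <- peaks$summit_offset %||% rep(NA_real_, nrow(peaks))
  ifelse(!is.na(summit), peaks$start + summit,
         floor((peaks$start + peaks$end) / 2))
}

#' Assign each peak to the gene with the nearest TSS
#'
#' Distances are measured from the peak's anchor point to gene TSSs on the
#' same chromosome. The signed distance is reported in gene orientation
#' (positive = downstream of the TSS): `anchor - tss` for plus-strand
#' genes and `tss - anchor` for minus-strand genes. Ties in absolute
#' distance are broken by the lexicographically smaller `gene_id`. Peaks
#' on chromosomes without genes get an `NA` gene and distance.
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble (see [read_gtf_genes()]).
#' @return A tibble parallel to `peaks` with `gene_id` and
#'   `signed_distance`.
#' @export
nearest_tss_gene <- function(peaks, genes) {
  check_intervals(peaks, "peaks")
  check_genes(genes)
  anchor <- anchor_point(peaks)
  gene_id <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  if (!nrow(genes) || !nrow(peaks)) {
    return(tibble(gene_id = gene_id, signed_distance = dist))
  }
  # One representative gene per distinct (chrom, tss): the lexicographically
  # smallest gene_id, which is exactly the tie-break rule.
  reps <- genes[order(genes$chrom, genes$tss, genes$gene_id), ]
  reps <- reps[!duplicated(reps[c("chrom", "tss")]), ]
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    g <- reps[reps$chrom == ch, ]
    if (!nrow(g)) next
    tssv <- g$tss  # sorted within chrom by construction
    idx <- findInterval(anchor[pi], tssv)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(tssv))
    d_left <- ifelse(idx >= 1, abs(anchor[pi] - tssv[left]), Inf)
    d_right <- ifelse(idx < length(tssv), abs(tssv[right] - anchor[pi]), Inf)
    use_left <- d_left < d_right |
      (d_left == d_right & g$gene_id[left] <= g$gene_id[right])
    pick <- ifelse(use_left, left, right)
    gene_id[pi] <- g$gene_id[pick]
    sign <- ifelse(g$strand[pick] == "+", 1, -1)
    dist[pi] <- sign * (anchor[pi] - g$tss[pick])
  }
  tibble(gene_id = gene_id, signed_distance = dist)
}

# Internal: vectorized category call for anchors paired with their
# assigned genes (rows with NA gene_id become intergenic).
classify_anchor <- function(anchor, genes_at, cfg) {
  n <- length(anchor)
  if (!n) return(factor(character(), levels = annotation_categories()))
  strand <- genes_at$strand
  sgn <- ifelse(strand == "+", 1, -1)
  d_tss <- sgn * (anchor - genes_at$tss)
  d_tes <- sgn * (anchor - genes_at$tes)
  in_win <- function(d, w) !is.na(d) & d >= w[1] & d < w[2]
  in_body <- !is.na(genes_at$start) &
    anchor >= genes_at$start & anchor < genes_at$end
  in_exon <- map2_lgl(genes_at$exons, anchor, function(ex, a) {
    !is.null(ex) && any(ex$start <= a & a < ex$end)
  })
  category <- dplyr::case_when(
    in_win(d_tss, cfg$promoter_window) ~ "promoter",
    in_win(d_tes, cfg$tes_window) ~ "TES",
    in_win(d_tss, cfg$upstream_window) ~ "upstream",
    in_win(d_tes, cfg$downstream_window) ~ "downstream",
    in_body & in_exon ~ "exon",
    in_body ~ "intron",
    TRUE ~ "intergenic"
  )
  factor(category, levels = annotation_categories())
}

#' Classify peaks relative to their assigned genes
#'
#' See the module description (`?annotation`) for windows and precedence.
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble.
#' @param cfg A [pipeline_config()].
#' @return A tibble parallel to `peaks`: peak columns plus `anchor`,
#'   `gene_id`, `signed_distance` and `category`.
#' @export
annotate_peaks <- function(peaks, genes, cfg = pipeline_config()) {
  check_intervals(peaks, "peaks")
  check_genes(genes)
  if (nrow(peaks) && nrow(genes)) {
    check_chrom_namespaces(peaks$chrom, genes$chrom, "peaks", "genes")
  }
  assign <- nearest_tss_gene(peaks, genes)
  ord <- match(assign$gene_id, genes$gene_id)
  genes_at <- genes[ifelse(is.na(ord), 1L, ord), , drop = FALSE]
  # blank out rows without an assigned gene so they fall to intergenic
  if (nrow(genes_at)) {
    blank <- is.na(ord)
    genes_at$start[blank] <- NA_real_
    genes_at$end[blank] <- NA_real_
    genes_at$tss[blank] <- NA_real_
    genes_at$tes[blank] <- NA_real_
    genes_at$exons[blank] <- list(NULL)
  }
  anchor <- anchor_point(peaks)
  out <- peaks
  out$anchor <- anchor
  out$gene_id <- assign$gene_id
  out$signed_distance <- assign$signed_distance
  out$category <- classify_anchor(anchor, genes_at, cfg)
  out
}

#' Genomic distribution of a peak set
#'
#' Annotates every peak and tabulates counts and fractions over the seven
#' location categories.
#'
#' @param peaks Non-empty peak tibble.
#' @param genes Gene-model tibble.
#' @param cfg A [pipeline_config()].
#' @return A list: `annotation` (per-peak table from [annotate_peaks()])
#'   and `distribution` (tibble with `category`, `count`, `fraction`;
#'   fractions sum to 1).
#' @export
genomic_distribution <- function(peaks, genes, cfg = pipeline_config()) {
  check_intervals(peaks, "peaks", require_rows = FALSE)
  if (nrow(peaks) == 0) {
    abort("`peaks` is empty: the genomic distribution is undefined; supply a non-empty peak set")
  }
  ann <- annotate_peaks(peaks, genes, cfg)
  counts <- table(ann$category)
  dist <- tibble(
    category = factor(names(counts), levels = annotation_categories()),
    count = as.integer(counts),
    fraction = as.integer(counts) / nrow(ann)
  )
  list(annotation = ann, distribution = dist)
}

#' Extract summit-centered sequence windows
#'
#' Returns the `[anchor - flank, anchor + flank)` sequence around each
#' peak's anchor point (summit when present, midpoint otherwise), in
#' uppercase, named `chrom:start-end`. Windows that would run past either
#' end of their chromosome are dropped, with the dropped count reported in
#' a message and as attribute `n_dropped`.
#'
#' @param peaks Peak tibble.
#' @param genome A `DNAStringSet` or path to a FASTA file.
#' @param cfg A [pipeline_config()]; `cfg$summit_flank` sets the
#'   half-width.
#' @return A `Biostrings::DNAStringSet`.
#' @export
extract_summit_windows <- function(peaks, genome, cfg = pipeline_config()) {
  check_intervals(peaks, "peaks")
  genome <- load_genome(genome)
  missing_chroms <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chroms)) {
    abort(sprintf("chromosome(s) absent from FASTA: %s",
                  paste(missing_chroms, collapse = ", ")))
  }
  anchor <- anchor_point(peaks)
  if (any(is.na(peaks$summit_offset %||% NA))) {
    inform(sprintf(
      "%d peak(s) lack a summit; their window is centered on the midpoint",
      sum(is.na(peaks$summit_offset %||% rep(NA, nrow(peaks))))
    ))
  }
  flank <- cfg$summit_flank
  lo <- anchor - flank
  hi <- anchor + flank
  len <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  ok <- lo >= 0 & hi <= len
  if (any(!ok)) {
    inform(sprintf("dropped %d window(s) exceeding chromosome bounds",
                   sum(!ok)))
  }
  seqs <- Biostrings::DNAStringSet(vapply(which(ok), function(i) {
    toupper(as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                            start = lo[i] + 1,
                                            end = hi[i])))
  }, character(1)))
  names(seqs) <- sprintf("%s:%s-%s", peaks$chrom[ok],
                         fmt_num(lo[ok]), fmt_num(hi[ok]))
  attr(seqs, "n_dropped") <- sum(!ok)
  seqs
}
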