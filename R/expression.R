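#' Expression stratification of promoter-bound genes
#'
#' Gene expression is quantified as FPKM (fragments per kilobase of
#' union-exon model per million assigned fragments), computed per
#' replicate and averaged across replicates. Genes are filtered before
#' quantification (union-exon length < 200 bp, rRNA biotypes, chrY), then
#' stratified by whether final ChIP peaks overlap their promoter window,
#' and group expression is compared with a two-sided t test (Welch on
#' `log2(FPKM + 1)` by default).
#'
#' @name expression
NULL

#' Filter the gene universe for expression analysis
#'
#' Removes genes with union-exon length below `cfg$min_gene_length`, genes
#' whose biotype matches any of `cfg$excluded_biotypes` (substring match),
#' and genes on `cfg$excluded_chroms`. Removal counts per criterion (first
#' matching rule, in that order) are attached as attribute `removed`.
#'
#' @param genes Gene-model tibble.
#' @param cfg A [pipeline_config()].
#' @return The retained genes.
#' @export
filter_genes <- function(genes, cfg = pipeline_config()) {
  check_genes(genes)
  too_short <- genes$union_exon_length < cfg$min_gene_length
  bad_biotype <- Reduce(`|`, lapply(cfg$excluded_biotypes, function(b) {
    grepl(b, genes$biotype, fixed = TRUE)
  }), init = rep(FALSE, nrow(genes)))
  bad_chrom <- genes$chrom %in% cfg$excluded_chroms
  drop <- too_short | bad_biotype | bad_chrom
  out <- genes[!drop, , drop = FALSE]
  attr(out, "removed") <- c(
    short = sum(too_short),
    biotype = sum(bad_biotype & !too_short),
    chrom = sum(bad_chrom & !too_short & !bad_biotype)
  )
  out
}

#' Per-replicate and replicate-averaged FPKM
#'
#' For replicate r, `FPKM[g, r] = counts[g, r] * 1e9 /
#' (union_exon_length[g] * T[r])` with `T[r]` the replicate's total count
#' over the genes in `counts` (the retained gene set; set
#' `cfg$prefilter_library_size` and pass `library_sizes` to use pre-filter
#' totals). `fpkm_mean` is the arithmetic mean over replicates.
#'
#' @param counts Tibble with `gene_id` plus one numeric column per
#'   replicate; every gene must be present in `genes`.
#' @param genes Gene-model tibble supplying `union_exon_length`.
#' @param cfg A [pipeline_config()].
#' @param library_sizes Optional named totals per replicate, overriding
#'   the column sums (used with `cfg$prefilter_library_size`).
#' @return A tibble: `gene_id`, `union_exon_length`, the count columns,
#'   one `fpkm_<replicate>` column per replicate, and `fpkm_mean`.
#' @export
fpkm <- function(counts, genes, cfg = pipeline_config(),
                 library_sizes = NULL) {
  check_genes(genes)
  if (!"gene_id" %in% names(counts)) abort("`counts` lacks gene_id")
  rep_cols <- setdiff(names(counts), "gene_id")
  if (!length(rep_cols)) abort("`counts` has no replicate columns")
  missing_genes <- setdiff(counts$gene_id, genes$gene_id)
  if (length(missing_genes)) {
    abort(sprintf("gene(s) in the count table absent from the gene models: %s",
                  paste(head(missing_genes, 5), collapse = ", ")))
  }
  for (cn in rep_cols) {
    if (!is.numeric(counts[[cn]]) || any(counts[[cn]] < 0)) {
      abort(sprintf("count column '%s' must be non-negative numeric", cn))
    }
  }
  totals <- if (is.null(library_sizes)) {
    vapply(rep_cols, function(cn) sum(counts[[cn]]), numeric(1))
  } else {
    if (!all(rep_cols %in% names(library_sizes))) {
      abort("`library_sizes` must name every replicate column")
    }
    library_sizes[rep_cols]
  }
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    abort(sprintf("replicate(s) with zero total counts: %s",
                  paste(zero, collapse = ", ")))
  }
  len <- genes$union_exon_length[match(counts$gene_id, genes$gene_id)]
  out <- counts
  out$union_exon_length <- len
  fpkm_cols <- sprintf("fpkm_%s", rep_cols)
  for (i in seq_along(rep_cols)) {
    out[[fpkm_cols[i]]] <- counts[[rep_cols[i]]] * 1e9 /
      (len * totals[[rep_cols[i]]])
  }
  out$fpkm_mean <- rowMeans(as.matrix(out[fpkm_cols]))
  out
}

#' Genes with a final peak at their promoter
#'
#' Under the default `binding_def = "promoter-overlap"` a gene is bound
#' when any peak shares >= 1 bp with its promoter window
#' (`cfg$promoter_window` in stranded coordinates around the TSS, i.e.
#' `[TSS - 1000, TSS + 500)` by default). The alternative
#' `"assigned-category"` definition instead marks the genes to which at
#' least one peak was assigned with category `promoter` by
#' [annotate_peaks()].
#'
#' @param peaks Final peak tibble (a consensus output).
#' @param genes Gene-model tibble.
#' @param cfg A [pipeline_config()].
#' @return A sorted character vector of bound gene ids.
#' @export
bound_genes <- function(peaks, genes, cfg = pipeline_config()) {
  check_intervals(peaks, "peaks")
  check_genes(genes)
  if (!nrow(genes)) return(character())
  if (cfg$binding_def == "assigned-category") {
    ann <- annotate_peaks(peaks, genes, cfg)
    return(sort(unique(ann$gene_id[!is.na(ann$gene_id) &
                                     ann$category == "promoter"])))
  }
  windows <- promoter_windows(genes, cfg)
  hit <- overlaps_any(windows, peaks)
  sort(unique(windows$gene_id[hit]))
}

# Internal: genomic (unstranded) span of each gene's stranded promoter
# window. For window [w1, w2) around the TSS: plus strand
# [tss + w1, tss + w2); minus strand positions x with tss - x in [w1, w2)
# => [tss - w2 + 1, tss - w1 + 1). Clipped at 0.
promoter_windows <- function(genes, cfg = pipeline_config()) {
  w <- cfg$promoter_window
  start <- ifelse(genes$strand == "+", genes$tss + w[1],
                  genes$tss - w[2] + 1)
  end <- ifelse(genes$strand == "+", genes$tss + w[2],
                genes$tss - w[1] + 1)
  tibble(chrom = genes$chrom, start = pmax(0, start), end = end,
         gene_id = genes$gene_id)
}

#' Two-sided t tests between expression groups
#'
#' Compares `log2(fpkm_mean + 1)` (or raw FPKM with `cfg$log_fpkm =
#' FALSE`) between every pair of the requested groups with a two-sided
#' Welch t test (pooled variance with `cfg$pooled_variance = TRUE`).
#'
#' @param records Tibble with `gene_id`, `fpkm_mean` and `group`.
#' @param groups Character vector (>= 2) of group labels to compare.
#' @param cfg A [pipeline_config()].
#' @return A list: `comparisons` (tibble `group_a`, `group_b`, `n_a`,
#'   `n_b`, `statistic`, `df`, `p_value`) and `values` (long-format tibble
#'   `gene_id`, `group`, `expression`, boxplot-ready).
#' @export
compare_groups <- function(records,
                           groups = c("nonbound", "dual", "A_only"),
                           cfg = pipeline_config()) {
  if (!all(c("fpkm_mean", "group") %in% names(records))) {
    abort("`records` needs fpkm_mean and group columns")
  }
  if (length(groups) < 2) abort("need at least two groups to compare")
  transform <- if (cfg$log_fpkm) function(x) log2(x + 1) else identity
  values <- records[records$group %in% groups,
                    c("gene_id", "group", "fpkm_mean")]
  values$expression <- transform(values$fpkm_mean)
  values$fpkm_mean <- NULL
  sizes <- table(factor(values$group, levels = groups))
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    abort(sprintf("group(s) with fewer than 3 genes: %s",
                  paste(small, collapse = ", ")))
  }
  pairs <- utils::combn(groups, 2)
  comparisons <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    xa <- values$expression[values$group == ga]
    xb <- values$expression[values$group == gb]
    tt <- stats::t.test(xa, xb, var.equal = cfg$pooled_variance)
    tibble(group_a = ga, group_b = gb, n_a = length(xa), n_b = length(xb),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
  }))
  list(comparisons = comparisons, values = values)
}

#' Promoter-binding expression analysis, end to end
#'
#' Filters the gene universe, quantifies FPKM from the count table,
#' derives the promoter-bound gene sets of both factors, labels every
#' filtered gene `nonbound` / `dual` / `<A>_only` / `<B>_only` (genes
#' removed by the filter are labeled `excluded`), and runs the group
#' comparisons.
#'
#' @param counts Count tibble (`gene_id` + replicate columns); genes
#'   removed by the filter are dropped from the table before FPKM.
#' @param genes Gene-model tibble (the full universe).
#' @param peaks_a,peaks_b Final peak tibbles of the two factors.
#' @param cfg A [pipeline_config()].
#' @param labels Length-2 factor names (e.g. `c("PHF20", "PHF20L1")`).
#' @param compare Group labels to test; defaults to nonbound, dual and
#'   `<A>_only` (the `<B>_only` group is labeled but not tested).
#' @return A list: `records` (per-gene FPKM + group), `comparisons`,
#'   `values` (long format), `bound` (list of bound id vectors),
#'   `filter_removed` (named counts), `library_sizes`.
#' @export
expression_pipeline <- function(counts, genes, peaks_a, peaks_b,
                                cfg = pipeline_config(),
                                labels = c("A", "B"),
                                compare = NULL) {
  kept <- filter_genes(genes, cfg)
  removed <- attr(kept, "removed")
  rep_cols <- setdiff(names(counts), "gene_id")
  pre_totals <- vapply(rep_cols, function(cn) sum(counts[[cn]]), numeric(1))
  unknown <- setdiff(counts$gene_id, genes$gene_id)
  if (length(unknown)) {
    abort(sprintf("gene(s) in the count table absent from the gene models: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  counts_kept <- counts[counts$gene_id %in% kept$gene_id, , drop = FALSE]
  expr <- fpkm(
    counts_kept, kept, cfg,
    library_sizes = if (cfg$prefilter_library_size) pre_totals else NULL
  )
  bound_a <- bound_genes(peaks_a, kept, cfg)
  bound_b <- bound_genes(peaks_b, kept, cfg)
  groups <- shared_and_exclusive_genes(kept$gene_id, bound_a, bound_b,
                                       labels)
  groups$group[groups$group == "none"] <- "nonbound"
  records <- dplyr::left_join(expr, groups, by = "gene_id")
  excluded <- genes$gene_id[!genes$gene_id %in% kept$gene_id]
  if (length(excluded)) {
    records <- dplyr::bind_rows(
      records, tibble(gene_id = excluded, group = "excluded")
    )
  }
  if (is.null(compare)) {
    compare <- c("nonbound", "dual", paste0(labels[1], "_only"))
  }
  cmp <- compare_groups(records[records$group != "excluded", ],
                        groups = compare, cfg = cfg)
  list(
    records = records,
    comparisons = cmp$comparisons,
    values = cmp$values,
    bound = stats::setNames(list(bound_a, bound_b), labels),
    filter_removed = removed,
    library_sizes = if (cfg$prefilter_library_size) pre_totals
                    else vapply(rep_cols, function(cn) sum(counts_kept[[cn]]),
                                numeric(1))
  )
}
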