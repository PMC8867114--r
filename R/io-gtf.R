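#' Gene models from GTF
#'
#' Genes are collapsed to a single gene-level model: the TSS is the 5'-most
#' transcribed base over all transcripts, the TES the 3'-most, and the
#' union-exon length is the number of bases covered by the union of all
#' exons of the gene. GTF's 1-based inclusive coordinates are converted to
#' the package's 0-based half-open convention at the boundary, so for a
#' plus-strand gene `tss == start` and `tes == end - 1`, and mirrored on
#' the minus strand.
#'
#' @name gtf_io
NULL

#' Read gene models from a GENCODE-style GTF
#'
#' Parsing is delegated to `rtracklayer::import()`; `gene` and `exon`
#' features are used, with the biotype taken from `gene_type` (GENCODE) or
#' `gene_biotype` (Ensembl). A gene feature without exon features is an
#' error, as is a gene without a definite strand.
#'
#' @param path Path to a GTF file.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open genomic span), `tss`, `tes`
#'   (0-based positions of the 5'-most / 3'-most transcribed base),
#'   `biotype`, `union_exon_length`, and `exons` (list column of sorted
#'   exon tibbles in 0-based half-open coordinates).
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) abort(sprintf("file does not exist: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  if (!nrow(meta)) return(empty_genes())
  if (!"gene_id" %in% names(meta)) {
    abort(sprintf("%s: GTF records carry no gene_id attribute", path))
  }
  biotype_col <- intersect(c("gene_type", "gene_biotype"), names(meta))[1]
  feat <- tibble(
    type = as.character(meta$type),
    gene_id = as.character(meta$gene_id),
    chrom = as.character(meta$seqnames),
    start = meta$start - 1,  # -> 0-based half-open
    end = as.numeric(meta$end),
    strand = as.character(meta$strand),
    biotype = if (!is.na(biotype_col)) as.character(meta[[biotype_col]])
              else NA_character_
  )
  gene_rows <- feat[feat$type == "gene", , drop = FALSE]
  exon_rows <- feat[feat$type == "exon", , drop = FALSE]
  ids <- unique(c(gene_rows$gene_id, exon_rows$gene_id))
  no_exons <- setdiff(gene_rows$gene_id, exon_rows$gene_id)
  if (length(no_exons)) {
    abort(sprintf("%s: gene(s) without exon features: %s", path,
                  paste(sort(no_exons), collapse = ", ")))
  }
  exon_split <- split(exon_rows[c("chrom", "start", "end", "strand")],
                      exon_rows$gene_id)
  gene_attr <- as.data.frame(gene_rows[!duplicated(gene_rows$gene_id), ,
                                       drop = FALSE])
  rownames(gene_attr) <- gene_attr$gene_id

  build_one <- function(gid) {
    ex <- exon_split[[gid]]
    ex <- ex[order(ex$start, ex$end), , drop = FALSE]
    if (length(unique(ex$chrom)) > 1) {
      abort(sprintf("%s: gene %s has exons on multiple chromosomes",
                    path, gid))
    }
    ga <- if (gid %in% rownames(gene_attr)) gene_attr[gid, ] else NULL
    strand <- if (!is.null(ga)) ga$strand else unique(ex$strand)[1]
    if (!strand %in% c("+", "-")) {
      abort(sprintf("%s: gene %s has no definite strand ('%s')",
                    path, gid, strand))
    }
    span_start <- min(ex$start, if (!is.null(ga)) ga$start else Inf)
    span_end <- max(ex$end, if (!is.null(ga)) ga$end else -Inf)
    merged <- merge_intervals(tibble(chrom = ex$chrom, start = ex$start,
                                     end = ex$end))
    biotype <- if (!is.null(ga) && !is.na(ga$biotype)) ga$biotype
               else if (!all(is.na(ex_bio <- exon_rows$biotype[
                 exon_rows$gene_id == gid]))) ex_bio[!is.na(ex_bio)][1]
               else "unknown"
    tibble(
      gene_id = gid,
      chrom = ex$chrom[1],
      strand = strand,
      start = span_start,
      end = span_end,
      tss = if (strand == "+") span_start else span_end - 1,
      tes = if (strand == "+") span_end - 1 else span_start,
      biotype = biotype,
      union_exon_length = sum(merged$end - merged$start),
      exons = list(tibble(start = merged$start, end = merged$end))
    )
  }
  genes <- dplyr::bind_rows(lapply(sort(ids), build_one))
  genes[order(genes$chrom, genes$start, genes$gene_id), ]
}

# Internal: empty gene-model tibble.
empty_genes <- function() {
  tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = numeric(), end = numeric(), tss = numeric(), tes = numeric(),
    biotype = character(), union_exon_length = numeric(), exons = list()
  )
}

# Internal: validate a gene-model tibble.
check_genes <- function(genes, arg = "genes") {
  need <- c("gene_id", "chrom", "strand", "start", "end", "tss", "tes",
            "biotype", "union_exon_length")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols)) {
    abort(sprintf("`%s` lacks gene-model column(s): %s", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genes) && !all(genes$strand %in% c("+", "-"))) {
    abort(sprintf("`%s`: gene strand must be '+' or '-'", arg))
  }
  invisible(genes)
}

#' Write gene models as GTF
#'
#' Emits `gene` and `exon` features with `gene_id`, `transcript_id` and
#' `gene_type` attributes (one synthetic transcript per gene), converting
#' back to GTF's 1-based inclusive coordinates.
#'
#' @param genes Gene-model tibble (see [read_gtf_genes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  check_genes(genes)
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attr_gene <- sprintf('gene_id "%s"; gene_type "%s"; gene_name "%s";',
                         g$gene_id, g$biotype, g$gene_id)
    lines <- c(lines, paste(
      g$chrom, "peakscape", "gene", fmt_num(g$start + 1), fmt_num(g$end),
      ".", g$strand, ".", attr_gene, sep = "\t"
    ))
    ex <- g$exons[[1]]
    attr_exon <- sprintf(
      'gene_id "%s"; transcript_id "%s.t1"; gene_type "%s"; gene_name "%s";',
      g$gene_id, g$gene_id, g$biotype, g$gene_id
    )
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        g$chrom, "peakscape", "exon", fmt_num(ex$start[j] + 1),
        fmt_num(ex$end[j]), ".", g$strand, ".", attr_exon, sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Internal: accept a DNAStringSet or a FASTA path.
load_genome <- function(genome) {
  if (is.character(genome)) {
    if (!file.exists(genome)) {
      abort(sprintf("file does not exist: %s", genome))
    }
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (!methods::is(genome, "DNAStringSet")) {
    abort("`genome` must be a DNAStringSet or a FASTA path")
  }
  genome
}
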