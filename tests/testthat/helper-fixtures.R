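# Small in-code fixture builders shared across the test files.

iv <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

# single- or multi-exon gene model row; exons default to the full span
gene_row <- function(gene_id, chrom = "chr1", strand = "+",
                     start = 0, end = 1000,
                     exons = NULL, biotype = "protein_coding") {
  if (is.null(exons)) exons <- tibble::tibble(start = start, end = end)
  merged <- peakscape::merge_intervals(
    tibble::tibble(chrom = chrom, start = exons$start, end = exons$end)
  )
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    tss = if (strand == "+") start else end - 1,
    tes = if (strand == "+") end - 1 else start,
    biotype = biotype,
    union_exon_length = sum(merged$end - merged$start),
    exons = list(tibble::tibble(start = merged$start, end = merged$end))
  )
}

tags_tbl <- function(chrom, pos, strand, read_length = 50) {
  tibble::tibble(chrom = chrom, five_prime_pos = pos, strand = strand,
                 read_length = read_length)
}

random_tags <- function(n, chroms = "chr1", max_pos = 5000,
                        read_length = 50) {
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    five_prime_pos = sample(300:(max_pos - 300), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    read_length = read_length
  )
}

# random peak set with p-values and summits
random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                         source_id = "rep") {
  start <- sample(0:(max_pos - 400), n, replace = TRUE)
  width <- sample(100:300, n, replace = TRUE)
  peakscape::peaks_tbl(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width,
    neglog10_p = round(runif(n, 0, 6), 3),
    summit_offset = floor(width / 2),
    source_id = source_id
  )
}

# a tiny deterministic multi-gene annotation for classification tests:
# generous spacing so windows never collide across genes
toy_genes <- function() {
  dplyr::bind_rows(
    gene_row("gA", "chr1", "+", 20000, 24000,
             exons = tibble::tibble(start = c(20000, 22000),
                                    end = c(20500, 24000))),
    gene_row("gB", "chr1", "-", 50000, 56000,
             exons = tibble::tibble(start = c(50000, 54000),
                                    end = c(51000, 56000))),
    gene_row("gC", "chr2", "+", 30000, 30300)  # short single-exon gene
  )
}
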