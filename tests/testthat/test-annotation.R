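test_that("anchor point is the summit when present, else the floored midpoint", {
  # peaks_tbl sorts by (chrom, start, end): rows come back as
  # (end 300, summit 80), (end 300, summit 0), (end 301, no summit)
  pk <- peaks_tbl("chr1", c(100, 100, 100), c(300, 301, 300),
                  summit_offset = c(80, NA, 0))
  expect_equal(anchor_point(pk), c(180, 100, 200))
})

test_that("nearest-TSS assignment signs distances in gene orientation", {
  genes <- dplyr::bind_rows(
    gene_row("g1", "chr1", "+", 1000, 3000),
    gene_row("g2", "chr1", "+", 5000, 8000)
  )
  pk <- peaks_tbl("chr1", 1400, 1601, summit_offset = 100)  # anchor 1500
  res <- nearest_tss_gene(pk, genes)
  expect_equal(res$gene_id, "g1")
  expect_equal(res$signed_distance, 500)

  # minus-strand gene 500 bp right of the anchor: downstream in gene frame
  gneg <- gene_row("gneg", "chr1", "-", 500, 2001)  # tss = 2000
  res <- nearest_tss_gene(pk, gneg)
  expect_equal(res$signed_distance, 500)

  # no gene on the chromosome -> NA assignment, intergenic category
  pk2 <- peaks_tbl("chrM", 100, 200)
  res2 <- nearest_tss_gene(pk2, genes)
  expect_true(is.na(res2$gene_id))
  ann <- suppressWarnings(annotate_peaks(pk2, genes))
  expect_equal(as.character(ann$category), "intergenic")
})

test_that("nearest-TSS matches a linear-scan oracle with deterministic ties", {
  withr::with_seed(707, {
    genes <- dplyr::bind_rows(lapply(1:20, function(i) {
      s <- sample(0:100000, 1)
      gene_row(sprintf("g%02d", i), sample(c("chr1", "chr2"), 1),
               sample(c("+", "-"), 1), s, s + sample(500:3000, 1))
    }))
    pk <- random_peaks(100, max_pos = 100000)
    res <- nearest_tss_gene(pk, genes)
    anchors <- anchor_point(pk)
    for (i in seq_len(nrow(pk))) {
      want <- oracle_nearest(anchors[i], pk$chrom[i], genes)
      expect_equal(res$gene_id[i], want$gene_id)
      expect_equal(res$signed_distance[i], want$dist)
    }
  })
  # exact tie: both TSSs 100 bp away -> lexicographically smaller gene id
  tie <- dplyr::bind_rows(gene_row("gb", "chr1", "+", 1000, 2000),
                          gene_row("ga", "chr1", "+", 1200, 2200))
  pk <- peaks_tbl("chr1", 1050, 1151, summit_offset = 50)  # anchor 1100
  expect_equal(nearest_tss_gene(pk, tie)$gene_id, "ga")
})

test_that("the seven categories follow the stated windows and precedence", {
  cfg <- pipeline_config()
  genes <- toy_genes()
  # gA: + strand, tss 20000, tes 23999, exons [20000,20500) [22000,24000)
  cases <- list(
    list(anchor = 20000, want = "promoter"),   # exactly at the TSS
    list(anchor = 17000, want = "upstream"),   # 3 kb 5' of the TSS
    list(anchor = 19000, want = "promoter"),   # -1000 boundary inclusive
    list(anchor = 18999, want = "upstream"),   # just past it
    list(anchor = 20499, want = "promoter"),   # +499 inside
    list(anchor = 20500, want = "intron"),     # +500 excluded from promoter,
                                               # and past exon 1's half-open end
    list(anchor = 22500, want = "exon"),       # inside exon 2, outside windows
    list(anchor = 21000, want = "intron"),
    list(anchor = 23700, want = "TES"),        # within TES -500
    list(anchor = 25500, want = "downstream"), # TES +1501
    list(anchor = 33000, want = "intergenic")  # past downstream window
  )
  for (cs in cases) {
    pk <- peaks_tbl("chr1", cs$anchor - 10, cs$anchor + 10,
                    summit_offset = 10)
    ann <- annotate_peaks(pk, genes, cfg)
    expect_equal(as.character(ann$category), cs$want,
                 label = sprintf("anchor %d", cs$anchor))
  }
  # mirrored on the minus strand: gB tss 55999; anchor 300 bp 3' of TSS
  pk <- peaks_tbl("chr1", 55689, 55710, summit_offset = 10)  # anchor 55699
  ann <- annotate_peaks(pk, genes, cfg)
  expect_equal(as.character(ann$category), "promoter")
  expect_equal(ann$signed_distance, 300)
})

test_that("promoter takes precedence inside short genes", {
  cfg <- pipeline_config()
  genes <- toy_genes()  # gC: 300 bp single-exon + gene at chr2:30000
  pk <- peaks_tbl("chr2", 30090, 30111, summit_offset = 10)  # anchor 30100
  ann <- annotate_peaks(pk, genes, cfg)
  # anchor is simultaneously in promoter, TES window and exon; promoter wins
  expect_equal(as.character(ann$category), "promoter")
  # past the promoter window the TES window wins over exon
  pk2 <- peaks_tbl("chr2", 30690, 30711, summit_offset = 10)  # anchor 30700
  ann2 <- annotate_peaks(pk2, genes, cfg)
  expect_equal(as.character(ann2$category), "TES")
})

test_that("promoter category is equivalent to anchor-in-window", {
  cfg <- pipeline_config()
  withr::with_seed(808, {
    genes <- dplyr::bind_rows(lapply(1:10, function(i) {
      s <- i * 30000
      gene_row(sprintf("g%02d", i), "chr1", sample(c("+", "-"), 1),
               s, s + sample(1000:4000, 1))
    }))
    pk <- random_peaks(200, chroms = "chr1", max_pos = 330000)
    ann <- annotate_peaks(pk, genes, cfg)
    anchors <- anchor_point(pk)
    g <- genes[match(ann$gene_id, genes$gene_id), ]
    d <- ifelse(g$strand == "+", anchors - g$tss, g$tss - anchors)
    in_window <- d >= -1000 & d < 500
    expect_equal(ann$category == "promoter", in_window)
  })
})

test_that("the distribution partitions peaks and is order-invariant", {
  cfg <- pipeline_config()
  genes <- toy_genes()
  withr::with_seed(909, {
    pk <- random_peaks(150, chroms = c("chr1", "chr2"), max_pos = 60000)
    gd <- genomic_distribution(pk, genes, cfg)
    expect_equal(sum(gd$distribution$count), nrow(pk))
    expect_equal(sum(gd$distribution$fraction), 1, tolerance = 1e-12)
    expect_equal(nrow(gd$distribution), 7)
    # shuffling the peaks changes nothing
    shuf <- pk[sample(nrow(pk)), ]
    gd2 <- genomic_distribution(shuf, genes, cfg)
    expect_equal(gd$distribution, gd2$distribution)
  })
  expect_error(genomic_distribution(peaks_tbl(character(), numeric(),
                                              numeric()), genes, cfg),
               "non-empty")
})

test_that("summit windows extract the exact sequence and drop overflow", {
  cfg <- pipeline_config()
  withr::with_seed(111, {
    genome <- Biostrings::DNAStringSet(c(
      chr1 = paste(sample(c("a", "c", "g", "t"), 2000, TRUE), collapse = "")
    ))
  })
  pk <- peaks_tbl("chr1", c(500, 250), c(700, 351),
                  summit_offset = c(100, 50))  # anchors 600, 300
  res <- suppressMessages(extract_summit_windows(pk, genome, cfg))
  # anchor 300 underflows (300 - 500 < 0) and is dropped
  expect_equal(length(res), 1)
  expect_equal(attr(res, "n_dropped"), 1)
  expect_equal(names(res), "chr1:100-1100")
  want <- toupper(substr(as.character(genome[["chr1"]]), 101, 1100))
  expect_equal(as.character(res[[1]]), want)
  expect_equal(Biostrings::width(res), 1000)
  expect_error(extract_summit_windows(peaks_tbl("chrZ", 600, 700), genome,
                                      cfg),
               "absent from FASTA.*chrZ")
})
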