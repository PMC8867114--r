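test_that("gene filtering removes short, rRNA and chrY genes", {
  cfg <- pipeline_config()
  genes <- dplyr::bind_rows(
    gene_row("keep", "chr1", "+", 0, 5000),
    gene_row("short_rrna_y", "chrY", "+", 0, 150, biotype = "rRNA"),
    gene_row("rrna", "chr1", "+", 10000, 12000, biotype = "rRNA"),
    gene_row("rrna_pseudo", "chr1", "+", 20000, 22000,
             biotype = "rRNA_pseudogene"),
    gene_row("ygene", "chrY", "+", 0, 5000),
    gene_row("tiny", "chr2", "+", 0, 199)
  )
  kept <- filter_genes(genes, cfg)
  expect_equal(kept$gene_id, "keep")
  # first matching rule wins: the 150 bp chrY rRNA counts as "short"
  expect_equal(attr(kept, "removed"),
               c(short = 2L, biotype = 2L, chrom = 1L))
  withr::with_seed(616, {
    rg <- dplyr::bind_rows(lapply(1:50, function(i) {
      gene_row(sprintf("g%02d", i),
               sample(c("chr1", "chrY"), 1), "+",
               0, sample(c(100, 150, 300, 5000), 1),
               biotype = sample(c("protein_coding", "rRNA", "lincRNA"), 1))
    }))
    kept <- filter_genes(rg, cfg)
    want <- rg$union_exon_length >= 200 & !grepl("rRNA", rg$biotype) &
      rg$chrom != "chrY"
    expect_equal(kept$gene_id, rg$gene_id[want])
  })
})

test_that("FPKM follows the closed form and its invariances", {
  cfg <- pipeline_config()
  # worked value: count 100, length 1 kb, library 1e6 -> FPKM 100
  genes <- gene_row("g1", "chr1", "+", 0, 1000)
  filler <- gene_row("g0", "chr1", "+", 5000, 6000)
  counts <- tibble::tibble(gene_id = c("g1", "g0"),
                           rep1 = c(100, 1e6 - 100))
  res <- fpkm(counts, dplyr::bind_rows(genes, filler), cfg)
  expect_equal(res$fpkm_rep1[res$gene_id == "g1"], 100)
  expect_equal(res$fpkm_mean[res$gene_id == "g1"], 100)

  # scale invariance: doubling all counts (and so the library) is a no-op
  doubled <- counts; doubled$rep1 <- doubled$rep1 * 2
  res2 <- fpkm(doubled, dplyr::bind_rows(genes, filler), cfg)
  expect_equal(res2$fpkm_rep1, res$fpkm_rep1)

  # doubling a gene's length halves its FPKM
  genes2 <- gene_row("g1", "chr1", "+", 0, 2000)
  res3 <- fpkm(counts, dplyr::bind_rows(genes2, filler), cfg)
  expect_equal(res3$fpkm_rep1[res3$gene_id == "g1"], 50)

  expect_error(fpkm(tibble::tibble(gene_id = "nope", rep1 = 5),
                    genes, cfg), "absent from the gene models.*nope")
  expect_error(fpkm(tibble::tibble(gene_id = "g1", rep1 = 0), genes, cfg),
               "zero total")
})

test_that("FPKM matches an independent two-line oracle on random tables", {
  cfg <- pipeline_config()
  withr::with_seed(626, {
    genes <- dplyr::bind_rows(lapply(1:30, function(i) {
      gene_row(sprintf("g%02d", i), "chr1", "+",
               i * 10000, i * 10000 + sample(300:4000, 1))
    }))
    counts <- tibble::tibble(
      gene_id = genes$gene_id,
      r1 = rpois(30, 500), r2 = rpois(30, 800)
    )
    res <- fpkm(counts, genes, cfg)
    for (r in c("r1", "r2")) {
      want <- counts[[r]] * 1e9 / (genes$union_exon_length * sum(counts[[r]]))
      expect_equal(res[[paste0("fpkm_", r)]], want)
    }
    expect_equal(res$fpkm_mean, (res$fpkm_r1 + res$fpkm_r2) / 2)
  })
})

test_that("promoter binding is >=1 bp overlap with the stranded window", {
  cfg <- pipeline_config()
  gp <- gene_row("gp", "chr1", "+", 10000, 14000)   # promoter [9000,10500)
  gm <- gene_row("gm", "chr1", "-", 30000, 34000)   # tss 33999,
                                                    # promoter [33500,35000)
  genes <- dplyr::bind_rows(gp, gm)
  expect_equal(bound_genes(peaks_tbl("chr1", 9900, 10100), genes, cfg), "gp")
  # wholly 2 kb upstream: not bound
  expect_equal(length(bound_genes(peaks_tbl("chr1", 7500, 8000), genes,
                                  cfg)), 0)
  # minus-strand window boundaries: [tss-499, tss+1001) = [33500+1, 35000)
  expect_equal(bound_genes(peaks_tbl("chr1", 34999, 35100), genes, cfg),
               "gm")
  expect_equal(length(bound_genes(peaks_tbl("chr1", 35000, 35100), genes,
                                  cfg)), 0)
  withr::with_seed(636, {
    genes <- dplyr::bind_rows(lapply(1:12, function(i) {
      gene_row(sprintf("g%02d", i), "chr1", sample(c("+", "-"), 1),
               i * 20000, i * 20000 + 4000)
    }))
    pk <- random_peaks(80, chroms = "chr1", max_pos = 260000)
    got <- bound_genes(pk, genes, cfg)
    win <- peakscape:::promoter_windows(genes, cfg)
    want <- sort(win$gene_id[oracle_overlaps_any(win, pk)])
    expect_equal(got, want)
  })
})

test_that("group comparison runs two-sided t tests on log2 FPKM", {
  cfg <- pipeline_config()
  rec <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:6),
    fpkm_mean = c(1, 2, 3, 1, 2, 3),
    group = rep(c("nonbound", "dual"), each = 3)
  )
  res <- compare_groups(rec, groups = c("nonbound", "dual"), cfg = cfg)
  expect_equal(res$comparisons$statistic, 0)
  expect_equal(res$comparisons$p_value, 1)
  expect_equal(res$comparisons$n_a, 3)
  expect_equal(sort(unique(res$values$group)), c("dual", "nonbound"))
  expect_equal(res$values$expression[1], log2(2))
  expect_error(
    compare_groups(rec[1:4, ], groups = c("nonbound", "dual"), cfg),
    "fewer than 3"
  )
})

test_that("Welch p agrees with a permutation oracle on small groups", {
  cfg <- pipeline_config(log_fpkm = FALSE)
  withr::with_seed(646, {
    x <- c(3.1, 4.5, 2.2, 5.0, 3.3, 4.1, 2.9, 3.8)
    y <- c(5.2, 6.1, 4.9, 5.8, 6.4, 5.5, 5.1, 6.0)
    rec <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:16),
      fpkm_mean = c(x, y),
      group = rep(c("a", "b"), each = 8)
    )
    p_welch <- compare_groups(rec, groups = c("a", "b"),
                              cfg = cfg)$comparisons$p_value
    pooled <- c(x, y)
    obs <- abs(mean(x) - mean(y))
    perm <- replicate(10000, {
      idx <- sample(16, 8)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    })
    p_perm <- mean(perm >= obs - 1e-12)
    expect_lt(abs(p_welch - p_perm), 0.01)
  })
})

test_that("the expression pipeline partitions genes into disjoint groups", {
  cfg <- pipeline_config()
  withr::with_seed(656, {
    genes <- dplyr::bind_rows(lapply(1:40, function(i) {
      gene_row(sprintf("g%02d", i),
               if (i <= 36) "chr1" else "chrY", "+",
               i * 20000, i * 20000 + 3000,
               biotype = if (i %in% 35:36) "rRNA" else "protein_coding")
    }))
    # factor A binds genes 1..10, factor B genes 6..15
    mk_peaks <- function(idx) {
      tss <- genes$tss[idx]
      peaks_tbl("chr1", tss - 50, tss + 50, source_id = "final")
    }
    counts <- tibble::tibble(gene_id = genes$gene_id,
                             rep1 = rpois(40, 500), rep2 = rpois(40, 500))
    res <- expression_pipeline(counts, genes, mk_peaks(1:10), mk_peaks(6:15),
                               cfg, labels = c("A", "B"))
    grp <- res$records$group
    expect_equal(sum(grp == "dual"), 5)
    expect_equal(sum(grp == "A_only"), 5)
    expect_equal(sum(grp == "B_only"), 5)
    expect_equal(sum(grp == "excluded"), 6)  # 2 rRNA + 4 chrY
    expect_equal(sum(grp == "nonbound"), 19)
    # every gene appears exactly once across the five labels
    expect_equal(nrow(res$records), 40)
    expect_equal(res$comparisons$group_a,
                 c("nonbound", "nonbound", "dual"))
    expect_true(all(res$comparisons$p_value >= 0 &
                      res$comparisons$p_value <= 1))
  })
})
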