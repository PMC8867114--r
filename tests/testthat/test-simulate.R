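# a small, fast configuration shared by the simulator tests
small_cfg <- function(...) {
  args <- list(n_genes = 40L, n_genes_chry = 2L, n_rrna = 2L, n_short = 2L,
               background_per_kb = 5, tags_per_site = 30L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("the generated annotation is deterministic and self-consistent", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, seed = 7, dir = d1)
  simulate_dataset(cfg, seed = 7, dir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  simulate_dataset(cfg, seed = 8, dir = d3)
  expect_false(identical(readLines(file.path(d1, "genes.gtf")),
                         readLines(file.path(d3, "genes.gtf"))))

  # GTF round trip reproduces the in-memory gene models
  ann <- simulate_annotation(cfg, seed = 7 + 11)
  back <- read_gtf_genes(file.path(d1, "genes.gtf"))
  expect_equal(back$gene_id, ann$genes$gene_id)
  expect_equal(back$tss, ann$genes$tss)
  expect_equal(back$tes, ann$genes$tes)
  expect_equal(back$union_exon_length, ann$genes$union_exon_length)
  expect_equal(back$biotype, ann$genes$biotype)
  expect_true(all(back$end - back$start >= back$union_exon_length))
  # genome matches the declared chromosome lengths
  fa <- Biostrings::readDNAStringSet(file.path(d1, "genome.fa"))
  expect_equal(unname(Biostrings::width(fa)), unname(ann$chrom_lengths))
})

test_that("gene placement honors spacing, filters fodder, and density errors", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg, seed = 3)
  g <- ann$genes
  expect_equal(nrow(g), 40)
  expect_equal(sum(g$chrom == "chrY"), 2)
  expect_equal(sum(g$biotype == "rRNA"), 2)
  expect_equal(sum(g$union_exon_length < 200), 2)
  # >= 5.5 kb clearance between consecutive genes on a chromosome
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    if (nrow(gc) > 1) {
      expect_true(all(gc$start[-1] - gc$end[-nrow(gc)] >= 5500))
    }
  }
  # empty annotation is valid
  ann0 <- simulate_annotation(sim_config(n_genes = 0, n_genes_chry = 0,
                                         n_rrna = 0, n_short = 0), seed = 1)
  expect_equal(nrow(ann0$genes), 0)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann0$genes, path)
  expect_equal(length(readLines(path)), 0)
  # requesting an impossible density errors
  expect_error(
    simulate_annotation(sim_config(n_genes = 100, chrom_length = 50000),
                        seed = 1),
    "density"
  )
})

test_that("planted truth uses largest-remainder group sizes and promoter summits", {
  # 200 eligible genes at the default fractions -> exactly 60/30/4
  cfg <- sim_config(n_genes = 200, n_genes_chry = 0, n_rrna = 0, n_short = 0)
  ann <- simulate_annotation(cfg, seed = 5)
  truth <- simulate_truth(ann$genes, cfg, seed = 5)
  sizes <- table(truth$membership)
  expect_equal(unname(sizes[c("dual", "A_only", "B_only")]),
               as.table(c(60L, 30L, 4L)), ignore_attr = TRUE)
  # all summits inside the stranded promoter window of their gene
  bound <- truth[!is.na(truth$summit_pos), ]
  g <- ann$genes[match(bound$gene_id, ann$genes$gene_id), ]
  d <- ifelse(g$strand == "+", bound$summit_pos - g$tss,
              g$tss - bound$summit_pos)
  expect_true(all(d >= -1000 & d < 500))
  # f_dual = 1 marks every eligible gene dual
  all_dual <- simulate_truth(ann$genes,
                             sim_config(f_dual = 1, f_a_only = 0,
                                        f_b_only = 0), seed = 5)
  expect_true(all(all_dual$membership == "dual"))
  expect_error(sim_config(f_dual = 0.8, f_a_only = 0.3), "sum to <= 1")
  # ineligible genes are never bound
  cfg2 <- small_cfg()
  ann2 <- simulate_annotation(cfg2, seed = 5)
  truth2 <- simulate_truth(ann2$genes, cfg2, seed = 5)
  inel <- ann2$genes$union_exon_length < 200 |
    ann2$genes$biotype == "rRNA" | ann2$genes$chrom == "chrY"
  expect_true(all(truth2$membership[inel] == "none"))
})

test_that("perfect sensitivity and no false peaks reproduce the truth exactly", {
  cfg <- small_cfg(sensitivity_a = c(1, 1), false_peak_rate_per_mb = 0)
  ann <- simulate_annotation(cfg, seed = 9)
  truth <- simulate_truth(ann$genes, cfg, seed = 9)
  pks <- simulate_replicate_peaks(truth, ann$genes, ann$chrom_lengths, cfg,
                                  seed = 9, "A")
  sites <- truth[truth$membership %in% c("A_only", "dual"), ]
  for (r in pks) {
    expect_equal(nrow(r), nrow(sites))
    expect_equal(sort(r$start), sort(sites$summit_pos - 150))
    expect_equal(unique(r$summit_offset), 150)
    expect_true(all(r$neglog10_p >= 2))
  }
})

test_that("false peaks are intergenic; capped p-values fail the strict cut", {
  cfg <- small_cfg(false_peak_rate_per_mb = 50,
                   false_p_range = c(1, 1.9))
  ann <- simulate_annotation(cfg, seed = 13)
  truth <- simulate_truth(ann$genes, cfg, seed = 13)
  pks <- simulate_replicate_peaks(truth, ann$genes, ann$chrom_lengths, cfg,
                                  seed = 13, "A")
  false_pk <- pks$rep1[grepl("false", pks$rep1$name), ]
  expect_gt(nrow(false_pk), 0)
  gene_spans <- ann$genes[c("chrom", "start", "end")]
  expect_false(any(peakscape:::overlaps_any(false_pk, gene_spans)))
  # a Uniform cap below 2 means every false peak fails p <= 0.01
  expect_equal(nrow(threshold_peaks(false_pk, 0.01)), 0)
})

test_that("duplicate injection is recovered by dedup at the configured rate", {
  cfg <- small_cfg(duplicate_rate = 0.5, background_per_kb = 20)
  ann <- simulate_annotation(cfg, seed = 17)
  truth <- simulate_truth(ann$genes, cfg, seed = 17)
  tags <- simulate_tags(truth, ann$genes, ann$chrom_lengths, cfg,
                        seed = 17, "A")
  n <- nrow(tags$input)
  dd <- dedup_tags(tags$input)
  removed_frac <- attr(dd, "n_removed") / n
  # 1/3 of tags are injected copies; collisions can only push this higher,
  # and position collisions among background tags are rare at this density
  expect_gt(removed_frac, 0.28)
  expect_lt(removed_frac, 0.40)
})

test_that("with no enrichment the ChIP tags are indistinguishable from input", {
  cfg <- small_cfg(tags_per_site = 0L, background_per_kb = 15)
  ann <- simulate_annotation(cfg, seed = 7)
  truth <- simulate_truth(ann$genes, cfg, seed = 7)
  tags <- simulate_tags(truth, ann$genes, ann$chrom_lengths, cfg,
                        seed = 7, "A")
  chip <- tags$chip[[1]]; input <- tags$input
  ks <- suppressWarnings(stats::ks.test(
    chip$five_prime_pos[chip$chrom == "chr1"],
    input$five_prime_pos[input$chrom == "chr1"]
  ))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero dispersion gives Poisson counts; defaults plant a 4x shift", {
  cfg <- small_cfg(dispersion = 0)
  ann <- simulate_annotation(cfg, seed = 19)
  truth <- simulate_truth(ann$genes, cfg, seed = 19)
  cnt <- simulate_counts(truth, ann$genes, cfg, seed = 19)
  mu <- ifelse(truth$membership[match(ann$genes$gene_id,
                                      truth$gene_id)] != "none",
               400, 100) * ann$genes$union_exon_length / 1000
  z <- (cnt$rep1 - mu) / sqrt(mu)  # Poisson: variance == mean
  expect_lt(abs(mean(z)), 0.5)
  expect_lt(abs(stats::var(z) - 1), 0.6)
  # bound genes get ~4x the unbound per-kb rate
  bound <- truth$membership != "none"
  rate <- cnt$rep1 / (ann$genes$union_exon_length / 1000)
  expect_gt(mean(rate[bound]) / mean(rate[!bound]), 3)
})

test_that("under the null the group-comparison p-values are uniform", {
  cfg <- sim_config(n_genes = 60, n_genes_chry = 0, n_rrna = 0, n_short = 0,
                    f_dual = 0.5, f_a_only = 0, f_b_only = 0,
                    mu_bound = 100, mu_unbound = 100)
  pcfg <- pipeline_config()
  ann <- simulate_annotation(cfg, seed = 23)
  truth <- simulate_truth(ann$genes, cfg, seed = 23)
  grp <- ifelse(truth$membership == "dual", "dual", "nonbound")
  pvals <- vapply(1:300, function(i) {
    cnt <- simulate_counts(truth, ann$genes, cfg, seed = 10000 + i)
    rec <- fpkm(cnt, ann$genes, pcfg)
    rec$group <- grp
    compare_groups(rec, groups = c("nonbound", "dual"),
                   cfg = pcfg)$comparisons$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
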