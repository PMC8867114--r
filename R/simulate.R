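#' Seeded synthetic ChIP-seq / RNA-seq study generator
#'
#' Generates, deterministically from a seed, a complete toy study with the
#' statistical structure the analysis assumes: a random-base genome with
#' non-overlapping stranded multi-exon genes (including rRNA, sub-200 bp
#' and chrY genes to exercise the filters), planted promoter binding
#' shared or exclusive between two factors, per-replicate tag alignments
#' with background noise and PCR duplicates, per-replicate peak calls of
#' unequal quality with intergenic false peaks, and a negative-binomial
#' count table in which promoter-bound genes are systematically more
#' highly expressed.
#'
#' @name synthetic_data
NULL

#' Simulator configuration
#'
#' Defaults encode the study conditions the pipeline is designed for: 200
#' genes on three chromosomes (including chrY), dominant shared binding
#' between the two factors (30% dual, 15% A-exclusive, 2% B-exclusive of
#' eligible genes), summits centered on the TSS with 50 bp jitter, two
#' A-factor replicates of sensitivity 1.0 / 0.9 (three for B), 5 false
#' peaks per Mb of intergenic space, 50 bp reads with a 10% duplicate
#' rate, about 20 background tags per kb, 100 enrichment tags per bound
#' site, and counts with unbound mean 100 / bound mean 400 per kb of exon
#' model (planted log2 fold change of 2) at NB dispersion 0.3.
#'
#' @param n_genes Total genes, including chrY/rRNA/short genes.
#' @param n_genes_chry Genes placed on chrY.
#' @param n_rrna,n_short Autosomal genes given an rRNA biotype / a
#'   sub-200 bp length, to exercise the expression filters.
#' @param gene_length_range,short_gene_length_range Genomic gene-length
#'   ranges (bp).
#' @param max_exons Maximum exons per gene.
#' @param min_feature_width Minimum exon/intron width (bp).
#' @param intergenic_gap_range Range of gaps between consecutive genes
#'   (bp); the lower bound keeps annotation windows of neighboring genes
#'   from colliding.
#' @param chrom_margin Gene-free margin at each chromosome end (bp).
#' @param chrom_names Chromosome names; `"chrY"` is recognized by the
#'   expression filter defaults.
#' @param chrom_length Optional fixed chromosome length; genes that do not
#'   fit raise an error. `NULL` sizes each chromosome to its genes.
#' @param f_dual,f_a_only,f_b_only Fractions of eligible genes planted as
#'   dual / A-exclusive / B-exclusive targets (largest-remainder rounding).
#' @param summit_sd SD (bp) of the planted summit offset from the TSS;
#'   summits are clipped into the promoter window.
#' @param promoter_window Stranded promoter window used for clipping.
#' @param background_per_kb Background tags per kb of chromosome (both
#'   strands pooled) per sample.
#' @param tags_per_site Enrichment tags per bound site in a
#'   sensitivity-1.0 replicate.
#' @param fragment_span Span (bp) within which enrichment tag 5' ends are
#'   placed so extended fragments cover the summit; matches the pipeline
#'   extension size.
#' @param read_length Read length (bp).
#' @param duplicate_rate Fraction of extra duplicate tags injected.
#' @param sensitivity_a,sensitivity_b Per-replicate detection
#'   sensitivities (first entry = best replicate); also scale enrichment
#'   tag counts.
#' @param false_peak_rate_per_mb Poisson rate of false peaks per Mb of
#'   intergenic space, per replicate.
#' @param peak_halfwidth Half-width of simulated peaks (bp).
#' @param true_p_offset,true_p_mean True-peak `-log10 p = offset +
#'   Exponential(mean)`.
#' @param false_p_range False-peak `-log10 p ~ Uniform(range)`.
#' @param mu_unbound,mu_bound NB count means per kb of exon model.
#' @param dispersion NB dispersion (0 gives Poisson draws).
#' @param n_count_replicates RNA-seq replicates.
#' @param n_blacklist,blacklist_width Number and width of random
#'   intergenic blacklist regions.
#' @return A list with class `"peakscape_sim_config"`.
#' @export
sim_config <- function(n_genes = 200L, n_genes_chry = 8L,
                       n_rrna = 5L, n_short = 5L,
                       gene_length_range = c(1000L, 4000L),
                       short_gene_length_range = c(80L, 180L),
                       max_exons = 4L, min_feature_width = 100L,
                       intergenic_gap_range = c(6000L, 9000L),
                       chrom_margin = 6000L,
                       chrom_names = c("chr1", "chr2", "chrY"),
                       chrom_length = NULL,
                       f_dual = 0.30, f_a_only = 0.15, f_b_only = 0.02,
                       summit_sd = 50,
                       promoter_window = c(-1000L, 500L),
                       background_per_kb = 20,
                       tags_per_site = 100L,
                       fragment_span = 200L,
                       read_length = 50L,
                       duplicate_rate = 0.1,
                       sensitivity_a = c(1, 0.9),
                       sensitivity_b = c(1, 0.9, 0.8),
                       false_peak_rate_per_mb = 5,
                       peak_halfwidth = 150L,
                       true_p_offset = 2, true_p_mean = 3,
                       false_p_range = c(1, 2.5),
                       mu_unbound = 100, mu_bound = 400,
                       dispersion = 0.3,
                       n_count_replicates = 2L,
                       n_blacklist = 3L, blacklist_width = 1000L) {
  if (f_dual + f_a_only + f_b_only > 1 + 1e-12) {
    abort("binding fractions must sum to <= 1")
  }
  stopifnot(
    n_genes >= 0, n_genes_chry >= 0, n_genes_chry <= n_genes,
    all(sensitivity_a > 0), all(sensitivity_a <= 1),
    all(sensitivity_b > 0), all(sensitivity_b <= 1),
    duplicate_rate >= 0, dispersion >= 0, read_length > 0
  )
  structure(as.list(environment()), class = "peakscape_sim_config")
}

# Internal: largest-remainder apportionment of n items over fractions.
largest_remainder <- function(fractions, n) {
  exact <- fractions * n
  base <- floor(exact)
  left <- round(n - sum(base))
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a genome and gene annotation
#'
#' Places non-overlapping stranded multi-exon genes along each chromosome
#' with intergenic gaps large enough that the annotation windows of
#' neighboring genes cannot collide, flags the configured numbers of rRNA
#' and sub-200 bp genes, and generates a uniform-random ACGT genome.
#' Byte-identical per (config, seed).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list: `genome` (`DNAStringSet`), `genes` (gene-model tibble
#'   as from [read_gtf_genes()]), `chrom_lengths` (named vector).
#' @export
simulate_annotation <- function(cfg = sim_config(), seed = 7) {
  withr::with_seed(seed, {
    autosomes <- setdiff(cfg$chrom_names, "chrY")
    has_chry <- "chrY" %in% cfg$chrom_names
    n_auto <- cfg$n_genes - if (has_chry) cfg$n_genes_chry else 0L
    per_chrom <- if (length(autosomes)) {
      largest_remainder(rep(1 / length(autosomes), length(autosomes)),
                        n_auto)
    } else {
      integer(0)
    }
    alloc <- stats::setNames(as.list(per_chrom), autosomes)
    if (has_chry) alloc$chrY <- cfg$n_genes_chry
    # flag rRNA / short genes among autosomal gene slots
    n_auto_total <- sum(unlist(alloc[autosomes]))
    if (cfg$n_rrna + cfg$n_short > n_auto_total) {
      abort("n_rrna + n_short exceeds the number of autosomal genes")
    }
    special <- sample(seq_len(max(n_auto_total, 1)),
                      min(cfg$n_rrna + cfg$n_short, n_auto_total))
    rrna_slots <- special[seq_len(cfg$n_rrna)]
    short_slots <- setdiff(special, rrna_slots)

    genes <- list()
    chrom_lengths <- numeric(0)
    auto_slot <- 0L
    for (ch in cfg$chrom_names) {
      n_here <- alloc[[ch]] %||% 0L
      pos <- cfg$chrom_margin
      for (i in seq_len(n_here)) {
        is_auto <- ch %in% autosomes
        if (is_auto) auto_slot <- auto_slot + 1L
        short <- is_auto && auto_slot %in% short_slots
        rrna <- is_auto && auto_slot %in% rrna_slots
        len_range <- if (short) cfg$short_gene_length_range
                     else cfg$gene_length_range
        L <- sample(len_range[1]:len_range[2], 1)
        strand <- sample(c("+", "-"), 1)
        k <- if (short) 1L else sample(seq_len(cfg$max_exons), 1)
        exons <- make_exon_structure(pos, L, k, cfg$min_feature_width)
        genes[[length(genes) + 1]] <- tibble(
          chrom = ch, strand = strand, start = pos, end = pos + L,
          biotype = if (rrna) "rRNA" else "protein_coding",
          exons = list(exons)
        )
        pos <- pos + L +
          sample(cfg$intergenic_gap_range[1]:cfg$intergenic_gap_range[2], 1)
      }
      len <- if (is.null(cfg$chrom_length)) {
        # pos already includes one trailing gap for chroms with genes
        if (n_here) pos + cfg$chrom_margin else 2 * cfg$chrom_margin
      } else {
        if (pos + cfg$chrom_margin > cfg$chrom_length + 1e-9 && n_here) {
          abort(sprintf(
            "genes do not fit on %s at the requested density; increase chrom_length beyond %d",
            ch, as.integer(pos + cfg$chrom_margin)
          ))
        }
        cfg$chrom_length
      }
      chrom_lengths[ch] <- len
    }
    genes <- if (length(genes)) dplyr::bind_rows(genes) else NULL
    if (is.null(genes)) {
      genes <- empty_genes()
    } else {
      genes <- genes[order(genes$chrom, genes$start), ]
      genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
      genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
      genes$tes <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
      genes$union_exon_length <- map_dbl(genes$exons,
                                         ~ sum(.x$end - .x$start))
      genes <- genes[c("gene_id", "chrom", "strand", "start", "end",
                       "tss", "tes", "biotype", "union_exon_length",
                       "exons")]
    }
    genome <- Biostrings::DNAStringSet(vapply(
      chrom_lengths,
      function(len) paste(sample(c("A", "C", "G", "T"), len,
                                 replace = TRUE), collapse = ""),
      character(1)
    ))
    names(genome) <- names(chrom_lengths)
    list(genome = genome, genes = genes, chrom_lengths = chrom_lengths)
  })
}

# Internal: k disjoint exons covering the first and last base of the gene
# span [pos, pos + L); exon/intron widths >= min_width (single exon when
# the span is too small to honor that).
make_exon_structure <- function(pos, L, k, min_width) {
  if (k > 1 && L < (2 * k - 1) * min_width) k <- 1L
  if (k == 1) return(tibble(start = pos, end = pos + L))
  n_seg <- 2L * k - 1L
  slack <- L - n_seg * min_width
  w <- runif(n_seg)
  extra <- floor(w / sum(w) * slack)
  extra[n_seg] <- extra[n_seg] + (slack - sum(extra))
  widths <- min_width + extra
  bounds <- pos + c(0, cumsum(widths))
  idx <- seq(1, n_seg, by = 2)
  tibble(start = bounds[idx], end = bounds[idx + 1])
}

#' Plant binding truth over the eligible genes
#'
#' Eligible genes (union-exon length >= 200 bp, non-rRNA, not on chrY)
#' are assigned memberships `dual` / `A_only` / `B_only` / `none` by
#' seeded sampling without replacement, with group sizes fixed by
#' largest-remainder rounding of the configured fractions. Each bound
#' gene receives one summit at `TSS + round(Normal(0, summit_sd))` in
#' stranded orientation, clipped into the promoter window.
#'
#' @param genes Gene-model tibble.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble: `gene_id`, `membership`, `summit_chrom`,
#'   `summit_pos` (`NA` for unbound genes), `regime` (`high`/`baseline`).
#' @export
simulate_truth <- function(genes, cfg = sim_config(), seed = 7) {
  check_genes(genes)
  if (cfg$f_dual + cfg$f_a_only + cfg$f_b_only > 1 + 1e-12) {
    abort("binding fractions must sum to <= 1")
  }
  withr::with_seed(seed, {
    eligible <- genes$union_exon_length >= 200 &
      !grepl("rRNA", genes$biotype, fixed = TRUE) &
      genes$chrom != "chrY"
    ids <- genes$gene_id[eligible]
    n <- length(ids)
    sizes <- largest_remainder(
      c(cfg$f_dual, cfg$f_a_only, cfg$f_b_only,
        1 - cfg$f_dual - cfg$f_a_only - cfg$f_b_only), n
    )
    perm <- sample(ids)
    membership <- rep("none", nrow(genes))
    names(membership) <- genes$gene_id
    assign_grp <- rep(c("dual", "A_only", "B_only", "none"), sizes)
    membership[perm] <- assign_grp
    bound <- unname(membership[genes$gene_id] != "none") & eligible
    off <- round(rnorm(nrow(genes), 0, cfg$summit_sd))
    sgn <- ifelse(genes$strand == "+", 1, -1)
    w <- cfg$promoter_window
    # stranded offset clipped into [w1, w2 - 1], then mapped to genome
    off <- pmin(pmax(off, w[1]), w[2] - 1)
    summit <- genes$tss + sgn * off
    tibble(
      gene_id = genes$gene_id,
      membership = unname(membership[genes$gene_id]),
      summit_chrom = ifelse(bound, genes$chrom, NA_character_),
      summit_pos = ifelse(bound, summit, NA_real_),
      regime = ifelse(bound, "high", "baseline")
    )
  })
}

# Internal: uniform background tags over one chromosome, both strands,
# fully inside [0, len).
background_tags <- function(chrom, len, rate_per_kb, read_length) {
  n <- round(len / 1000 * rate_per_kb)
  if (n == 0) {
    return(tibble(chrom = character(), five_prime_pos = numeric(),
                  strand = character(), read_length = numeric()))
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  u <- floor(runif(n) * (len - read_length + 1))
  tibble(
    chrom = chrom,
    five_prime_pos = ifelse(strand == "+", u, u + read_length - 1),
    strand = strand,
    read_length = read_length
  )
}

# Internal: inject PCR duplicates by appending copies of sampled tags.
inject_duplicates <- function(tags, rate) {
  n_dup <- round(rate * nrow(tags))
  if (n_dup == 0) return(tags)
  dplyr::bind_rows(tags, tags[sample(nrow(tags), n_dup, replace = TRUE), ])
}

#' Simulate ChIP and input tag alignments
#'
#' Background tag 5' positions are uniform on each chromosome on both
#' strands; enrichment tags at each of the factor's planted sites are
#' positioned so that `fragment_span`-extended fragments cover the
#' summit (plus-strand 5' = summit - Uniform(0, span - 1), minus strand
#' mirrored). Enrichment depth scales with each replicate's sensitivity;
#' duplicates are injected at the configured rate. The input sample is
#' background only.
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param genes Gene-model tibble.
#' @param chrom_lengths Named chromosome lengths.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param factor_label `"A"` or `"B"`: which factor's sites are enriched.
#' @return A list: `chip` (list of tag tibbles, one per replicate) and
#'   `input` (tag tibble).
#' @export
simulate_tags <- function(truth, genes, chrom_lengths,
                          cfg = sim_config(), seed = 7,
                          factor_label = "A") {
  withr::with_seed(seed, {
    members <- if (factor_label == "A") c("A_only", "dual")
               else c("B_only", "dual")
    sites <- truth[truth$membership %in% members & !is.na(truth$summit_pos), ]
    sens <- if (factor_label == "A") cfg$sensitivity_a else cfg$sensitivity_b
    span <- cfg$fragment_span
    one_background <- function() {
      dplyr::bind_rows(lapply(names(chrom_lengths), function(ch) {
        background_tags(ch, chrom_lengths[[ch]], cfg$background_per_kb,
                        cfg$read_length)
      }))
    }
    chip <- lapply(seq_along(sens), function(r) {
      n_per_site <- round(cfg$tags_per_site * sens[r])
      enrich <- if (nrow(sites) && n_per_site > 0) {
        total <- nrow(sites) * n_per_site
        summit <- rep(sites$summit_pos, each = n_per_site)
        chrom <- rep(sites$summit_chrom, each = n_per_site)
        strand <- sample(c("+", "-"), total, replace = TRUE)
        offset <- sample(0:(span - 1), total, replace = TRUE)
        tibble(
          chrom = chrom,
          five_prime_pos = ifelse(strand == "+", summit - offset,
                                  summit + offset),
          strand = strand,
          read_length = cfg$read_length
        )
      } else {
        tibble(chrom = character(), five_prime_pos = numeric(),
               strand = character(), read_length = numeric())
      }
      inject_duplicates(dplyr::bind_rows(one_background(), enrich),
                        cfg$duplicate_rate)
    })
    names(chip) <- sprintf("rep%d", seq_along(chip))
    input <- inject_duplicates(one_background(), cfg$duplicate_rate)
    list(chip = chip, input = input)
  })
}

# Internal: intergenic blocks (gene spans padded by `pad`, complemented
# within each chromosome).
intergenic_blocks <- function(genes, chrom_lengths, pad = 2000) {
  blocks <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) return(tibble(chrom = ch, start = 0, end = len))
    occ <- merge_intervals(tibble(
      chrom = ch, start = pmax(0, g$start - pad), end = pmin(len, g$end + pad)
    ))
    starts <- c(0, occ$end)
    ends <- c(occ$start, len)
    keep <- starts < ends
    tibble(chrom = ch, start = starts[keep], end = ends[keep])
  })
  dplyr::bind_rows(blocks)
}

# Internal: sample n intervals of width w uniformly inside blocks.
sample_in_blocks <- function(blocks, n, w) {
  fit <- blocks[blocks$end - blocks$start >= w, , drop = FALSE]
  if (!nrow(fit) || n == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  room <- fit$end - fit$start - w + 1
  pick <- sample(nrow(fit), n, replace = TRUE, prob = room)
  start <- fit$start[pick] + floor(runif(n) * room[pick])
  tibble(chrom = fit$chrom[pick], start = start, end = start + w)
}

#' Simulate per-replicate peak calls
#'
#' Each planted site of the factor appears in replicate r with probability
#' equal to that replicate's sensitivity, as a peak
#' `[summit - halfwidth, summit + halfwidth)` with the summit offset at
#' `halfwidth` and `-log10 p = true_p_offset + Exponential(true_p_mean)`.
#' False peaks are placed uniformly in intergenic space (>= 2 kb from any
#' gene) at the configured Poisson rate per Mb with
#' `-log10 p ~ Uniform(false_p_range)`.
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param genes Gene-model tibble.
#' @param chrom_lengths Named chromosome lengths.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param factor_label `"A"` or `"B"`.
#' @return A named list of peak tibbles, one per replicate.
#' @export
simulate_replicate_peaks <- function(truth, genes, chrom_lengths,
                                     cfg = sim_config(), seed = 7,
                                     factor_label = "A") {
  withr::with_seed(seed, {
    members <- if (factor_label == "A") c("A_only", "dual")
               else c("B_only", "dual")
    sites <- truth[truth$membership %in% members & !is.na(truth$summit_pos), ]
    sens <- if (factor_label == "A") cfg$sensitivity_a else cfg$sensitivity_b
    blocks <- intergenic_blocks(genes, chrom_lengths)
    total_mb <- sum(blocks$end - blocks$start) / 1e6
    hw <- cfg$peak_halfwidth
    out <- lapply(seq_along(sens), function(r) {
      detected <- if (nrow(sites)) runif(nrow(sites)) <= sens[r]
                  else logical(0)
      det <- sites[detected, , drop = FALSE]
      true_peaks <- if (nrow(det)) {
        peaks_tbl(
          chrom = det$summit_chrom,
          start = pmax(0, det$summit_pos - hw),
          end = det$summit_pos + hw,
          name = sprintf("%s_rep%d_site_%s", factor_label, r, det$gene_id),
          neglog10_p = cfg$true_p_offset + rexp(nrow(det),
                                                1 / cfg$true_p_mean),
          summit_offset = det$summit_pos - pmax(0, det$summit_pos - hw),
          source_id = sprintf("%s_rep%d", factor_label, r)
        )
      } else {
        empty_peaks()
      }
      n_false <- rpois(1, cfg$false_peak_rate_per_mb * total_mb)
      false_peaks <- if (n_false > 0) {
        fp <- sample_in_blocks(blocks, n_false, 2 * hw)
        peaks_tbl(
          chrom = fp$chrom, start = fp$start, end = fp$end,
          name = sprintf("%s_rep%d_false%d", factor_label, r,
                         seq_len(nrow(fp))),
          neglog10_p = runif(nrow(fp), cfg$false_p_range[1],
                             cfg$false_p_range[2]),
          summit_offset = hw,
          source_id = sprintf("%s_rep%d", factor_label, r)
        )
      } else {
        empty_peaks()
      }
      sort_intervals(dplyr::bind_rows(true_peaks, false_peaks))
    })
    names(out) <- sprintf("rep%d", seq_along(out))
    out
  })
}

#' Simulate an RNA-seq count table
#'
#' Negative-binomial fragment counts for every gene (bound genes at
#' `mu_bound`, all others at `mu_unbound`, scaled by union-exon length in
#' kb), for `n_count_replicates` replicates. Dispersion 0 gives Poisson
#' draws.
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param genes Gene-model tibble.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble: `gene_id` plus `rep1`, `rep2`, ... count columns.
#' @export
simulate_counts <- function(truth, genes, cfg = sim_config(), seed = 7) {
  withr::with_seed(seed, {
    bound <- truth$membership[match(genes$gene_id, truth$gene_id)] != "none"
    bound[is.na(bound)] <- FALSE
    mu <- ifelse(bound, cfg$mu_bound, cfg$mu_unbound) *
      genes$union_exon_length / 1000
    out <- tibble(gene_id = genes$gene_id)
    for (r in seq_len(cfg$n_count_replicates)) {
      out[[sprintf("rep%d", r)]] <- if (cfg$dispersion > 0) {
        rnbinom(nrow(genes), mu = mu, size = 1 / cfg$dispersion)
      } else {
        rpois(nrow(genes), mu)
      }
    }
    out
  })
}

#' Simulate blacklist regions
#'
#' A few random intergenic regions, written alongside the peak calls to
#' exercise blacklist filtering.
#'
#' @param genes Gene-model tibble.
#' @param chrom_lengths Named chromosome lengths.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return An interval tibble.
#' @export
simulate_blacklist <- function(genes, chrom_lengths, cfg = sim_config(),
                               seed = 7) {
  withr::with_seed(seed, {
    blocks <- intergenic_blocks(genes, chrom_lengths)
    sort_intervals(sample_in_blocks(blocks, cfg$n_blacklist,
                                    cfg$blacklist_width))
  })
}

#' Generate the complete synthetic study
#'
#' Runs every simulator stage with seeds derived deterministically from
#' `seed` and optionally writes the whole dataset as plain-text files:
#' `genome.fa`, `genes.gtf`, `truth.tsv`, `blacklist.bed`,
#' `a_repN.tagAlign.bed` + `input.tagAlign.bed` (factor A tags),
#' `a_repN.narrowPeak` / `b_repN.narrowPeak`, and `counts.tsv`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (keep below ~2e9).
#' @param dir Optional output directory (created if needed).
#' @return Invisibly, a list: `genome`, `genes`, `chrom_lengths`, `truth`,
#'   `tags` (factor A: `chip` list + `input`), `peaks_a`, `peaks_b`,
#'   `counts`, `blacklist`, `seed`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 7, dir = NULL) {
  ann <- simulate_annotation(cfg, seed + 11)
  truth <- simulate_truth(ann$genes, cfg, seed + 23)
  tags <- simulate_tags(truth, ann$genes, ann$chrom_lengths, cfg,
                        seed + 37, "A")
  peaks_a <- simulate_replicate_peaks(truth, ann$genes, ann$chrom_lengths,
                                      cfg, seed + 41, "A")
  peaks_b <- simulate_replicate_peaks(truth, ann$genes, ann$chrom_lengths,
                                      cfg, seed + 43, "B")
  counts <- simulate_counts(truth, ann$genes, cfg, seed + 53)
  blacklist <- simulate_blacklist(ann$genes, ann$chrom_lengths, cfg,
                                  seed + 61)
  out <- list(
    genome = ann$genome, genes = ann$genes,
    chrom_lengths = ann$chrom_lengths,
    truth = truth, tags = tags, peaks_a = peaks_a, peaks_b = peaks_b,
    counts = counts, blacklist = blacklist, seed = seed
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(ann$genome, file.path(dir, "genome.fa"))
    write_gtf(ann$genes, file.path(dir, "genes.gtf"))
    write_truth_tsv(truth, file.path(dir, "truth.tsv"))
    write_bed(blacklist, file.path(dir, "blacklist.bed"))
    for (r in seq_along(tags$chip)) {
      write_tagalign(tags$chip[[r]],
                     file.path(dir, sprintf("a_rep%d.tagAlign.bed", r)))
    }
    write_tagalign(tags$input, file.path(dir, "input.tagAlign.bed"))
    for (r in seq_along(peaks_a)) {
      write_narrowpeak(peaks_a[[r]],
                       file.path(dir, sprintf("a_rep%d.narrowPeak", r)))
    }
    for (r in seq_along(peaks_b)) {
      write_narrowpeak(peaks_b[[r]],
                       file.path(dir, sprintf("b_rep%d.narrowPeak", r)))
    }
    write_counts_table(counts, file.path(dir, "counts.tsv"))
  }
  invisible(out)
}

# Internal: truth table writer (plain TSV).
write_truth_tsv <- function(truth, path) {
  header <- paste(names(truth), collapse = "\t")
  body <- do.call(paste, c(lapply(truth, function(col) {
    if (is.numeric(col)) ifelse(is.na(col), "NA", fmt_num(col))
    else ifelse(is.na(col), "NA", as.character(col))
  }), sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
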