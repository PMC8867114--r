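# Brute-force per-base oracles. Deliberately naive: every one enumerates
# bases or pairs directly and shares no code with the implementation.

oracle_bases <- function(chrom, start, end) {
  if (end <= start) return(character(0))
  paste(chrom, seq(start, end - 1), sep = ":")
}

oracle_overlaps_pair <- function(a, b) {
  length(intersect(oracle_bases(a$chrom, a$start, a$end),
                   oracle_bases(b$chrom, b$start, b$end))) > 0
}

# connected components of the pairwise >=1 bp overlap graph (base painting
# alone would wrongly chain adjacent intervals, which share no base)
oracle_components <- function(xs) {
  n <- nrow(xs)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] && oracle_overlaps_pair(xs[i, ], xs[j, ])) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

oracle_merge <- function(x) {
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    xs <- x[x$chrom == ch, ]
    comp <- oracle_components(xs)
    runs <- lapply(unique(comp), function(cc) {
      tibble::tibble(chrom = ch, start = min(xs$start[comp == cc]),
                     end = max(xs$end[comp == cc]))
    })
    part <- dplyr::bind_rows(runs)
    out[[ch]] <- part[order(part$start), ]
  }
  dplyr::bind_rows(out)
}

oracle_overlaps_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(vapply(seq_len(nrow(subject)), function(j) {
      oracle_overlaps_pair(query[i, ], subject[j, ])
    }, logical(1)))
  }, logical(1))
}

# overlap-chain components of the pooled peaks, labeled with the union of
# contributing sources
oracle_venn <- function(sets) {
  set_names <- names(sets)
  pooled <- dplyr::bind_rows(lapply(set_names, function(nm) {
    tibble::tibble(chrom = sets[[nm]]$chrom, start = sets[[nm]]$start,
                   end = sets[[nm]]$end, source = nm)
  }))
  member <- character(0)
  for (ch in sort(unique(pooled$chrom))) {
    xs <- pooled[pooled$chrom == ch, ]
    comp <- oracle_components(xs)
    member <- c(member, vapply(unique(comp), function(cc) {
      src <- unique(xs$source[comp == cc])
      paste(set_names[set_names %in% src], collapse = "&")
    }, character(1)))
  }
  table(member)
}

# naive per-base depth loop, normalized and binned
oracle_pileup <- function(fragments, chrom_lengths, cfg, n_tags) {
  scale <- cfg$norm_target_reads / n_tags
  bins <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    depth <- numeric(len)
    fr <- fragments[fragments$chrom == ch, ]
    for (i in seq_len(nrow(fr))) {
      for (p in seq(fr$start[i], fr$end[i] - 1)) {
        depth[p + 1] <- depth[p + 1] + 1
      }
    }
    depth <- depth * scale
    nb <- ceiling(len / cfg$track_bin)
    v <- numeric(nb)
    for (b in seq_len(nb)) {
      lo <- (b - 1) * cfg$track_bin + 1
      hi <- min(b * cfg$track_bin, len)
      v[b] <- sum(depth[lo:hi]) / cfg$track_bin
    }
    bins[[ch]] <- v
  }
  bins
}

# linear scan over all same-chromosome genes; ties -> smaller gene_id
oracle_nearest <- function(anchor, chrom, genes) {
  g <- genes[genes$chrom == chrom, ]
  if (!nrow(g)) return(list(gene_id = NA_character_, dist = NA_real_))
  d <- abs(anchor - g$tss)
  best <- which(d == min(d))
  best <- best[order(g$gene_id[best])][1]
  sgn <- if (g$strand[best] == "+") 1 else -1
  list(gene_id = g$gene_id[best], dist = sgn * (anchor - g$tss[best]))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 1000, max_width = 120) {
  start <- sample(0:(max_pos - 2), n, replace = TRUE)
  width <- sample(seq_len(max_width), n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = pmin(start + width, max_pos)
  )
}
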