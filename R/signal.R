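#' Normalized signal tracks and TSS metaprofiles
#'
#' Tags (5'-anchored single-end reads) are deduplicated, replaced by
#' fixed-length fragments extended toward their 3' end, piled up at base
#' resolution, scaled so the library totals `norm_target_reads` (default
#' 10 M) tags, and averaged in `track_bin` (default 10 bp) windows.
#' Metaprofiles average the same normalized per-base coverage over
#' +/- `metaprofile_flank` windows around every usable TSS.
#'
#' @name signal
NULL

# Internal: validate a tag tibble.
check_tags <- function(tags, arg = "tags") {
  need <- c("chrom", "five_prime_pos", "strand", "read_length")
  missing_cols <- setdiff(need, names(tags))
  if (length(missing_cols)) {
    abort(sprintf("`%s` lacks tag column(s): %s", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tags)) {
    if (!all(tags$strand %in% c("+", "-"))) {
      abort(sprintf("`%s`: tag strand must be '+' or '-'", arg))
    }
    if (any(tags$read_length <= 0)) {
      abort(sprintf("`%s`: read_length must be > 0", arg))
    }
  }
  invisible(tags)
}

#' Remove duplicate tags
#'
#' Keeps the first occurrence of each (chrom, 5' position, strand) key;
#' tags at the same position on opposite strands are distinct. The count
#' of removed duplicates is attached as attribute `n_removed`.
#'
#' @param tags Tag tibble.
#' @return The deduplicated tags.
#' @export
dedup_tags <- function(tags) {
  check_tags(tags)
  out <- tags[!duplicated(tags[c("chrom", "five_prime_pos", "strand")]), ,
              drop = FALSE]
  attr(out, "n_removed") <- nrow(tags) - nrow(out)
  out
}

#' Extend tags 3'-ward into fragments
#'
#' In the default `"extsize"` mode each tag becomes an `extsize` bp
#' fragment anchored at its 5' position `p`: `[p, p + extsize)` on the
#' plus strand and `[p - extsize + 1, p + 1)` on the minus strand. The
#' `"append"` mode instead keeps the read and appends `extsize` bp past
#' its 3' terminus. Fragments are clipped to `[0, chrom_length)`; a tag on
#' a chromosome with unknown length is an error.
#'
#' @param tags Tag tibble (deduplicate first).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param cfg A [pipeline_config()] (`extsize`, `extension_mode`).
#' @return An interval tibble of fragments, one per tag.
#' @export
extend_tags <- function(tags, chrom_lengths, cfg = pipeline_config()) {
  check_tags(tags)
  if (is.null(names(chrom_lengths))) {
    abort("`chrom_lengths` must be a named vector")
  }
  unknown <- setdiff(unique(tags$chrom), names(chrom_lengths))
  if (length(unknown)) {
    abort(sprintf("cannot clip fragments: unknown chromosome length for %s",
                  paste(unknown, collapse = ", ")))
  }
  p <- tags$five_prime_pos
  ext <- cfg$extsize
  if (cfg$extension_mode == "extsize") {
    start <- ifelse(tags$strand == "+", p, p - ext + 1)
    end <- ifelse(tags$strand == "+", p + ext, p + 1)
  } else {
    len <- tags$read_length
    start <- ifelse(tags$strand == "+", p, p - len + 1 - ext)
    end <- ifelse(tags$strand == "+", p + len + ext, p + 1)
  }
  lens <- unname(chrom_lengths[tags$chrom])
  tibble(
    chrom = tags$chrom,
    start = unname(pmax(0, start)),
    end = unname(pmin(lens, end))
  )
}

# Internal: per-base fragment depth on one chromosome via a difference
# array; fragments must lie within [0, len).
coverage_vector <- function(starts, ends, len) {
  if (!length(starts)) return(numeric(len))
  delta <- tabulate(starts + 1, nbins = len + 1) -
    tabulate(ends + 1, nbins = len + 1)
  cumsum(delta)[seq_len(len)]
}

#' Depth-normalized binned pileup
#'
#' Per-base fragment depth is multiplied by
#' `scale_factor = norm_target_reads / n_tags` and summarised in
#' consecutive `track_bin` bp bins as the mean per-base value (positions
#' past the chromosome end count as zero depth in a truncated final bin,
#' so total mass `sum(value) * bin_size` is conserved exactly).
#'
#' @param fragments Interval tibble of extended fragments, all within
#'   `[0, chrom_length)`.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param cfg A [pipeline_config()].
#' @param n_tags Library size used for normalization; defaults to the
#'   number of fragments (one fragment per deduplicated tag).
#' @return A `signal_track`: list with `bin_size`, `n_tags_used`,
#'   `scale_factor` and `bins` (tibble `chrom`, `start`, `end`, `value`,
#'   dense including zero bins).
#' @export
pileup <- function(fragments, chrom_lengths, cfg = pipeline_config(),
                   n_tags = nrow(fragments)) {
  check_intervals(fragments, "fragments")
  if (is.null(names(chrom_lengths))) {
    abort("`chrom_lengths` must be a named vector")
  }
  if (n_tags == 0) abort("n_tags is 0: cannot normalize an empty library")
  unknown <- setdiff(unique(fragments$chrom), names(chrom_lengths))
  if (length(unknown)) {
    abort(sprintf("unknown chromosome length for %s",
                  paste(unknown, collapse = ", ")))
  }
  oob <- fragments$end > chrom_lengths[fragments$chrom]
  if (any(oob)) {
    abort(sprintf("%d fragment(s) extend past their chromosome end; clip with extend_tags()",
                  sum(oob)))
  }
  scale_factor <- cfg$norm_target_reads / n_tags
  bin <- cfg$track_bin
  per_chrom <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    sel <- fragments$chrom == ch
    cov <- coverage_vector(fragments$start[sel], fragments$end[sel], len) *
      scale_factor
    nb <- ceiling(len / bin)
    padded <- c(cov, numeric(nb * bin - len))
    value <- colSums(matrix(padded, nrow = bin)) / bin
    starts <- (seq_len(nb) - 1) * bin
    tibble(chrom = ch, start = starts, end = pmin(starts + bin, len),
           value = value)
  })
  structure(
    list(
      bin_size = bin,
      n_tags_used = n_tags,
      scale_factor = scale_factor,
      bins = dplyr::bind_rows(per_chrom)
    ),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf(
    "<signal_track> %d bins of %d bp over %d chromosome(s); %s tags, scale %.4g\n",
    nrow(x$bins), x$bin_size, length(unique(x$bins$chrom)),
    format(x$n_tags_used, big.mark = ","), x$scale_factor
  ))
  invisible(x)
}

#' Write a signal track as bedGraph
#'
#' Zero-valued bins are omitted unless `dense = TRUE`.
#'
#' @param track A `signal_track` from [pileup()].
#' @param path Output path.
#' @param dense Also write zero bins.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, dense = FALSE) {
  bins <- track$bins
  if (!dense) bins <- bins[bins$value != 0, , drop = FALSE]
  writeLines(
    paste(bins$chrom, fmt_num(bins$start), fmt_num(bins$end),
          fmt_num(bins$value), sep = "\t"),
    path
  )
  invisible(path)
}

#' Aggregate TSS metaprofile
#'
#' Tags are deduplicated, extended ([extend_tags()]) and piled up at base
#' resolution, normalized to `norm_target_reads`, then averaged over the
#' `[TSS - flank, TSS + flank)` window of every gene whose window lies
#' fully inside its chromosome (genes with truncated windows are dropped
#' and counted). With `orient_metaprofile_by_strand` (default) the window
#' of a minus-strand gene is mirrored so increasing bin index always runs
#' downstream of the TSS; otherwise all windows are taken in genomic
#' orientation.
#'
#' @param tags Tag tibble.
#' @param genes Gene-model tibble.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per bin: `bin`, `offset_start`,
#'   `offset_mid` (bp relative to the TSS) and `value` (mean normalized
#'   depth). Attributes: `n_tss`, `n_dropped_tss`, `n_tags_used`.
#' @export
tss_metaprofile <- function(tags, genes, chrom_lengths,
                            cfg = pipeline_config()) {
  check_genes(genes)
  tags <- dedup_tags(tags)
  n_used <- nrow(tags)
  if (n_used == 0) abort("no tags supplied")
  frags <- extend_tags(tags, chrom_lengths, cfg)
  flank <- cfg$metaprofile_flank
  bin <- cfg$track_bin
  nbins <- as.integer(2 * flank / bin)
  orient <- cfg$orient_metaprofile_by_strand
  acc <- numeric(nbins * bin)
  n_tss <- 0L
  n_dropped <- 0L
  for (ch in intersect(unique(genes$chrom), names(chrom_lengths))) {
    g <- genes[genes$chrom == ch, ]
    len <- chrom_lengths[[ch]]
    sel <- frags$chrom == ch
    cov <- coverage_vector(frags$start[sel], frags$end[sel], len)
    for (i in seq_len(nrow(g))) {
      minus <- g$strand[i] == "-"
      if (orient && minus) {
        # stranded offsets d = tss - x in [-flank, flank) => x in
        # [tss - flank + 1, tss + flank + 1)
        lo <- g$tss[i] - flank + 1
      } else {
        lo <- g$tss[i] - flank
      }
      hi <- lo + 2 * flank
      if (lo < 0 || hi > len) {
        n_dropped <- n_dropped + 1L
        next
      }
      w <- cov[(lo + 1):hi]
      if (orient && minus) w <- rev(w)
      acc <- acc + w
      n_tss <- n_tss + 1L
    }
  }
  n_dropped <- n_dropped + sum(!genes$chrom %in% names(chrom_lengths))
  if (n_tss == 0) {
    abort("no gene has a full TSS window inside its chromosome")
  }
  per_base <- acc * (cfg$norm_target_reads / n_used) / n_tss
  value <- colSums(matrix(per_base, nrow = bin)) / bin
  offset_start <- -flank + (seq_len(nbins) - 1) * bin
  offset_mid <- offset_start + bin / 2
  out <- tibble(
    bin = seq_len(nbins),
    offset_start = offset_start,
    offset_mid = offset_mid,
    value = value
  )
  attr(out, "n_tss") <- n_tss
  attr(out, "n_dropped_tss") <- n_dropped
  attr(out, "n_tags_used") <- n_used
  out
}

#' Side-by-side ChIP and input TSS metaprofiles
#'
#' Convenience wrapper computing [tss_metaprofile()] for a ChIP and an
#' input tag set over the same genes, ready for plotting.
#'
#' @param chip_tags,input_tags Tag tibbles.
#' @param genes Gene-model tibble.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param cfg A [pipeline_config()].
#' @return A tibble with `bin`, `offset_mid`, `chip_mean`, `input_mean`.
#' @export
tss_metaprofile_pair <- function(chip_tags, input_tags, genes,
                                 chrom_lengths, cfg = pipeline_config()) {
  chip <- tss_metaprofile(chip_tags, genes, chrom_lengths, cfg)
  input <- tss_metaprofile(input_tags, genes, chrom_lengths, cfg)
  tibble(bin = chip$bin, offset_mid = chip$offset_mid,
         chip_mean = chip$value, input_mean = input$value)
}
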