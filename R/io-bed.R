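#' Readers and writers for BED-family formats
#'
#' BED, tagAlign and ENCODE narrowPeak files are tab-separated text with
#' 0-based half-open coordinates, which is also the package's internal
#' convention, so fields map through unchanged. `browser`, `track` and `#`
#' header lines are tolerated on input; malformed records raise errors that
#' name the offending line.
#'
#' @name bed_io
NULL

# Internal: read non-header lines of a BED-family file, keeping original
# line numbers for error messages.
read_bed_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file does not exist: %s", path))
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^(browser|track|#)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = lineno[keep])
}

bed_field_error <- function(path, lineno, msg) {
  abort(sprintf("%s: line %d: %s", path, lineno, msg))
}

parse_bed_coords <- function(fields, path, lineno) {
  start <- suppressWarnings(as.numeric(fields[, 2]))
  end <- suppressWarnings(as.numeric(fields[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    bed_field_error(path, lineno[bad[1]], "start/end are not numeric")
  }
  bad <- which(start < 0)
  if (length(bad)) {
    bed_field_error(path, lineno[bad[1]], "negative start coordinate")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    bed_field_error(
      path, lineno[bad[1]],
      sprintf("start (%s) must be < end (%s)",
              format(start[bad[1]], scientific = FALSE),
              format(end[bad[1]], scientific = FALSE))
    )
  }
  list(start = start, end = end)
}

#' Read a BED file as intervals or 5'-anchored tags
#'
#' Three-to-five column records are returned as plain intervals. Six-column
#' records carrying a valid strand (tagAlign and BED6 alignment dumps) are
#' returned as tags: each record is reduced to the 0-based position of its
#' 5' base (`start` on the plus strand, `end - 1` on the minus strand,
#' since a minus-strand read runs rightward-to-leftward) plus
#' `read_length = end - start`. Use `as` to force either reading, e.g. for
#' a BED6 blacklist that must stay intervals.
#'
#' @param path Path to a BED/tagAlign file.
#' @param as `"auto"` (tags when 6+ columns with a `+`/`-` strand),
#'   `"intervals"` or `"tags"`.
#' @return A sorted tibble: intervals (`chrom`, `start`, `end`, and `name`,
#'   `score`, `strand` when present) or tags (`chrom`, `five_prime_pos`,
#'   `strand`, `read_length`).
#' @export
read_bed <- function(path, as = c("auto", "intervals", "tags")) {
  as <- match.arg(as)
  raw <- read_bed_lines(path)
  if (!length(raw$lines)) {
    if (as == "tags") {
      return(tibble(chrom = character(), five_prime_pos = numeric(),
                    strand = character(), read_length = numeric()))
    }
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields_list <- strsplit(raw$lines, "\t", fixed = TRUE)
  nf <- lengths(fields_list)
  if (any(nf < 3)) {
    bed_field_error(path, raw$lineno[which(nf < 3)[1]],
                    "fewer than 3 tab-separated columns")
  }
  ncol_use <- min(nf)
  fields <- t(vapply(fields_list, function(f) f[seq_len(ncol_use)],
                     character(ncol_use)))
  if (ncol_use == 1) fields <- matrix(fields, ncol = 1)
  coords <- parse_bed_coords(fields, path, raw$lineno)

  has_strand <- ncol_use >= 6 && all(fields[, 6] %in% c("+", "-", "."))
  want_tags <- switch(as,
    auto = ncol_use >= 6 && all(fields[, 6] %in% c("+", "-")),
    tags = TRUE,
    intervals = FALSE
  )
  if (want_tags) {
    if (ncol_use < 6) {
      bed_field_error(path, raw$lineno[1],
                      "tag records need 6 columns including strand")
    }
    bad <- which(!fields[, 6] %in% c("+", "-"))
    if (length(bad)) {
      bed_field_error(path, raw$lineno[bad[1]],
                      sprintf("invalid tag strand '%s'", fields[bad[1], 6]))
    }
    strand <- fields[, 6]
    out <- tibble(
      chrom = fields[, 1],
      five_prime_pos = ifelse(strand == "+", coords$start, coords$end - 1),
      strand = strand,
      read_length = coords$end - coords$start
    )
    return(out[order(out$chrom, out$five_prime_pos, out$strand), ])
  }
  out <- tibble(chrom = fields[, 1], start = coords$start, end = coords$end)
  if (ncol_use >= 4) out$name <- fields[, 4]
  if (ncol_use >= 5) out$score <- suppressWarnings(as.numeric(fields[, 5]))
  if (has_strand) out$strand <- fields[, 6]
  sort_intervals(out)
}

#' Read MACS2 narrowPeak calls
#'
#' Expects the 10-column ENCODE narrowPeak layout: BED6 plus signalValue,
#' -log10 pValue, -log10 qValue and the summit offset from `start` (`-1`
#' meaning no summit, stored as `NA`).
#'
#' @param path Path to a narrowPeak file.
#' @param source_id Label recorded on every peak (typically the replicate
#'   name); defaults to the file name.
#' @return A peak tibble sorted by (chrom, start): `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`, `signal`, `neglog10_p`, `neglog10_q`,
#'   `summit_offset`, `source_id`.
#' @export
read_narrowpeak <- function(path, source_id = basename(path)) {
  raw <- read_bed_lines(path)
  if (!length(raw$lines)) return(empty_peaks(source_id))
  fields_list <- strsplit(raw$lines, "\t", fixed = TRUE)
  nf <- lengths(fields_list)
  if (any(nf < 10)) {
    bed_field_error(path, raw$lineno[which(nf < 10)[1]],
                    "narrowPeak requires 10 tab-separated columns")
  }
  fields <- t(vapply(fields_list, function(f) f[1:10], character(10)))
  coords <- parse_bed_coords(fields, path, raw$lineno)
  neglog10_p <- suppressWarnings(as.numeric(fields[, 8]))
  bad <- which(is.na(neglog10_p) | neglog10_p < 0)
  if (length(bad)) {
    bed_field_error(path, raw$lineno[bad[1]],
                    "column 8 (-log10 pValue) must be a non-negative number")
  }
  summit <- suppressWarnings(as.numeric(fields[, 10]))
  bad <- which(is.na(summit))
  if (length(bad)) {
    bed_field_error(path, raw$lineno[bad[1]],
                    "column 10 (summit offset) must be numeric")
  }
  summit[summit < 0] <- NA_real_
  width <- coords$end - coords$start
  bad <- which(!is.na(summit) & summit >= width)
  if (length(bad)) {
    bed_field_error(path, raw$lineno[bad[1]],
                    "summit offset lies outside the peak interval")
  }
  out <- tibble(
    chrom = fields[, 1],
    start = coords$start,
    end = coords$end,
    name = fields[, 4],
    score = suppressWarnings(as.numeric(fields[, 5])),
    strand = fields[, 6],
    signal = suppressWarnings(as.numeric(fields[, 7])),
    neglog10_p = neglog10_p,
    neglog10_q = suppressWarnings(as.numeric(fields[, 9])),
    summit_offset = summit,
    source_id = source_id
  )
  sort_intervals(out)
}

# Internal: empty peak tibble with the full column set.
empty_peaks <- function(source_id = character(0)) {
  tibble(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), score = numeric(), strand = character(),
    signal = numeric(), neglog10_p = numeric(), neglog10_q = numeric(),
    summit_offset = numeric(),
    source_id = if (length(source_id)) character() else character()
  )
}

#' Construct a peak tibble in code
#'
#' Convenience constructor filling narrowPeak-style defaults; used by the
#' simulator and handy in tests.
#'
#' @param chrom,start,end Coordinates (0-based half-open).
#' @param name Peak names (default `peak_1`, ...).
#' @param neglog10_p -log10 peak p-values (>= 0).
#' @param summit_offset Summit offsets from `start`, `NA` when absent.
#' @param source_id Replicate/sample label.
#' @param score,strand,signal,neglog10_q Remaining narrowPeak columns.
#' @return A sorted peak tibble.
#' @export
peaks_tbl <- function(chrom, start, end, name = NULL, neglog10_p = 0,
                      summit_offset = NA_real_, source_id = "peaks",
                      score = 0, strand = ".", signal = 0, neglog10_q = -1) {
  n <- length(start)
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  out <- tibble(
    chrom = rep_len(chrom, n), start = as.numeric(start),
    end = as.numeric(end), name = name,
    score = rep_len(as.numeric(score), n),
    strand = rep_len(strand, n),
    signal = rep_len(as.numeric(signal), n),
    neglog10_p = rep_len(as.numeric(neglog10_p), n),
    neglog10_q = rep_len(as.numeric(neglog10_q), n),
    summit_offset = rep_len(as.numeric(summit_offset), n),
    source_id = rep_len(source_id, n)
  )
  check_intervals(out, "peaks")
  if (any(out$neglog10_p < 0)) abort("neglog10_p must be >= 0")
  bad <- !is.na(out$summit_offset) &
    (out$summit_offset < 0 | out$summit_offset >= out$end - out$start)
  if (any(bad)) abort("summit_offset must lie inside the peak interval")
  sort_intervals(out)
}

# Internal: fixed-precision numeric formatting for text tracks (never
# scientific, locale-independent).
fmt_num <- function(x, digits = 5) {
  ifelse(x == round(x) & abs(x) < 1e15,
         format(x, scientific = FALSE, trim = TRUE),
         formatC(x, format = "f", digits = digits))
}

#' Write intervals as BED
#'
#' Emits 3 columns, or 6 when `name`/`score`/`strand` are present.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x, "x")
  cols <- list(x$chrom, fmt_num(x$start), fmt_num(x$end))
  if (any(c("name", "score", "strand") %in% names(x))) {
    cols <- c(cols, list(
      if ("name" %in% names(x)) x$name else rep(".", nrow(x)),
      if ("score" %in% names(x)) fmt_num(x$score) else rep("0", nrow(x)),
      if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
    ))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Write tags as tagAlign (BED6)
#'
#' Reconstructs the aligned span from the 5' position, strand and read
#' length; the sequence column is written as `N`.
#'
#' @param tags Tag tibble (`chrom`, `five_prime_pos`, `strand`,
#'   `read_length`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tagalign <- function(tags, path) {
  start <- ifelse(tags$strand == "+", tags$five_prime_pos,
                  tags$five_prime_pos - tags$read_length + 1)
  end <- start + tags$read_length
  writeLines(
    paste(tags$chrom, fmt_num(start), fmt_num(end), "N", "1000", tags$strand,
          sep = "\t"),
    path
  )
  invisible(path)
}

#' Write peaks as ENCODE narrowPeak
#'
#' @param peaks Peak tibble (see [read_narrowpeak()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  check_intervals(peaks, "peaks")
  summit <- ifelse(is.na(peaks$summit_offset), -1, peaks$summit_offset)
  writeLines(
    paste(peaks$chrom, fmt_num(peaks$start), fmt_num(peaks$end), peaks$name,
          fmt_num(peaks$score), peaks$strand, fmt_num(peaks$signal),
          fmt_num(peaks$neglog10_p), fmt_num(peaks$neglog10_q),
          fmt_num(summit), sep = "\t"),
    path
  )
  invisible(path)
}

#' Read an htseq-count style count table
#'
#' Accepts a tab-separated table with a gene-id column followed by one
#' integer column per replicate, with or without a header line. Rows whose
#' gene id starts with `__` (htseq-count summary rows such as
#' `__no_feature`) are dropped and reported via a message.
#'
#' @param path Path to the table.
#' @param replicate_names Optional column names for the count columns when
#'   the file has no header.
#' @return A tibble with `gene_id` plus one numeric column per replicate.
#' @export
read_counts_table <- function(path, replicate_names = NULL) {
  if (!file.exists(path)) abort(sprintf("file does not exist: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(sprintf("%s: empty count table", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    abort(sprintf("%s: line %d: count tables need >= 2 columns",
                  path, which(nf < 2)[1]))
  }
  ncols <- nf[1]
  if (any(nf != ncols)) {
    abort(sprintf("%s: line %d: inconsistent column count",
                  path, which(nf != ncols)[1]))
  }
  mat <- t(vapply(fields, identity, character(ncols)))
  first_counts <- suppressWarnings(as.numeric(mat[1, -1]))
  has_header <- any(is.na(first_counts))
  if (has_header) {
    rep_names <- mat[1, -1]
    mat <- mat[-1, , drop = FALSE]
  } else {
    rep_names <- replicate_names %||% sprintf("rep%d", seq_len(ncols - 1))
  }
  summary_rows <- grepl("^__", mat[, 1])
  if (any(summary_rows)) {
    inform(sprintf("dropped %d htseq summary row(s): %s",
                   sum(summary_rows),
                   paste(mat[summary_rows, 1], collapse = ", ")))
    mat <- mat[!summary_rows, , drop = FALSE]
  }
  counts <- apply(mat[, -1, drop = FALSE], 2, function(col) {
    v <- suppressWarnings(as.numeric(col))
    if (any(is.na(v))) abort(sprintf("%s: non-numeric count value", path))
    if (any(v < 0)) abort(sprintf("%s: negative count value", path))
    v
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(mat))
  out <- as_tibble(as.data.frame(counts))
  names(out) <- rep_names
  dplyr::bind_cols(tibble(gene_id = mat[, 1]), out)
}

#' Write a count table with a header line
#'
#' @param counts Tibble with `gene_id` plus count columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  rep_cols <- setdiff(names(counts), "gene_id")
  header <- paste(c("gene_id", rep_cols), collapse = "\t")
  body <- do.call(paste, c(
    list(counts$gene_id),
    lapply(rep_cols, function(cn) fmt_num(counts[[cn]])),
    sep = "\t"
  ))
  writeLines(c(header, body), path)
  invisible(path)
}
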