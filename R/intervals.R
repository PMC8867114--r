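#' Genomic interval primitives
#'
#' All intervals in the package are tibbles with at least `chrom`, `start`
#' and `end` columns in 0-based half-open (BED) coordinates: `start` is the
#' first base covered, `end` is one past the last. An interval therefore
#' covers `end - start` bases and two intervals that merely touch
#' (`a$end == b$start`) share no base.
#'
#' @name intervals
NULL

# Internal: validate an interval tibble (shared by every consumer).
check_intervals <- function(x, arg = "x", require_rows = FALSE) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals", arg))
  }
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols)) {
    abort(sprintf("`%s` lacks column(s): %s", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  if (require_rows && nrow(x) == 0) {
    abort(sprintf("`%s` must contain at least one interval", arg))
  }
  if (nrow(x)) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end))) {
      abort(sprintf("`%s` has non-finite coordinates", arg))
    }
    if (any(x$start < 0)) {
      abort(sprintf("`%s` has negative start coordinates", arg))
    }
    if (any(x$start >= x$end)) {
      bad <- which(x$start >= x$end)[1]
      abort(sprintf(
        "`%s` row %d: start (%s) must be < end (%s) in half-open coordinates",
        arg, bad, format(x$start[bad], scientific = FALSE),
        format(x$end[bad], scientific = FALSE)
      ))
    }
  }
  invisible(x)
}

# Internal: canonical (chrom, start, end) sort.
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Test whether intervals share at least one base
#'
#' Elementwise comparison of two interval tibbles (rows are recycled when
#' one side has a single row). Under half-open arithmetic two intervals
#' overlap iff they are on the same chromosome and
#' `a$start < b$end && b$start < a$end`; adjacency is not overlap. Strand
#' is ignored.
#'
#' @param a,b Interval tibbles with `chrom`, `start`, `end`.
#' @return A logical vector.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
#' b <- tibble::tibble(chrom = "chr1", start = c(5, 10), end = c(15, 20))
#' overlaps(a, b)
overlaps <- function(a, b) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  na <- nrow(a); nb <- nrow(b)
  if (na != nb && na != 1 && nb != 1) {
    abort("`a` and `b` must have equal row counts (or one of them one row)")
  }
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

# Internal: merge plus a map from each input row to its merged region.
merge_with_index <- function(x) {
  check_intervals(x, "x")
  n <- nrow(x)
  if (n == 0) {
    return(list(
      merged = tibble(chrom = character(), start = numeric(), end = numeric()),
      index = integer()
    ))
  }
  ord <- order(x$chrom, x$start, x$end)
  chrom <- x$chrom[ord]; start <- x$start[ord]; end <- x$end[ord]
  new_chrom <- c(TRUE, chrom[-1] != chrom[-n])
  run_max <- stats::ave(end, cumsum(new_chrom), FUN = cummax)
  lag_max <- c(-Inf, run_max[-n])
  # A new merged region starts at a chromosome switch or when the interval
  # begins at/after the furthest end seen so far (adjacency does not chain).
  new_region <- new_chrom | (start >= lag_max)
  grp <- cumsum(new_region)
  starts <- start[new_region]
  ends <- run_max[c(which(new_region)[-1] - 1L, n)]
  index <- integer(n)
  index[ord] <- grp
  list(
    merged = tibble(chrom = chrom[new_region], start = starts, end = ends),
    index = index
  )
}

#' Merge overlapping intervals
#'
#' Collapses every chain of pairwise >= 1 bp overlaps into a single
#' interval. Adjacent-but-not-overlapping intervals (zero shared bases) are
#' kept separate. The result is sorted and pairwise non-overlapping;
#' merging is idempotent.
#'
#' @param x Interval tibble.
#' @return A tibble with `chrom`, `start`, `end`.
#' @export
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(0, 9, 30), end = c(10, 20, 40))
#' merge_intervals(x)
merge_intervals <- function(x) {
  merge_with_index(x)$merged
}

# Internal: for each query interval, does it overlap >= 1 subject interval?
# Sorted-scan with a cumulative-max end; O((n+m) log m) per chromosome.
overlaps_any <- function(query, subject) {
  check_intervals(query, "query")
  check_intervals(subject, "subject")
  hit <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(subject) == 0) return(hit)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sj <- subject$chrom == ch
    if (!any(sj)) next
    s_start <- subject$start[sj]
    s_end <- subject$end[sj]
    o <- order(s_start)
    s_start <- s_start[o]
    run_end <- cummax(s_end[o])
    # candidates: subjects with start < query end
    idx <- findInterval(query$end[qi] - 0.5, s_start)
    ok <- idx > 0
    ok[ok] <- run_end[idx[ok]] > query$start[qi][ok]
    hit[qi] <- ok
  }
  hit
}

#' Warn when two chromosome namespaces do not intersect
#'
#' Silent chromosome-naming mismatches (e.g. `"1"` vs `"chr1"`) are the most
#' common cause of empty annotations; chromosome matching everywhere in the
#' package is exact string equality, so this check is run by the annotation
#' entry points.
#'
#' @param x_chroms,y_chroms Character vectors of chromosome names.
#' @param x_label,y_label Labels used in the warning message.
#' @return `TRUE` (invisibly) when the namespaces share a name.
#' @export
check_chrom_namespaces <- function(x_chroms, y_chroms,
                                   x_label = "first input",
                                   y_label = "second input") {
  shared <- intersect(unique(x_chroms), unique(y_chroms))
  if (length(x_chroms) && length(y_chroms) && !length(shared)) {
    warn(sprintf(
      "chromosome names of %s (%s, ...) and %s (%s, ...) do not intersect; chromosome matching is exact string equality",
      x_label, x_chroms[1], y_label, y_chroms[1]
    ))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
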