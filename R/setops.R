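#' Multi-set peak comparison
#'
#' Peaks from two or three sets are pooled and merged with >= 1 bp overlap
#' chaining; each merged region's membership is the set of input peak sets
#' that contributed at least one peak to it, and regions are counted per
#' membership combination. Counts are therefore of merged regions, not of
#' original peaks, and the per-set totals printed alongside avoid
#' misreading them as input peak counts.
#'
#' @name setops
NULL

#' Merged-region Venn counts for 2-3 peak sets
#'
#' @param sets Named list of 2 or 3 non-empty peak/interval tibbles.
#' @return A `venn_result`: list with `set_names`, `counts` (named integer
#'   vector over all non-empty subsets, e.g. `"A"`, `"A&B"`), `n_merged`
#'   and `n_input` (peak count per input set).
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' venn_counts(list(A = a, B = b))
venn_counts <- function(sets) {
  if (!is.list(sets) || is.data.frame(sets) ||
      length(sets) < 2 || length(sets) > 3) {
    abort("`sets` must be a named list of 2 or 3 peak sets")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be named")
  }
  empty <- vapply(sets, function(s) nrow(s) == 0, logical(1))
  if (any(empty)) {
    abort(sprintf("empty peak set(s): %s",
                  paste(names(sets)[empty], collapse = ", ")))
  }
  set_names <- names(sets)
  pooled <- dplyr::bind_rows(lapply(set_names, function(nm) {
    tibble(chrom = sets[[nm]]$chrom, start = sets[[nm]]$start,
           end = sets[[nm]]$end, source = nm)
  }))
  mi <- merge_with_index(pooled[c("chrom", "start", "end")])
  # membership of each merged region = distinct sources of its peaks
  member <- vapply(
    split(pooled$source, mi$index),
    function(src) paste(set_names[set_names %in% src], collapse = "&"),
    character(1)
  )
  subset_keys <- unlist(lapply(seq_along(set_names), function(k) {
    apply(utils::combn(set_names, k), 2, paste, collapse = "&")
  }))
  counts <- table(factor(member, levels = subset_keys))
  structure(
    list(
      set_names = set_names,
      counts = stats::setNames(as.integer(counts), subset_keys),
      n_merged = nrow(mi$merged),
      n_input = vapply(sets, nrow, integer(1)),
      merged = mi$merged,
      membership = unname(member)
    ),
    class = "venn_result"
  )
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("<venn_result> %d merged regions from %d sets\n",
              x$n_merged, length(x$set_names)))
  cat("input peaks: ",
      paste(sprintf("%s=%d", names(x$n_input), x$n_input), collapse = ", "),
      "\n", sep = "")
  for (k in names(x$counts)) {
    cat(sprintf("  %-12s %d\n", k, x$counts[[k]]))
  }
  invisible(x)
}

#' Label genes by promoter binding in two factors
#'
#' Given the promoter-bound gene sets of two factors (see
#' [bound_genes()]) over a common gene universe, assigns each gene exactly
#' one of `dual`, `A_only`, `B_only`, `none` (labels follow `labels`).
#'
#' @param universe Character vector of gene ids (the filtered gene set).
#' @param bound_a,bound_b Character vectors of promoter-bound gene ids;
#'   must be subsets of `universe`.
#' @param labels Length-2 names of the two factors, used to build the
#'   `<A>_only` / `<B>_only` labels.
#' @return A tibble with `gene_id` and `group`.
#' @export
shared_and_exclusive_genes <- function(universe, bound_a, bound_b,
                                       labels = c("A", "B")) {
  stray <- setdiff(c(bound_a, bound_b), universe)
  if (length(stray)) {
    abort(sprintf(
      "gene universes differ: %d bound gene(s) absent from `universe` (e.g. %s)",
      length(stray), stray[1]
    ))
  }
  in_a <- universe %in% bound_a
  in_b <- universe %in% bound_b
  group <- dplyr::case_when(
    in_a & in_b ~ "dual",
    in_a ~ paste0(labels[1], "_only"),
    in_b ~ paste0(labels[2], "_only"),
    TRUE ~ "none"
  )
  tibble(gene_id = universe, group = group)
}
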