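#' Replicate-consensus peak filtering
#'
#' ChIP replicates of unequal quality are combined asymmetrically: the
#' strongest replicate is thresholded at a strict peak p-value (default
#' p <= 0.01), the remaining replicates at a looser one (default
#' p <= 0.05), and a best-replicate peak enters the final list only when
#' it overlaps (>= 1 bp) peaks called in the other replicate(s). Peaks
#' overlapping blacklist regions are removed per replicate beforehand.
#' Final peaks keep the best replicate's coordinates, summits and
#' p-values.
#'
#' @name consensus
NULL

#' Remove peaks overlapping blacklist regions
#'
#' A peak is removed when it shares >= 1 base with any blacklist interval;
#' half-open adjacency does not count. Order is preserved. The number of
#' removed peaks is attached as attribute `n_removed`.
#'
#' @param peaks Peak tibble.
#' @param blacklist Interval tibble (possibly empty).
#' @return The retained peaks.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  check_intervals(peaks, "peaks")
  check_intervals(blacklist, "blacklist")
  hit <- overlaps_any(peaks, blacklist)
  out <- peaks[!hit, , drop = FALSE]
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Threshold peaks on their p-value
#'
#' Keeps peaks with p-value <= `p_max`, i.e. `neglog10_p >= -log10(p_max)`.
#' The boundary is inclusive (compared with a 1e-9 guard against decimal
#' round-off in -log10 space).
#'
#' @param peaks Peak tibble with a `neglog10_p` column.
#' @param p_max Maximum peak p-value, in (0, 1].
#' @return The retained peaks, order preserved.
#' @export
threshold_peaks <- function(peaks, p_max) {
  if (!is.numeric(p_max) || length(p_max) != 1 || p_max <= 0 || p_max > 1) {
    abort("`p_max` must be a single probability in (0, 1]")
  }
  if (is.null(peaks$neglog10_p)) abort("`peaks` lacks a neglog10_p column")
  peaks[peaks$neglog10_p >= -log10(p_max) - 1e-9, , drop = FALSE]
}

#' Consensus of a best replicate against the other replicates
#'
#' Inputs are expected to be already blacklist-filtered and thresholded
#' (the best set at `cfg$p_best`, the others at `cfg$p_other`); use
#' [consensus_pipeline()] for the full chain. With
#' `cfg$consensus_mode = "all"` a best peak must overlap >= 1 peak in
#' every other replicate; with `"any"`, in at least one.
#'
#' @param best Peak tibble of the designated best-signal replicate.
#' @param others Non-empty list of peak tibbles for the other replicates.
#' @param cfg A [pipeline_config()].
#' @return A list: `peaks` (the final set, a subset of `best`) and
#'   `report` (named counts).
#' @export
consensus_peaks <- function(best, others, cfg = pipeline_config()) {
  check_intervals(best, "best")
  if (!is.list(others) || is.data.frame(others) || length(others) == 0) {
    abort("consensus requires >= 2 replicates: `others` must be a non-empty list of peak sets")
  }
  hit <- vapply(others, function(o) overlaps_any(best, o),
                logical(nrow(best)))
  if (nrow(best) == 0) {
    keep <- logical(0)
  } else {
    hit <- matrix(hit, nrow = nrow(best))
    keep <- if (cfg$consensus_mode == "all") {
      rowSums(hit) == length(others)
    } else {
      rowSums(hit) > 0
    }
  }
  final <- best[keep, , drop = FALSE]
  report <- list(
    n_best = nrow(best),
    n_other = vapply(others, nrow, integer(1)),
    consensus_mode = cfg$consensus_mode,
    n_final = nrow(final)
  )
  list(peaks = final, report = report)
}

#' Full per-replicate consensus pipeline
#'
#' Applies blacklist filtering to every replicate, thresholds the best
#' replicate at `cfg$p_best` and the others at `cfg$p_other`, and keeps
#' the best-replicate peaks confirmed by the other replicate(s). The best
#' replicate is designated by the caller; [replicate_frip()] can inform
#' that choice but is never applied automatically.
#'
#' @param replicates Named list of raw peak tibbles (>= 2 entries).
#' @param best Name or index of the best-signal replicate.
#' @param blacklist Interval tibble of excluded regions (may be empty).
#' @param cfg A [pipeline_config()].
#' @return A list: `peaks` (final set) and `report` with
#'   `n_input_per_replicate`, `n_blacklisted`, `n_pass_threshold`,
#'   `n_final`, `best_replicate` and `consensus_mode`.
#' @export
consensus_pipeline <- function(replicates, best = 1,
                               blacklist = NULL,
                               cfg = pipeline_config()) {
  if (!is.list(replicates) || length(replicates) < 2) {
    abort("consensus requires >= 2 replicates")
  }
  if (is.null(names(replicates)) || any(!nzchar(names(replicates)))) {
    names(replicates) <- sprintf("rep%d", seq_along(replicates))
  }
  if (is.numeric(best)) best <- names(replicates)[best]
  if (!best %in% names(replicates)) {
    abort(sprintf("unknown best replicate '%s'", best))
  }
  if (is.null(blacklist)) {
    blacklist <- tibble(chrom = character(), start = numeric(),
                        end = numeric())
  }
  n_input <- vapply(replicates, nrow, integer(1))
  cleaned <- lapply(replicates, filter_blacklist, blacklist = blacklist)
  n_blacklisted <- vapply(cleaned, function(x) attr(x, "n_removed"),
                          integer(1))
  thresholded <- lapply(names(cleaned), function(nm) {
    threshold_peaks(cleaned[[nm]],
                    if (nm == best) cfg$p_best else cfg$p_other)
  })
  names(thresholded) <- names(cleaned)
  n_pass <- vapply(thresholded, nrow, integer(1))
  res <- consensus_peaks(thresholded[[best]],
                         thresholded[names(thresholded) != best], cfg)
  list(
    peaks = res$peaks,
    report = list(
      n_input_per_replicate = n_input,
      n_blacklisted = n_blacklisted,
      n_pass_threshold = n_pass,
      n_final = nrow(res$peaks),
      best_replicate = best,
      consensus_mode = cfg$consensus_mode
    )
  )
}

#' Fraction of tags in peaks per replicate
#'
#' Reports, for each tag set, the fraction of deduplicated tags whose 5'
#' position falls inside a peak of the matching peak set - a simple
#' signal-quality readout that can guide the choice of the best replicate.
#'
#' @param tags Tag tibble, or named list of tag tibbles.
#' @param peaks Peak tibble, or list parallel to `tags`.
#' @return A tibble with `replicate`, `n_tags`, `n_in_peaks`, `frip`.
#' @export
replicate_frip <- function(tags, peaks) {
  if (is.data.frame(tags)) tags <- list(rep1 = tags)
  if (is.data.frame(peaks)) peaks <- rep(list(peaks), length(tags))
  if (length(peaks) != length(tags)) {
    abort("`peaks` must match `tags` in length")
  }
  if (is.null(names(tags))) names(tags) <- sprintf("rep%d", seq_along(tags))
  rows <- lapply(seq_along(tags), function(i) {
    tg <- dedup_tags(tags[[i]])
    pos <- tibble(chrom = tg$chrom, start = tg$five_prime_pos,
                  end = tg$five_prime_pos + 1)
    inside <- overlaps_any(pos, peaks[[i]])
    tibble(replicate = names(tags)[i], n_tags = nrow(tg),
           n_in_peaks = sum(inside),
           frip = if (nrow(tg)) sum(inside) / nrow(tg) else NA_real_)
  })
  dplyr::bind_rows(rows)
}
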