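#' Quick plots for metaprofiles and expression groups
#'
#' Lightweight ggplot2 wrappers (ggplot2 is an optional dependency); the
#' underlying tibbles are plain and easy to plot by hand.
#'
#' @name plots
NULL

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("install ggplot2 to use the plotting helpers")
  }
}

#' Plot ChIP and input TSS metaprofiles
#'
#' @param pair Output of [tss_metaprofile_pair()].
#' @return A ggplot object.
#' @export
plot_tss_metaprofile <- function(pair) {
  require_ggplot()
  long <- tidyr::pivot_longer(pair, c("chip_mean", "input_mean"),
                              names_to = "sample", values_to = "value")
  long$sample <- sub("_mean$", "", long$sample)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$offset_mid, y = .data$value,
                               color = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from TSS (bp)",
                  y = "mean normalized depth", color = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplot of expression by binding group
#'
#' @param values Long-format `values` tibble from [compare_groups()].
#' @return A ggplot object.
#' @export
plot_expression_groups <- function(values) {
  require_ggplot()
  ggplot2::ggplot(values,
                  ggplot2::aes(x = .data$group, y = .data$expression)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "log2(FPKM + 1)") +
    ggplot2::theme_minimal()
}
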