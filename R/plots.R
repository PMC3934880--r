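#' Plot global fold-change scales across samples
#'
#' Overlays one line per scale set (e.g. laboratory-derived vs
#' count-derived scales), on the shared sample axis.
#'
#' @param ... Named [scale_set()] objects; names label the lines.
#' @return A ggplot object.
#' @export
plot_scales <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("scales", seq_along(sets))
  }
  df <- purrr::imap_dfr(sets, function(s, nm) {
    tibble(sample = factor(s$sample, levels = s$sample), scale = s$scale,
           set = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$scale,
                                   colour = .data$set, group = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = NULL, y = "global fold-change Z", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot scale_set
#' @export
autoplot.scale_set <- function(object, ...) plot_scales(scales = object)

#' Distribution of normalized values per sample
#'
#' Box plots of the per-sample value distributions: under BSN the sample
#' totals track the global scales, whereas RPM/TMM drive the samples
#' toward identical distributions.
#'
#' @param object A normalized table or raw [count_tbl()].
#' @param ... Unused.
#' @return A ggplot object (linear values are shown on a log10 axis).
#' @method autoplot bsn_norm
#' @export
autoplot.bsn_norm <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"gene", names_to = "sample",
                              values_to = "value")
  long$sample <- factor(long$sample, levels = sample_ids(object))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%s value", norm_method(object) %||% "raw")) +
    ggplot2::theme_minimal()
  if (identical(value_space(object), "linear")) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}

#' @method autoplot bsn_counts
#' @export
autoplot.bsn_counts <- function(object, ...) {
  x <- new_norm_tbl(object, "raw", "linear")
  autoplot.bsn_norm(x)
}

#' Per-gene fold changes by method against the benchmark
#'
#' Grouped bars per gene, one fill per method plus the benchmark, faceted
#' by stage pair: the panel layout used to compare normalization methods
#' against RT-qPCR.
#'
#' @param fc An [combine_fold_changes()] table.
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(fc) {
  stopifnot(inherits(fc, "fc_table"))
  methods <- c(attr(fc, "methods"), "benchmark")
  long <- tidyr::pivot_longer(fc, all_of(methods), names_to = "method",
                              values_to = "log2_fc")
  long$method <- factor(long$method, levels = methods)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$log2_fc,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~pair, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "log2 fold change", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
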