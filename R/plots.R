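#' Plot heterozygosity density along scaffolds
#'
#' One panel per scaffold; bars give het sites per kb in each window, the
#' dashed line marks the ROH-proxy threshold. Windows below the line are the
#' visual proxy for runs of homozygosity.
#'
#' @param windows tibble from [het_windows()].
#' @param max_het_per_kb threshold line to draw (default 0.1; `NULL` omits).
#' @return a ggplot object.
#' @export
plot_het_windows <- function(windows, max_het_per_kb = 0.1) {
  check_columns(windows, c("scaffold", "bin_start", "het_per_kb"), "windows")
  p <- ggplot2::ggplot(
    windows,
    ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2e6, y = .data$het_per_kb)
  ) +
    ggplot2::geom_col(width = (windows$bin_end - windows$bin_start) / 1e6,
                      fill = "grey30") +
    ggplot2::facet_wrap(~scaffold, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "het sites / kb") +
    ggplot2::theme_minimal()
  if (!is.null(max_het_per_kb)) {
    p <- p + ggplot2::geom_hline(yintercept = max_het_per_kb, linetype = "dashed")
  }
  p
}

#' Plot genome fraction in ROH by length class
#'
#' @param summary tibble from [roh_summary()] (the `sub` class is dropped).
#' @return a ggplot object.
#' @export
plot_roh_summary <- function(summary) {
  check_columns(summary, c("length_class", "fraction"), "summary")
  df <- filter(summary, .data$length_class != "sub") |>
    mutate(length_class = factor(.data$length_class, levels = c("short", "medium", "long")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length_class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "ROH length class (short: 10-100 kb, medium: 100 kb-1 Mb, long: >= 1 Mb)",
      y = "fraction of genome"
    ) +
    ggplot2::theme_minimal()
}

#' Plot closure outcomes by gap size class
#'
#' @param x a `gap_closure` object (see [patch_assembly()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gap_closure <- function(x, ...) {
  df <- tidy(x) |>
    mutate(class = ifelse(is.na(.data$class), "other", .data$class))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, fill = .data$status)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = "gap size class", y = "gaps", fill = "status") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
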