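#' Plot a plaque size histogram
#'
#' Bars of relative percentage per equivalent-diameter bin.
#'
#' @param object a [size_histogram()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot size_histogram
#' @export
autoplot.size_histogram <- function(object, ...) {
  df <- as.data.frame(object)
  df$bin <- factor(df$bin, levels = df$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$rel_percent)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::labs(x = "equivalent diameter (µm)",
                  y = "relative percentage of plaques",
                  title = sprintf("Plaque size distribution (n = %d)",
                                  attr(object, "n"))) +
    ggplot2::theme_minimal()
}

#' Plot per-cube plaque density or load by group
#'
#' Jittered per-cube values over group, one point per sample cube, the
#' standard display for cube-based stereological summaries.
#'
#' @param per_cube tibble from [quantify_animal()] / [run_pipeline()] with
#'   `group` and the chosen column.
#' @param what `"density_per_mm3"` or `"load_percent"`.
#' @return A ggplot object.
#' @export
plot_cube_summary <- function(per_cube, what = c("density_per_mm3",
                                                 "load_percent")) {
  what <- match.arg(what)
  lab <- c(density_per_mm3 = "plaques per mm³",
           load_percent = "plaque load (volume %)")[[what]]
  ggplot2::ggplot(per_cube,
                  ggplot2::aes(x = .data$group, y = .data[[what]],
                               colour = .data$animal)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 2) +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' Plot group size-fraction differences with significance stars
#'
#' @param fractions tibble from [compare_group_fractions()].
#' @return A ggplot object.
#' @export
plot_fraction_comparison <- function(fractions) {
  df <- fractions
  df$bin <- factor(df$bin, levels = df$bin[order(df$bin_lo_um)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$diff_percent)) +
    ggplot2::geom_col(fill = "#cc6677") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.4,
                       na.rm = TRUE) +
    ggplot2::labs(x = "equivalent diameter (µm)",
                  y = "fraction difference (percentage points)") +
    ggplot2::theme_minimal()
}
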