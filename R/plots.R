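#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.smad_ensemble <- function(object, max_cells = 20, ...) {
  df <- tidy(object)
  keep <- utils::head(unique(df$cell), max_cells)
  ps <- population_stats(object)
  ggplot2::ggplot() +
    ggplot2::geom_line(data = dplyr::filter(df, .data$cell %in% keep),
                       ggplot2::aes(.data$time, .data$ratio, group = .data$cell),
                       alpha = 0.35, linewidth = 0.3) +
    ggplot2::geom_line(data = ps, ggplot2::aes(.data$time, .data$mean),
                       linewidth = 1) +
    ggplot2::labs(x = "time (min)", y = "nuc/cyt SMAD2 ratio") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.burst_catalog <- function(object, max_index = 5, ...) {
  df <- dplyr::filter(object$bursts, .data$burst_index <= max_index)
  df_long <- tidyr::pivot_longer(df, c("height", "duration"),
                                 names_to = "feature")
  ggplot2::ggplot(df_long,
                  ggplot2::aes(factor(.data$burst_index), .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = stats::median, geom = "point", color = "red") +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "burst index", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.burst_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fdr, .data$sensitivity)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_point(data = object$best, color = "red", size = 3) +
    ggplot2::geom_vline(xintercept = object$fdr_max, linetype = 2) +
    ggplot2::labs(x = "false detection rate", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.smad_objective <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(stats::reorder(.data$component, .data$value),
                               .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "weighted component") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.strong_order <- function(object, ...) {
  ggplot2::ggplot(object$errors, ggplot2::aes(.data$dt, .data$error)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Delta * t), y = "strong error",
                  subtitle = sprintf("slope %.2f (all), %.2f (finest %d)",
                                     object$slope_full, object$slope_fine,
                                     object$n_fine)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cir_paths <- function(object, max_paths = 20, ...) {
  df <- dplyr::filter(tidy(object), .data$path <= max_paths)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   group = .data$path)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "parameter value") +
    ggplot2::theme_minimal()
}
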