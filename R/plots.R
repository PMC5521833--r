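#' Plot a fitted path model's standardized coefficients
#'
#' Dot-and-interval plot of the standardized edge coefficients (approximate
#' 95% intervals on the standardized scale use the raw SE rescaled by the
#' standardized/raw estimate ratio).
#'
#' @param object A `path_model_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot path_model_fit
#' @export
autoplot.path_model_fit <- function(object, ...) {
  pt <- dplyr::filter(tidy(object), .data$type == "edge")
  scale_ratio <- ifelse(pt$estimate != 0, pt$std_estimate / pt$estimate, 1)
  pt$lo <- pt$std_estimate - 1.96 * pt$std.error * abs(scale_ratio)
  pt$hi <- pt$std_estimate + 1.96 * pt$std.error * abs(scale_ratio)
  ggplot2::ggplot(pt, ggplot2::aes(x = .data$std_estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$std_estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "standardized coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an effect decomposition
#'
#' Bar chart of the direct, per-path indirect, total-indirect and total
#' effects for one source-target pair.
#'
#' @param object An `effect_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot effect_decomposition
#' @export
autoplot.effect_decomposition <- function(object, ...) {
  d <- as_tibble(object)
  d$label <- ifelse(is.na(d$path), d$effect_type,
                    paste0(d$effect_type, ": ", d$path))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$label,
                                                     .data$estimate),
                                  fill = .data$effect_type)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(
      x = "standardized effect", y = NULL,
      title = paste0(d$source[1], " → ", d$target[1])
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot per-model fit summaries of a plan report
#'
#' CFI and RMSEA per model against their very-good-fit thresholds.
#'
#' @param report A `plan_report`.
#' @return A ggplot object.
#' @export
plot_fit_summary <- function(report) {
  stopifnot(inherits(report, "plan_report"))
  d <- tidyr::pivot_longer(
    report$models[c("model", "cfi", "rmsea")],
    cols = c("cfi", "rmsea"), names_to = "index", values_to = "value")
  thr <- tibble(index = c("cfi", "rmsea"), threshold = c(0.97, 0.03))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = 2, colour = "firebrick") +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
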