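# ggplot2 visualizations for the workflow result types.

#' Plot an active-learning campaign trace
#'
#' Cumulative fraction of actives retrieved per screening step.
#'
#' @param object A `campaign_trace` (or a row-bound tibble of several
#'   traces with an extra `strategy`/grouping column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.campaign_trace <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$step, y = .data$cum_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "screening step", y = "actives retrieved",
                  title = if (!is.null(cfg)) paste("strategy:", cfg$strategy) else NULL) +
    ggplot2::theme_minimal()
}

#' Plot an undersampling trace
#'
#' Validation average precision against the fraction of the training
#' set removed.
#'
#' @param object An `undersample_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.undersample_trace <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frac_removed, y = .data$avg_precision)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "training set removed", y = "average precision",
                  title = if (!is.null(cfg)) paste("policy:", cfg$policy) else NULL) +
    ggplot2::theme_minimal()
}

#' Plot importance score distributions of ranked actives
#'
#' Score distributions of the triaged actives split by confirmatory
#' outcome, the visual counterpart of the FP/TP decile rule.
#'
#' @param object A `triage_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triage_result <- function(object, ...) {
  df <- object$ranked |>
    dplyr::filter(!is.na(.data$confirmatory_label)) |>
    dplyr::mutate(outcome = ifelse(.data$confirmatory_label == 1,
                                   "true positive", "false positive"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "importance score", title = object$method) +
    ggplot2::theme_minimal()
}
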