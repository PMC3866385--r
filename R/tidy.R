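#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a study result
#'
#' One row per metric and method pair: the paired t comparisons, with the
#' max-degree variance F tests appended (their statistic column is `F`,
#' reported in `statistic` with `test = "F"`).
#'
#' @param x A `gsr_study`.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `method_a`, `method_b`, `test`,
#'   `statistic`, `p.value`, and the per-method means.
#' @export
tidy.gsr_study <- function(x, ...) {
  tt <- dplyr::transmute(x$comparisons,
    metric = .data$metric, method_a = .data$method_a,
    method_b = .data$method_b, test = "paired t",
    statistic = .data$t, df = as.numeric(.data$df), p.value = .data$p,
    mean_a = .data$mean_a, mean_b = .data$mean_b
  )
  ff <- dplyr::transmute(x$ftests,
    metric = .data$metric, method_a = .data$method_a,
    method_b = .data$method_b, test = "variance F",
    statistic = .data$F, df = NA_real_, p.value = .data$p,
    mean_a = .data$var_a, mean_b = .data$var_b
  )
  dplyr::bind_rows(tt, ff)
}

#' Glance at a study result
#'
#' @param x A `gsr_study`.
#' @param ... Unused.
#' @return A one-row tibble: study size, failure count, and the headline
#'   mean correlation per method.
#' @export
glance.gsr_study <- function(x, ...) {
  means <- dplyr::summarise(dplyr::group_by(x$metrics, .data$method),
                            mean_corr = mean(.data$mean_corr, na.rm = TRUE))
  wide <- stats::setNames(as.list(means$mean_corr),
                          paste0("mean_corr_", means$method))
  dplyr::bind_cols(tibble::tibble(
    n_subjects = x$config$n_subjects,
    n_methods = length(x$config$methods),
    n_nodes = x$phantom$n_nodes,
    S_target = x$config$S_target,
    n_failed = sum(x$metrics$status != "ok")
  ), tibble::as_tibble(wide))
}

#' Plot a study result
#'
#' `type = "metrics"` shows per-subject boxplots of the headline network
#' metrics by correction method; `type = "correlation"` shows the mean
#' correlation-coefficient distribution summaries per method.
#'
#' @param object A `gsr_study`.
#' @param type `"metrics"` or `"correlation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsr_study <- function(object, type = c("metrics", "correlation"), ...) {
  type <- match.arg(type)
  if (type == "correlation") {
    df <- dplyr::filter(object$metrics, .data$status == "ok")
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$mean_corr)) +
        ggplot2::geom_boxplot(outlier.size = 0.8) +
        ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
        ggplot2::labs(x = NULL, y = "mean off-diagonal correlation",
                      title = "Correlation bias by correction method")
    )
  }
  long <- tidyr::pivot_longer(
    dplyr::filter(object$metrics, .data$status == "ok"),
    cols = c("C", "L", "Nc", "connected_fraction", "Q", "n_modules",
             "n_junk_wm_adjacent"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Network metrics by correction method")
}

#' Plot a correlation-distribution summary
#'
#' Histogram of the off-diagonal correlations with the central sampling
#' density (population correlation zero) overlaid for reference: under
#' effective global-signal correction the histogram should be centred on zero.
#'
#' @param object A `corr_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.corr_summary <- function(object, ...) {
  h <- object$histogram
  width <- 2 / nrow(h)
  dens <- h$count / (sum(h$count) * width)
  df <- tibble::tibble(mid = h$mid, density = dens)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = width, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$mean, colour = "red") +
    ggplot2::labs(x = "correlation coefficient", y = "density",
                  title = sprintf("Off-diagonal correlations (mean %.4f)",
                                  object$mean))
}

#' Plot a degree distribution
#'
#' Log-log empirical degree distribution of a thresholded network.
#'
#' @param network A `binary_network`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(network) {
  dd <- degree_distribution(network)
  df <- dplyr::filter(dd$histogram, .data$degree > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "count",
                  title = sprintf("Degree distribution (max %d)", dd$max_degree))
}

#' @importFrom rlang .data
NULL
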