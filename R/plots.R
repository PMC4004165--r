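#' Plot a degree distribution with its power-law fit
#'
#' Log-log scatter of the empirical degree distribution `P(k)` with the
#' least-squares line whose negative slope is the reported exponent gamma.
#'
#' @param x A `reg_kb` or `causality_graph`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(x) {
  deg <- node_degrees(x)
  deg <- deg[deg > 0]
  tab <- table(deg)
  df <- tibble(k = as.numeric(names(tab)),
               pk = as.numeric(tab) / sum(tab))
  fit <- degree_power_law_fit(x)
  subtitle <- if (isTRUE(fit$available)) {
    sprintf("gamma = %.2f, r = %.0f", fit$gamma, fit$r)
  } else {
    "power-law fit unavailable (fewer than 3 degree bins)"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$pk)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(k)",
                  title = "Degree distribution", subtitle = subtitle)
  if (isTRUE(fit$available)) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                                  se = FALSE, linewidth = 0.5)
  }
  p
}

#' Plot benchmark success against the cutoff
#'
#' Success percentage as a function of the number of retained candidates,
#' one line per score key, faceted by candidate view.
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot benchmark_result
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(object$aggregate,
                  ggplot2::aes(x = .data$top_n, y = .data$success_pct,
                               colour = .data$key)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$view)) +
    ggplot2::labs(x = "candidates retained (top n)", y = "success (%)",
                  colour = "score",
                  title = if (object$params$shuffled) {
                    "Success at top n (shuffled control)"
                  } else {
                    "Success at top n"
                  }) +
    ggplot2::ylim(0, 100)
}

#' Plot the retained candidate set
#'
#' Scores of the retained candidates, coloured by hypothesis sign, tie
#' groups separated.
#'
#' @param ranked A [rank_with_ties()] tibble.
#' @param max_candidates Cap on bars drawn.
#' @return A ggplot object.
#' @export
plot_candidates <- function(ranked, max_candidates = 30) {
  df <- ranked[ranked$retained %||% rep(TRUE, nrow(ranked)), ]
  df <- head(df, max_candidates)
  ggplot2::ggplot(df,
                  ggplot2::aes(x = stats::reorder(.data$candidate, .data$rank),
                               y = .data$score, fill = .data$sign)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = attr(ranked, "key") %||% "score",
                  fill = "hypothesis",
                  title = "Upstream regulator candidates")
}
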