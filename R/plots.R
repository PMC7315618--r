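# ggplot2 views of the result tables.

#' Plot binding-site logos as stacked frequency bars
#'
#' One panel per group: at each primer position (5'→3') the observed template
#' base composition as a stacked bar, with the primer's own sequence along
#' the axis. A frequency (not information-content) scaling is used.
#'
#' @param pcm Long-form position count matrix from [build_pcm()].
#' @param primer Optional [primer()] used to label the x axis with the primer
#'   sequence.
#' @return A ggplot object.
#' @export
plot_primer_logo <- function(pcm, primer = NULL) {
  freq <- pcm |>
    group_by(.data$group, .data$position) |>
    mutate(freq = ifelse(sum(.data$count) > 0,
                         .data$count / sum(.data$count), 0)) |>
    ungroup()
  labels <- if (!is.null(primer)) {
    strsplit(primer$seq, "", fixed = TRUE)[[1]]
  } else {
    ggplot2::waiver()
  }
  ggplot2::ggplot(freq,
                  ggplot2::aes(x = .data$position, y = .data$freq,
                               fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(freq$position)),
                                labels = labels) +
    ggplot2::scale_fill_manual(values = c(A = "#33A02C", C = "#1F78B4",
                                          G = "#FF7F00", T = "#E31A1C",
                                          other = "grey70")) +
    ggplot2::facet_wrap(~group, ncol = 1) +
    ggplot2::labs(x = "primer position (5'→3')",
                  y = "template base frequency", fill = "base") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a fidelity regression
#'
#' Observed vs expected per-species proportions with the fitted OLS line and
#' the identity line a faithful pool should follow.
#'
#' @param object A `fidelity_fit` from [fit_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fidelity_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$value_x, y = .data$value_y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = g$slope, intercept = g$intercept,
                         colour = "#1F78B4") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "expected proportion", y = "observed proportion",
      title = sprintf("slope %.3f, intercept %.3f, R² %.3f",
                      g$slope, g$intercept, g$r_squared)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-pool fidelity panels
#'
#' Observed normalized proportions per pool against a reference profile
#' (typically the Best Estimate), one facet per pool, identity line shown.
#'
#' @param normalized [normalize_by_volume()] output.
#' @param reference `species` + value tibble (e.g. [best_estimate()] output).
#' @return A ggplot object.
#' @export
plot_pool_fidelity <- function(normalized, reference) {
  ref <- .profile_values(reference, "reference")
  dat <- normalized |>
    inner_join(ref, by = "species")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value, y = .data$norm_prop)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~pool) +
    ggplot2::labs(x = "reference proportion",
                  y = "normalized read proportion") +
    ggplot2::theme_minimal()
}
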