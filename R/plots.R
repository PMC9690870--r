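#' Ternary plot of compositions
#'
#' Draws compositions (typically yearly compositional means) in barycentric
#' coordinates, with PA at the origin, SB at the right vertex and SL at the
#' apex.
#'
#' @inheritParams comp_mean
#' @param colour Optional column mapped to point colour (e.g. `"year"`).
#' @return A ggplot object.
#' @export
plot_ternary <- function(data, parts = part_cols(), kappa = 24, colour = NULL) {
  tc <- ternary_coordinates(data, parts, kappa)
  if (!is.null(colour) && is.data.frame(data) && colour %in% names(data)) {
    tc[[colour]] <- data[[colour]]
  }
  tri <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  labs <- tibble::tibble(x = c(-0.03, 1.03, 0.5),
                         y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                         part = names(parts))
  p <- ggplot2::ggplot(tc, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$part), size = 3.5)
  p <- if (!is.null(colour) && colour %in% names(tc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data[[colour]])),
                            size = 2) +
      ggplot2::labs(colour = colour)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void()
}

#' Plot a substitution grid
#'
#' Predicted QoL change (with confidence ribbon) against reallocated time,
#' one panel per donor behaviour, one line per recipient.
#'
#' @param object A `qol_substitution` grid from [substitution_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qol_substitution
#' @export
autoplot.qol_substitution <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$feasible, , drop = FALSE]
  d$pair <- paste(d$from, "→", d$to)
  ggplot2::ggplot(d, ggplot2::aes(x = 60 * .data$amount, y = .data$delta,
                                  colour = .data$to, group = .data$pair)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high,
                                      fill = .data$to),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~from, labeller = ggplot2::labeller(
      from = function(f) paste("from", f))) +
    ggplot2::labs(x = "reallocated time (min)", y = "predicted QoL change",
                  colour = "to", fill = "to") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot quantile compositional profiles
#'
#' Group-mean versus overall-mean log-ratios by outcome quantile, one bar
#' per behaviour — the compositional geometric-mean bar chart by QoL level.
#'
#' @param profile Long tibble from [quantile_profile()] (optionally with a
#'   `year` column for facetting).
#' @return A ggplot object.
#' @export
plot_quantile_profile <- function(profile) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = factor(.data$quantile),
                                    y = .data$log_ratio, fill = .data$part)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "QoL quantile", y = "ln(group mean / overall mean)",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if ("year" %in% names(profile)) p <- p + ggplot2::facet_wrap(~year)
  p
}
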