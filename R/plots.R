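# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a survivorship/fecundity schedule
#'
#' Survivorship (lx) and per-class fecundity (mx) against age.
#'
#' @param object An `age_schedule`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.age_schedule <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("lx", "mx"),
      names_to = "quantity", values_to = "value"
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$x_h / 24, value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "Age (days)", y = NULL,
      title = "Survivorship (lx) and fecundity (mx) schedule"
    ) +
    ggplot2::theme_minimal()
}

#' Plot census trajectories
#'
#' Daily per-day growth rates of every census unit, with the averaging
#' window shaded.
#'
#' @param census A census tibble.
#' @param window Day range used for rate estimation.
#' @return A ggplot.
#' @export
plot_census <- function(census, window = c(7, 22)) {
  d <- dplyr::mutate(census,
    r_day = ifelse(.data$n_end > 0, log(.data$n_end / .data$n_start), NA_real_)
  )
  ggplot2::ggplot(d, ggplot2::aes(day, .data$r_day, group = unit_id)) +
    ggplot2::annotate("rect",
      xmin = window[1], xmax = window[2],
      ymin = -Inf, ymax = Inf, alpha = 0.1
    ) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(
      x = "Day", y = expression("Daily growth rate" ~ (d^-1)),
      title = "Serial-transfer census growth"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a direct/indirect decomposition
#'
#' Diverging bars of the indirect ((LP+P)-HP) and direct (LP-(LP+P))
#' relative differences per trait, with bootstrap intervals when present.
#'
#' @param x A `decomposition` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decomposition <- function(x, ...) {
  d <- tidy.decomposition(x)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    .data$relative_difference_pct, trait,
    fill = .data$component
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Relative difference (%)", y = NULL, fill = "Effect",
      title = "Direct vs indirect effects of P limitation"
    ) +
    ggplot2::theme_minimal()
  if (!all(is.na(d$conf_low))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3
    )
  }
  p
}
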