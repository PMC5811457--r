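# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an Euler-Lotka fit
#'
#' @param x An `euler_lotka` object.
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate` and the solver
#'   diagnostics.
#' @export
tidy.euler_lotka <- function(x, ...) {
  tibble::tibble(
    term = "r",
    estimate = x$r_d,
    unit = "per day",
    residual = x$residual
  )
}

#' @rdname tidy.euler_lotka
#' @export
glance.euler_lotka <- function(x, ...) {
  tibble::tibble(
    r_d = x$r_d,
    R0 = x$R0,
    generation_days = x$generation_days,
    residual = x$residual,
    iterations = x$iterations,
    n_classes = x$n_classes
  )
}

#' Tidy a decomposition result
#'
#' Pivots a `decomposition` table into one row per trait and component
#' (indirect, direct) with its relative difference and, when present,
#' bootstrap bounds — the shape of a direct/indirect overview table.
#'
#' @param x A `decomposition` tibble.
#' @param ... Unused.
#' @return A tibble with `trait`, `component`, `relative_difference_pct`,
#'   optional `conf_low`/`conf_high`, and `scenario`.
#' @export
tidy.decomposition <- function(x, ...) {
  x <- tibble::as_tibble(x)
  long <- dplyr::bind_rows(
    dplyr::transmute(x,
      trait,
      component = "indirect",
      contrast = "(LP+P)-HP",
      relative_difference_pct = .data$indirect_pct,
      conf_low = if ("indirect_lo" %in% names(x)) .data$indirect_lo else NA_real_,
      conf_high = if ("indirect_hi" %in% names(x)) .data$indirect_hi else NA_real_,
      scenario = .data$scenario
    ),
    dplyr::transmute(x,
      trait,
      component = "direct",
      contrast = "LP-(LP+P)",
      relative_difference_pct = .data$direct_pct,
      conf_low = if ("direct_lo" %in% names(x)) .data$direct_lo else NA_real_,
      conf_high = if ("direct_hi" %in% names(x)) .data$direct_hi else NA_real_,
      scenario = .data$scenario
    )
  )
  dplyr::arrange(long, trait, dplyr::desc(.data$component))
}
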