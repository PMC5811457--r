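# Intrinsic rate of increase from a life-table schedule (Euler-Lotka) and
# exponential growth rates from serial-transfer census series.

#' Intrinsic rate of increase from a schedule
#'
#' Solves the Euler-Lotka equation `1 = sum(lx * mx * exp(-r * x))` for the
#' intrinsic per-day rate of increase r. Because the left side is strictly
#' decreasing in r whenever some reproduction occurs at a positive age, the
#' root is unique; it is located by bracketed bisection with automatic
#' bracket doubling. The sign of r follows the net reproductive rate
#' `R0 = sum(lx * mx)`: r > 0 iff R0 > 1, r = 0 iff R0 = 1.
#'
#' @param schedule An [build_schedule()] result, or any data frame with
#'   columns `x_h` (or `x_d`), `lx`, `mx`.
#' @param x_unit Unit of the age column: ages in hours (`x_h`, default) are
#'   converted to days so r is per day.
#' @param tol Residual tolerance on `|sum(lx mx e^(-r x)) - 1|`.
#' @param bracket Initial rate bracket in per-day units; doubled outward
#'   until it straddles the root.
#' @param max_expand Maximum number of bracket doublings.
#'
#' @return An object of class `euler_lotka`: a list with `r_d` (per-day
#'   rate), `R0`, `generation_days`, `residual`, `iterations`,
#'   `n_classes`, `method`. Use [tidy()][generics::tidy] or
#'   [glance()][generics::glance] for a tibble view.
#' @export
#' @examples
#' sched <- tibble::tibble(x_h = 24, lx = 1, mx = 2)
#' euler_lotka_r(sched)$r_d # log(2): doubling each day
euler_lotka_r <- function(schedule, x_unit = c("hours", "days"),
                          tol = 1e-10, bracket = c(-5, 5),
                          max_expand = 60) {
  x_unit <- match.arg(x_unit)
  x <- if ("x_d" %in% names(schedule) && x_unit == "days") {
    schedule$x_d
  } else if (x_unit == "hours") {
    schedule$x_h / 24
  } else {
    schedule$x_h
  }
  lx <- schedule$lx
  mx <- schedule$mx
  stopifnot(length(x) == length(lx), length(lx) == length(mx))
  keep <- lx * mx > 0
  R0 <- sum(lx * mx)
  if (R0 == 0) {
    abort("No reproduction in schedule (R0 = 0); r is undefined.",
      class = "stoichdemo_no_reproduction_error"
    )
  }
  if (any(keep & x <= 0)) {
    abort("Reproduction at non-positive age; Euler-Lotka root may not exist.",
      class = "stoichdemo_config_error"
    )
  }
  f <- function(r) sum(lx[keep] * mx[keep] * exp(-r * x[keep])) - 1

  lo <- min(bracket)
  hi <- max(bracket)
  n_expand <- 0
  # f is decreasing: need f(lo) > 0 > f(hi)
  while (f(lo) < 0 && n_expand < max_expand) {
    lo <- lo - (hi - lo)
    n_expand <- n_expand + 1
  }
  while (f(hi) > 0 && n_expand < max_expand) {
    hi <- hi + (hi - lo)
    n_expand <- n_expand + 1
  }
  if (f(lo) < 0 || f(hi) > 0) {
    abort("Could not bracket the Euler-Lotka root after bracket expansion.",
      class = "stoichdemo_bracket_error"
    )
  }
  iter <- 0
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    iter <- iter + 1
    if (abs(fm) <= tol || (hi - lo) < .Machine$double.eps * max(1, abs(mid)) ||
      iter >= 200) {
      break
    }
    if (fm > 0) lo <- mid else hi <- mid
  }
  structure(
    list(
      r_d = mid,
      R0 = R0,
      generation_days = sum(x[keep] * lx[keep] * mx[keep]) / R0,
      residual = abs(fm),
      iterations = iter,
      n_classes = length(x),
      method = "euler_lotka"
    ),
    class = "euler_lotka"
  )
}

#' @export
print.euler_lotka <- function(x, ...) {
  cat("Euler-Lotka intrinsic rate of increase\n")
  cat(sprintf("  r  = %.6f per day\n", x$r_d))
  cat(sprintf("  R0 = %.4f;  mean generation time = %.3f days\n", x$R0, x$generation_days))
  cat(sprintf("  residual %.2e after %d bisection steps\n", x$residual, x$iterations))
  invisible(x)
}

#' Euler-Lotka r for every replicate of a trial
#'
#' Builds one schedule per group and solves for r in each.
#'
#' @inheritParams life_schedules
#' @param ... Passed to [euler_lotka_r()].
#' @return A tibble with the grouping columns plus `r_d`, `R0`,
#'   `generation_days`, `residual`, `truncated` (whether any individual in
#'   the group was horizon-censored, in which case the schedule — and r —
#'   reflect the truncated reproductive window).
#' @export
intrinsic_rates <- function(events, age_class_width = 2,
                            by = c("treatment", "chemostat_replicate"), ...) {
  events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(.keep = TRUE, .f = function(d, key) {
      fit <- euler_lotka_r(build_schedule(d, age_class_width), ...)
      tibble::tibble(
        r_d = fit$r_d, R0 = fit$R0,
        generation_days = fit$generation_days,
        residual = fit$residual,
        truncated = any(individual_summaries(d)$end_reason == "censored_horizon")
      )
    }) |>
    dplyr::ungroup()
}

#' Exponential growth rate from a census series
#'
#' For each unit, computes the per-day rate `R = (ln Nt - ln N0) / t` over
#' every scored 24-h period (t = 1 day) and averages it over the scoring
#' window — by default the last 16 days of a 22-day series (days 7-22),
#' the period over which serial-transfer growth has stabilised. Days with
#' a zero end count cannot enter the log-ratio: they are excluded and
#' counted in `n_excluded`.
#'
#' @param census A census tibble (see [simulate_census()] /
#'   [read_census()]).
#' @param window Inclusive day range to average over.
#' @return One row per unit: labels, `r_d` (mean per-day rate), `n_days`
#'   (days used), `n_excluded`.
#' @export
#' @examples
#' cen <- simulate_census(design_config(n_clones = 1, n_replicates = 2))
#' census_growth_rate(cen)
census_growth_rate <- function(census, window = c(7, 22)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (window[1] < min(census$day) || window[2] > max(census$day)) {
    abort(sprintf(
      "Window [%g, %g] lies outside the scored days [%g, %g].",
      window[1], window[2], min(census$day), max(census$day)
    ), class = "stoichdemo_config_error")
  }
  census |>
    dplyr::filter(day >= window[1], day <= window[2]) |>
    dplyr::group_by(unit_id, clone, treatment, chemostat_replicate) |>
    dplyr::summarise(
      n_days = sum(.data$n_end > 0),
      n_excluded = sum(.data$n_end == 0),
      r_d = mean(log(.data$n_end[.data$n_end > 0] /
        .data$n_start[.data$n_end > 0])),
      .groups = "drop"
    )
}
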