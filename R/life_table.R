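# Age-classed survivorship/fecundity schedules and per-individual
# life-history traits from interval-censored event logs.
#
# Age classes are the half-open intervals ((j-1)*w, j*w]: an event recorded
# at a check falls in the class ending at that check, because it happened
# at some point since the previous one. Survivorship is product-limit over
# classes; censored individuals leave the risk set without counting as
# deaths.

#' Summarise individuals from an event log
#'
#' Collapses an event log to one row per individual, inferring the end
#' reason: a `death` row means death; a `censored` row coinciding with a
#' `male_egg` event means censoring on male-egg production; a censoring at
#' the k-th hatched neonate is completion; anything else is a horizon
#' censoring.
#'
#' @param events An event-log tibble (see [simulate_individuals()]).
#' @param k_neonates Neonate count that defines completion (default 4).
#' @return One row per individual: labels, `end_time_h`, `end_reason`
#'   (`death`, `censored_male_egg`, `completed_k_neonates`,
#'   `censored_horizon`), and egg counts by fate.
#' @export
individual_summaries <- function(events, k_neonates = 4) {
  events |>
    dplyr::group_by(individual_id, clone, treatment, chemostat_replicate) |>
    dplyr::summarise(
      end_time_h = max(.data$event_time_h),
      died = any(.data$event_type == "death"),
      male_at_end = any(.data$event_type == "male_egg" &
        .data$event_time_h == max(.data$event_time_h)),
      n_eggs_laid = sum(.data$event_type %in% c("egg_laid", "male_egg")),
      n_hatched = sum(.data$event_type == "egg_hatched"),
      n_eggs_died = sum(.data$event_type == "egg_died"),
      n_male_eggs = sum(.data$event_type == "male_egg"),
      kth_hatch_at_end = sum(.data$event_type == "egg_hatched") >= k_neonates &&
        any(.data$event_type == "egg_hatched" &
          .data$event_time_h == max(.data$event_time_h)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      end_reason = dplyr::case_when(
        died ~ "death",
        male_at_end ~ "censored_male_egg",
        kth_hatch_at_end ~ "completed_k_neonates",
        TRUE ~ "censored_horizon"
      )
    ) |>
    dplyr::select(-"male_at_end", -"kth_hatch_at_end")
}

#' Build an age-classed survivorship/fecundity schedule
#'
#' Converts the event log of one cohort into a life-table schedule. Age
#' class j spans ages ((j-1)w, jw] with midpoint x = (j - 1/2)w. `lx` is
#' the product-limit fraction surviving from birth to the start of class j
#' (censored individuals exit the risk set without counting as deaths);
#' `mx` is the number of hatched neonates in class j per individual at
#' risk in that class. The schedule extends to the last observed event.
#'
#' @param events Event log of the cohort (all individuals pooled).
#' @param age_class_width Class width in hours; defaults to the 2-h
#'   monitoring resolution.
#' @return A tibble of class `age_schedule` with columns `age_class`,
#'   `x_h` (class midpoint, hours), `n_risk`, `deaths`, `neonates`, `lx`,
#'   `mx`.
#' @export
#' @examples
#' log <- simulate_individuals(design_config(n_replicates = 1, n_individuals = 5))
#' build_schedule(dplyr::filter(log, treatment == "HP"))
build_schedule <- function(events, age_class_width = 2) {
  if (!is.numeric(age_class_width) || age_class_width <= 0) {
    abort("`age_class_width` must be > 0.", class = "stoichdemo_config_error")
  }
  if (nrow(events) == 0) {
    abort("Cannot build a schedule from an empty event log.",
      class = "stoichdemo_config_error"
    )
  }
  w <- age_class_width
  ind <- individual_summaries(events)
  if (all(ind$end_time_h <= 0)) {
    abort("All individuals censored at birth; schedule undefined.",
      class = "stoichdemo_config_error"
    )
  }
  # class of an age: events at ((j-1)w, jw] belong to class j
  class_of <- function(t) pmax(1L, as.integer(ceiling(t / w - 1e-9)))
  last_event <- max(events$event_time_h)
  n_classes <- class_of(last_event)

  end_class <- class_of(ind$end_time_h)
  deaths <- tabulate(end_class[ind$end_reason == "death"], n_classes)
  hatch_times <- events$event_time_h[events$event_type == "egg_hatched"]
  neonates <- tabulate(class_of(hatch_times), n_classes)

  # at risk in class j: end time beyond the start of class j
  starts <- (seq_len(n_classes) - 1) * w
  n_risk <- vapply(
    starts, function(s) sum(ind$end_time_h > s + 1e-9), integer(1)
  )

  lx <- numeric(n_classes)
  lx[1] <- 1
  for (j in seq_len(n_classes - 1)) {
    surv <- if (n_risk[j] > 0) 1 - deaths[j] / n_risk[j] else 1
    lx[j + 1] <- lx[j] * surv
  }
  mx <- ifelse(n_risk > 0, neonates / n_risk, 0)

  out <- tibble::tibble(
    age_class = seq_len(n_classes),
    x_h = (seq_len(n_classes) - 0.5) * w,
    n_risk = n_risk,
    deaths = deaths,
    neonates = neonates,
    lx = lx,
    mx = mx
  )
  class(out) <- c("age_schedule", class(out))
  attr(out, "age_class_width") <- w
  attr(out, "n_individuals") <- nrow(ind)
  out
}

#' Schedules for every group of a trial
#'
#' Applies [build_schedule()] within groups (by default each treatment x
#' chemostat replicate, the trial's true unit of replication) and returns
#' one long tibble.
#'
#' @inheritParams build_schedule
#' @param by Grouping columns.
#' @return A tibble with the grouping columns plus the schedule columns.
#' @export
life_schedules <- function(events, age_class_width = 2,
                           by = c("treatment", "chemostat_replicate")) {
  events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(.keep = TRUE, .f = function(d, key) {
      sched <- build_schedule(d, age_class_width)
      tibble::as_tibble(sched)
    }) |>
    dplyr::ungroup()
}

#' Per-individual life-history traits
#'
#' Extracts, for each individual: age at first egg laying; development time
#' of each hatched egg (hatching minus laying); and the egg production
#' rate, defined as eggs laid per hour over the interval from the first to
#' the last laying, which must span at least two laying events — otherwise
#' the rate is `NA` (unavailable, not an error).
#'
#' @param events An event-log tibble.
#' @return One row per individual with `age_first_egg_h`,
#'   `first_egg_dev_h`, `mean_egg_dev_h`, `egg_production_rate_h`,
#'   `n_eggs_laid`, `n_hatched`, `n_eggs_died`, `died`.
#' @export
#' @examples
#' log <- simulate_individuals(design_config(n_replicates = 1, n_individuals = 3))
#' extract_traits(log)
extract_traits <- function(events) {
  lays <- events |>
    dplyr::filter(event_type %in% c("egg_laid", "male_egg")) |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(
      age_first_egg_h = min(.data$event_time_h),
      last_egg_h = max(.data$event_time_h),
      n_lays = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      egg_production_rate_h = dplyr::if_else(
        .data$n_lays >= 2 & .data$last_egg_h > .data$age_first_egg_h,
        .data$n_lays / (.data$last_egg_h - .data$age_first_egg_h),
        NA_real_
      )
    )
  dev <- egg_development(events) |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(
      first_egg_dev_h = .data$development_h[which.min(.data$egg_index)][1],
      mean_egg_dev_h = mean(.data$development_h),
      .groups = "drop"
    )
  individual_summaries(events) |>
    dplyr::left_join(lays, by = "individual_id") |>
    dplyr::left_join(dev, by = "individual_id") |>
    dplyr::select(
      "individual_id", "clone", "treatment", "chemostat_replicate",
      "age_first_egg_h", "first_egg_dev_h", "mean_egg_dev_h",
      "egg_production_rate_h", "n_eggs_laid", "n_hatched", "n_eggs_died",
      "died", "end_time_h", "end_reason"
    )
}

#' Per-egg development times
#'
#' @param events An event-log tibble.
#' @return One row per hatched egg: `individual_id`, `treatment`,
#'   `chemostat_replicate`, `egg_index`, `lay_time_h`, `hatch_time_h`,
#'   `development_h`.
#' @export
egg_development <- function(events) {
  lays <- events |>
    dplyr::filter(event_type == "egg_laid") |>
    dplyr::select(
      "individual_id", "treatment", "chemostat_replicate",
      "egg_index", lay_time_h = "event_time_h"
    )
  hatches <- events |>
    dplyr::filter(event_type == "egg_hatched") |>
    dplyr::select("individual_id", "egg_index", hatch_time_h = "event_time_h")
  dplyr::inner_join(lays, hatches, by = c("individual_id", "egg_index")) |>
    dplyr::mutate(development_h = .data$hatch_time_h - .data$lay_time_h)
}

#' Individual and egg mortality by group
#'
#' Individual mortality is observed deaths over individuals; egg mortality
#' is dead eggs over eggs with a resolved fate (hatched or died) — male and
#' unresolved eggs are excluded from the denominator so monitoring
#' truncation does not bias the estimate. Percentages are reported to one
#' decimal; a group with no resolved eggs gets `NA` egg mortality.
#'
#' @param events An event-log tibble.
#' @param by Grouping columns (default per treatment).
#' @return A tibble per group: `n_individuals`, `n_deaths`,
#'   `individual_mortality_pct`, `eggs_resolved`, `eggs_died`,
#'   `egg_mortality_pct`.
#' @export
#' @examples
#' log <- simulate_individuals()
#' mortality_summary(log)
mortality_summary <- function(events, by = "treatment") {
  events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_individuals = dplyr::n_distinct(.data$individual_id),
      n_deaths = sum(.data$event_type == "death"),
      eggs_resolved = sum(.data$event_type %in% c("egg_hatched", "egg_died")),
      eggs_died = sum(.data$event_type == "egg_died"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      individual_mortality_pct = round(100 * .data$n_deaths / .data$n_individuals, 1),
      egg_mortality_pct = dplyr::if_else(
        .data$eggs_resolved > 0,
        round(100 * .data$eggs_died / .data$eggs_resolved, 1),
        NA_real_
      )
    )
}
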