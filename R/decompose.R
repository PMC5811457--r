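# Decomposition of a food-quality response into direct (stoichiometric)
# and indirect (non-stoichiometric) components.
#
# In the three-arm P-supplementation contrast, LP+P food has the elemental
# composition of HP food but the growth history of LP food. The LP+P vs HP
# contrast therefore isolates the indirect (non-stoichiometric) effect of
# P-limited growth history, and the LP vs LP+P contrast the direct
# (stoichiometric) effect of P content itself. Each is expressed as a
# relative difference against its comparison baseline:
#   indirect = 100 * (mean_LPP - mean_HP) / mean_HP
#   direct   = 100 * (mean_LP - mean_LPP) / mean_LPP
# Mortality-type traits are decomposed on survival = 1 - mortality, since
# a zero-mortality baseline would make the relative difference undefined.

#' Decompose a trait response into direct and indirect components
#'
#' @param mean_hp,mean_lpp,mean_lp Treatment-level trait means (HP, LP+P,
#'   LP). For `mortality = TRUE` these must be proportions between 0 and 1 and
#'   are transformed to survival before decomposition.
#' @param trait Optional trait label carried into the result.
#' @param orientation `"benefit"` if larger trait values mean better
#'   performance, `"cost"` otherwise; recorded in the result and used by
#'   plotting.
#' @param mortality Decompose on survival = 1 - mean (for unit-interval
#'   mortality-type traits).
#' @param scenario_tolerance_pct Tolerance (percentage points) below which
#'   a component counts as absent when classifying the scenario.
#'
#' @return A one-row tibble of class `decomposition`: the three means, the
#'   `indirect_pct` and `direct_pct` relative differences, and `scenario`
#'   (`"I"` direct-only, `"II"` both, `"III"` indirect-only, `"none"`).
#'   A zero reference mean on a non-mortality trait yields `NA` for the
#'   affected component, with a warning.
#' @export
#' @examples
#' # egg mortality 0% (HP), 0% (LP+P), 23.1% (LP), on the survival scale:
#' decompose_effects(0, 0, 0.231, trait = "egg mortality", mortality = TRUE)
decompose_effects <- function(mean_hp, mean_lpp, mean_lp,
                              trait = NA_character_,
                              orientation = c("benefit", "cost"),
                              mortality = FALSE,
                              scenario_tolerance_pct = 5) {
  orientation <- match.arg(orientation)
  stopifnot(
    length(mean_hp) == 1, length(mean_lpp) == 1, length(mean_lp) == 1
  )
  if (any(is.na(c(mean_hp, mean_lpp, mean_lp)))) {
    abort("All three treatment means must be present.",
      class = "stoichdemo_domain_error"
    )
  }
  if (mortality) {
    if (any(c(mean_hp, mean_lpp, mean_lp) < 0 | c(mean_hp, mean_lpp, mean_lp) > 1)) {
      abort("Mortality-type means must be proportions in [0, 1].",
        class = "stoichdemo_domain_error"
      )
    }
    b_hp <- 1 - mean_hp
    b_lpp <- 1 - mean_lpp
    b_lp <- 1 - mean_lp
    orientation <- "cost"
  } else {
    b_hp <- mean_hp
    b_lpp <- mean_lpp
    b_lp <- mean_lp
  }
  indirect <- if (b_hp != 0) 100 * (b_lpp - b_hp) / b_hp else NA_real_
  direct <- if (b_lpp != 0) 100 * (b_lp - b_lpp) / b_lpp else NA_real_
  if (is.na(indirect) || is.na(direct)) {
    warn("Zero reference mean: affected component set to NA.")
  }
  out <- tibble::tibble(
    trait = trait,
    orientation = orientation,
    mortality_scale = mortality,
    mean_hp = mean_hp, mean_lpp = mean_lpp, mean_lp = mean_lp,
    indirect_pct = indirect,
    direct_pct = direct,
    scenario = classify_scenario(indirect, direct, scenario_tolerance_pct)
  )
  class(out) <- c("decomposition", class(out))
  out
}

#' Classify the decomposition scenario
#'
#' Scenario `"I"`: the response is driven by the direct, stoichiometric
#' effect alone (indirect component within tolerance). Scenario `"III"`:
#' entirely indirect, non-stoichiometric. Scenario `"II"`: both components
#' exceed the tolerance. `"none"`: neither does. `NA` components give `NA`.
#'
#' @param indirect_pct,direct_pct Relative differences in percent.
#' @param tolerance_pct Magnitude (percentage points) below which a
#'   component counts as absent. Default 5.
#' @return Character vector of `"I"`, `"II"`, `"III"` or `"none"`.
#' @export
#' @examples
#' classify_scenario(0, -23.1, tolerance_pct = 1) # direct only: "I"
#' classify_scenario(36.2, 2.9) # indirect only: "III"
classify_scenario <- function(indirect_pct, direct_pct, tolerance_pct = 5) {
  dplyr::case_when(
    is.na(indirect_pct) | is.na(direct_pct) ~ NA_character_,
    abs(indirect_pct) <= tolerance_pct & abs(direct_pct) <= tolerance_pct ~ "none",
    abs(indirect_pct) <= tolerance_pct ~ "I",
    abs(direct_pct) <= tolerance_pct ~ "III",
    TRUE ~ "II"
  )
}

#' Decompose replicate-level trait means with bootstrap intervals
#'
#' Takes replicate-level means (one row per chemostat replicate, the
#' trial's true unit of replication), averages them into treatment means,
#' decomposes, and attaches percentile bootstrap intervals obtained by
#' resampling replicates with replacement within each treatment.
#'
#' @param data A tibble with columns `treatment` (levels `HP`, `LP`,
#'   `LP+P`) and `value` (one replicate-level mean per row).
#' @param n_boot Bootstrap draws (>= 100).
#' @param seed Integer seed for the bootstrap.
#' @inheritParams decompose_effects
#' @return A one-row `decomposition` tibble with
#'   `indirect_lo`/`indirect_hi`/`direct_lo`/`direct_hi` 95% bounds added.
#' @export
decompose_replicates <- function(data, trait = NA_character_,
                                 orientation = c("benefit", "cost"),
                                 mortality = FALSE,
                                 scenario_tolerance_pct = 5,
                                 n_boot = 1000, seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("treatment", "value") %in% names(data)))
  grp <- split(data$value[!is.na(data$value)], data$treatment[!is.na(data$value)])
  need <- c("HP", "LP", "LP+P")
  if (!all(need %in% names(grp))) {
    abort("Data must contain the treatments HP, LP and LP+P.",
      class = "stoichdemo_domain_error"
    )
  }
  if (n_boot < 100) {
    abort("`n_boot` must be >= 100.", class = "stoichdemo_config_error")
  }
  if (any(vapply(grp[need], length, integer(1)) < 2)) {
    abort("At least 2 replicates per treatment are required.",
      class = "stoichdemo_domain_error"
    )
  }
  point <- decompose_effects(
    mean(grp$HP), mean(grp$`LP+P`), mean(grp$LP),
    trait = trait, orientation = orientation, mortality = mortality,
    scenario_tolerance_pct = scenario_tolerance_pct
  )
  boot <- with_unit_seed(seed, c("bootstrap", trait), {
    draws <- purrr::map(seq_len(n_boot), function(b) {
      m <- vapply(
        grp[need],
        function(v) mean(sample(v, length(v), replace = TRUE)),
        numeric(1)
      )
      suppressWarnings(decompose_effects(
        m[["HP"]], m[["LP+P"]], m[["LP"]],
        mortality = mortality,
        scenario_tolerance_pct = scenario_tolerance_pct
      ))
    })
    purrr::list_rbind(draws)
  })
  ci <- function(v) quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  ind_ci <- ci(boot$indirect_pct)
  dir_ci <- ci(boot$direct_pct)
  out <- dplyr::mutate(point,
    indirect_lo = ind_ci[1], indirect_hi = ind_ci[2],
    direct_lo = dir_ci[1], direct_hi = dir_ci[2],
    n_boot = n_boot
  )
  class(out) <- c("decomposition", setdiff(class(out), "decomposition"))
  out
}

#' Decompose every trait of a replicate-level summary table
#'
#' Applies [decompose_replicates()] to each trait of a long table of
#' replicate-level means, producing a report shaped like a
#' direct/indirect overview table.
#'
#' @param data Long tibble with columns `trait`, `treatment`,
#'   `chemostat_replicate`, `value`, and optionally `orientation` and
#'   `mortality` (constant within trait).
#' @inheritParams decompose_replicates
#' @return A `decomposition` tibble, one row per trait.
#' @export
decompose_traits <- function(data, scenario_tolerance_pct = 5,
                             n_boot = 1000, seed = 1L) {
  stopifnot(all(c("trait", "treatment", "value") %in% names(data)))
  out <- data |>
    dplyr::group_by(trait) |>
    dplyr::group_modify(function(d, key) {
      ori <- if ("orientation" %in% names(d)) d$orientation[1] else "benefit"
      mort <- if ("mortality" %in% names(d)) isTRUE(d$mortality[1]) else FALSE
      res <- decompose_replicates(
        d,
        trait = key$trait, orientation = ori, mortality = mort,
        scenario_tolerance_pct = scenario_tolerance_pct,
        n_boot = n_boot, seed = seed
      )
      dplyr::select(res, -"trait")
    }) |>
    dplyr::ungroup()
  class(out) <- c("decomposition", class(out))
  out
}
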