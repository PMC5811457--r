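#' Treatment-level simulation parameters
#'
#' One row of demographic, morphometric and stoichiometric parameters for a
#' single food-quality treatment. The three canonical treatments of a
#' P-supplementation design are `HP` (P-replete algae), `LP` (P-limited
#' algae) and `LP+P` (P-limited algae spiked with inorganic phosphate just
#' before feeding).
#'
#' Latent life-history times are Gaussian around their means, truncated at
#' zero; event times are only ever observed on the monitoring grid (see
#' [simulate_individuals()]). Monitoring stops either at the k-th hatched
#' neonate (`monitor_rule = "k_neonates"`) or at a fixed horizon
#' (`monitor_rule = "fixed_hours"`).
#'
#' @param treatment Treatment label, e.g. `"HP"`, `"LP"`, `"LP+P"`.
#' @param maturation_mean_h,maturation_sd_h Age at first egg laying (h).
#' @param inter_egg_mean_h,inter_egg_sd_h Interval between successive egg
#'   layings (h).
#' @param egg_dev_mean_h,egg_dev_sd_h Egg development time, laying to
#'   hatching (h).
#' @param egg_mortality_prob Probability that an egg dies before hatching.
#' @param adult_hazard_h Per-hour death probability of the focal female.
#' @param male_egg_prob Probability that an egg laying event is a male egg
#'   (which right-censors the individual).
#' @param monitor_rule `"k_neonates"` or `"fixed_hours"`.
#' @param monitor_k Number of hatched neonates ending monitoring (used when
#'   `monitor_rule = "k_neonates"`).
#' @param monitor_hours Fixed monitoring horizon in hours (used when
#'   `monitor_rule = "fixed_hours"`).
#' @param body_length_um,body_length_sd_um,body_width_um,body_width_sd_um
#'   Body length/width at first reproduction (micrometres).
#' @param egg_length_um,egg_length_sd_um,egg_width_um,egg_width_sd_um
#'   Length/width of the first egg (micrometres).
#' @param algal_cp_mean Mean molar C:P of the algal food.
#' @param algal_cp_se Standard error of the treatment-mean algal C:P; batch
#'   values are drawn with sd `algal_cp_se * sqrt(algal_cp_n)`.
#' @param algal_cp_n Number of batch measurements the standard error refers
#'   to.
#' @param c_per_ind_ug,n_per_ind_ug,p_per_ind_ug Mean C, N, P mass per
#'   rotifer individual (micrograms).
#' @param content_cv Coefficient of variation of pooled elemental masses.
#' @param growth_rate_d True per-day exponential growth rate in the census
#'   experiment.
#' @param census_sd Standard deviation of the lognormal day-to-day noise on
#'   census counts (on the log scale).
#'
#' @return A one-row tibble; bind rows to build a multi-treatment parameter
#'   table such as [default_params()].
#' @export
#' @examples
#' treatment_params("HP")
treatment_params <- function(treatment,
                             maturation_mean_h = 16, maturation_sd_h = 2,
                             inter_egg_mean_h = 5, inter_egg_sd_h = 1,
                             egg_dev_mean_h = 12, egg_dev_sd_h = 1.5,
                             egg_mortality_prob = 0,
                             adult_hazard_h = 0,
                             male_egg_prob = 0.02,
                             monitor_rule = "k_neonates",
                             monitor_k = 4,
                             monitor_hours = Inf,
                             body_length_um = 230, body_length_sd_um = 12,
                             body_width_um = 150, body_width_sd_um = 8,
                             egg_length_um = 105, egg_length_sd_um = 5,
                             egg_width_um = 85, egg_width_sd_um = 4,
                             algal_cp_mean = 112, algal_cp_se = 2.6,
                             algal_cp_n = 25,
                             c_per_ind_ug = 0.100,
                             n_per_ind_ug = 0.022,
                             p_per_ind_ug = 0.0026,
                             content_cv = 0.05,
                             growth_rate_d = 0.72,
                             census_sd = 0.10) {
  p <- tibble::tibble(
    treatment = as.character(treatment),
    maturation_mean_h = maturation_mean_h, maturation_sd_h = maturation_sd_h,
    inter_egg_mean_h = inter_egg_mean_h, inter_egg_sd_h = inter_egg_sd_h,
    egg_dev_mean_h = egg_dev_mean_h, egg_dev_sd_h = egg_dev_sd_h,
    egg_mortality_prob = egg_mortality_prob,
    adult_hazard_h = adult_hazard_h,
    male_egg_prob = male_egg_prob,
    monitor_rule = monitor_rule,
    monitor_k = monitor_k,
    monitor_hours = monitor_hours,
    body_length_um = body_length_um, body_length_sd_um = body_length_sd_um,
    body_width_um = body_width_um, body_width_sd_um = body_width_sd_um,
    egg_length_um = egg_length_um, egg_length_sd_um = egg_length_sd_um,
    egg_width_um = egg_width_um, egg_width_sd_um = egg_width_sd_um,
    algal_cp_mean = algal_cp_mean, algal_cp_se = algal_cp_se,
    algal_cp_n = algal_cp_n,
    c_per_ind_ug = c_per_ind_ug, n_per_ind_ug = n_per_ind_ug,
    p_per_ind_ug = p_per_ind_ug, content_cv = content_cv,
    growth_rate_d = growth_rate_d, census_sd = census_sd
  )
  validate_params(p)
  p
}

#' Default three-treatment parameter table
#'
#' Parameters for the canonical HP / LP / LP+P design. Algal C:P centres
#' (112, 631, 113 with SEs 2.6, 14.9, 2.7), egg mortality (23.1% in LP,
#' none elsewhere), adult mortality ordering, and the monitoring rules
#' (fourth neonate in HP and LP+P, a fixed 62-h horizon in LP) follow the
#' feeding-trial design the package targets. Trait means are not published
#' numerically for that trial, so the defaults are plausible values for
#' *Brachionus calyciflorus* at 23 degrees C chosen to reproduce the
#' qualitative ordering HP fastest, LP+P intermediate, LP slowest.
#'
#' @return A three-row parameter tibble (one row per treatment).
#' @export
#' @examples
#' default_params()[, 1:6]
default_params <- function() {
  dplyr::bind_rows(
    treatment_params("HP",
      maturation_mean_h = 16, inter_egg_mean_h = 5, egg_dev_mean_h = 12,
      egg_mortality_prob = 0, adult_hazard_h = 0,
      body_length_um = 230, body_width_um = 150,
      egg_length_um = 105, egg_width_um = 85,
      algal_cp_mean = 112, algal_cp_se = 2.6,
      c_per_ind_ug = 0.100, p_per_ind_ug = 0.0026,
      growth_rate_d = 0.72
    ),
    treatment_params("LP",
      maturation_mean_h = 28, maturation_sd_h = 3,
      inter_egg_mean_h = 14, inter_egg_sd_h = 2,
      egg_dev_mean_h = 14.7, egg_dev_sd_h = 1.8,
      egg_mortality_prob = 0.231, adult_hazard_h = 0.0013,
      monitor_rule = "fixed_hours", monitor_hours = 62,
      body_length_um = 212, body_width_um = 138,
      egg_length_um = 119, egg_width_um = 95,
      algal_cp_mean = 631, algal_cp_se = 14.9,
      c_per_ind_ug = 0.069, n_per_ind_ug = 0.016, p_per_ind_ug = 0.00084,
      growth_rate_d = 0.45
    ),
    treatment_params("LP+P",
      maturation_mean_h = 19, maturation_sd_h = 2.2,
      inter_egg_mean_h = 7.5, inter_egg_sd_h = 1.3,
      egg_dev_mean_h = 14.5, egg_dev_sd_h = 1.8,
      egg_mortality_prob = 0, adult_hazard_h = 0.0004,
      body_length_um = 228, body_width_um = 149,
      egg_length_um = 118, egg_width_um = 94,
      algal_cp_mean = 113, algal_cp_se = 2.7,
      c_per_ind_ug = 0.115, n_per_ind_ug = 0.024, p_per_ind_ug = 0.0028,
      growth_rate_d = 0.59
    )
  )
}

#' Experimental design configuration
#'
#' Dimensions and monitoring resolution of the trial. The defaults mirror
#' the canonical design: a life table of 3 treatments x 5 chemostat
#' replicates x 15 individuals (225 units) checked every 2 h, a shortened
#' morphometric cohort of 5 individuals per replicate (75 units), a census
#' experiment of 3 clones x 3 treatments x 5 replicates (45 units) scored
#' daily for 22 days and reseeded with 10 individuals per transfer, and an
#' elemental cohort of 2 clones x 3 treatments x 5 replicates.
#'
#' @param n_clones Clones in the census experiment.
#' @param n_replicates Chemostat replicates per treatment (the true unit of
#'   replication).
#' @param n_individuals Individuals per replicate in the life table.
#' @param n_morpho_individuals Individuals per replicate in the shortened
#'   morphometric cohort.
#' @param obs_interval_h Monitoring interval of the life table (hours).
#' @param census_days Number of scored days per census unit.
#' @param census_seed_count Individuals transferred at each daily reseed.
#' @param cp_occasions Algal C:P sampling occasions per replicate.
#' @param n_clones_elemental Clones in the elemental composition cohort.
#' @param clone_labels Labels used for census clones.
#' @param life_table_clone Clone used for the single-clone life table.
#'
#' @return A list with class `design_config`.
#' @export
#' @examples
#' design_config()
design_config <- function(n_clones = 3,
                          n_replicates = 5,
                          n_individuals = 15,
                          n_morpho_individuals = 5,
                          obs_interval_h = 2,
                          census_days = 22,
                          census_seed_count = 10,
                          cp_occasions = 5,
                          n_clones_elemental = 2,
                          clone_labels = c("D12", "D61", "E1"),
                          life_table_clone = "D12") {
  design <- structure(
    list(
      n_clones = as.integer(n_clones),
      n_replicates = as.integer(n_replicates),
      n_individuals = as.integer(n_individuals),
      n_morpho_individuals = as.integer(n_morpho_individuals),
      obs_interval_h = obs_interval_h,
      census_days = as.integer(census_days),
      census_seed_count = as.integer(census_seed_count),
      cp_occasions = as.integer(cp_occasions),
      n_clones_elemental = as.integer(n_clones_elemental),
      clone_labels = as.character(clone_labels),
      life_table_clone = as.character(life_table_clone)
    ),
    class = "design_config"
  )
  validate_design(design)
  design
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf(
    "  life table : %d trt x %d reps x %d ind (checked every %g h)\n",
    NA_integer_, x$n_replicates, x$n_individuals, x$obs_interval_h
  ))
  cat(sprintf(
    "  census     : %d clones x %d reps, %d days, reseed %d\n",
    x$n_clones, x$n_replicates, x$census_days, x$census_seed_count
  ))
  cat(sprintf(
    "  morphometry: %d ind/rep; elemental: %d clones; C:P occasions: %d\n",
    x$n_morpho_individuals, x$n_clones_elemental, x$cp_occasions
  ))
  invisible(x)
}

validate_params <- function(params) {
  stopifnot(is.data.frame(params), nrow(params) >= 1)
  probs <- c("egg_mortality_prob", "adult_hazard_h", "male_egg_prob")
  for (col in probs) {
    if (any(params[[col]] < 0 | params[[col]] > 1)) {
      abort(sprintf("`%s` must lie in [0, 1].", col), class = "stoichdemo_config_error")
    }
  }
  pos <- c(
    "maturation_mean_h", "inter_egg_mean_h", "egg_dev_mean_h",
    "body_length_um", "body_width_um", "egg_length_um", "egg_width_um",
    "algal_cp_mean"
  )
  for (col in pos) {
    if (any(!is.finite(params[[col]]) | params[[col]] <= 0)) {
      abort(sprintf("`%s` must be strictly positive.", col), class = "stoichdemo_config_error")
    }
  }
  nonneg <- c(
    "maturation_sd_h", "inter_egg_sd_h", "egg_dev_sd_h", "algal_cp_se",
    "content_cv", "census_sd", "c_per_ind_ug", "n_per_ind_ug", "p_per_ind_ug"
  )
  for (col in nonneg) {
    if (any(params[[col]] < 0)) {
      abort(sprintf("`%s` must be non-negative.", col), class = "stoichdemo_config_error")
    }
  }
  bad_rule <- !params$monitor_rule %in% c("k_neonates", "fixed_hours")
  if (any(bad_rule)) {
    abort("`monitor_rule` must be 'k_neonates' or 'fixed_hours'.",
      class = "stoichdemo_config_error"
    )
  }
  if (anyDuplicated(params$treatment)) {
    abort("Duplicate treatment labels in parameter table.",
      class = "stoichdemo_config_error"
    )
  }
  invisible(params)
}

validate_design <- function(design) {
  counts <- c(
    "n_clones", "n_replicates", "n_individuals", "n_morpho_individuals",
    "census_seed_count", "cp_occasions", "n_clones_elemental"
  )
  for (col in counts) {
    if (is.na(design[[col]]) || design[[col]] < 1) {
      abort(sprintf("`%s` must be a count >= 1.", col), class = "stoichdemo_config_error")
    }
  }
  if (!is.finite(design$obs_interval_h) || design$obs_interval_h <= 0) {
    abort("`obs_interval_h` must be > 0.", class = "stoichdemo_config_error")
  }
  if (is.na(design$census_days) || design$census_days < 2) {
    abort("`census_days` must be >= 2.", class = "stoichdemo_config_error")
  }
  if (length(design$clone_labels) < design$n_clones) {
    abort("Not enough `clone_labels` for `n_clones`.", class = "stoichdemo_config_error")
  }
  invisible(design)
}

params_for <- function(params, treatment) {
  row <- params[params$treatment == treatment, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown treatment label '%s'.", treatment),
      class = "stoichdemo_config_error"
    )
  }
  row
}
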