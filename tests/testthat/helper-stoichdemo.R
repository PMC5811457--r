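# Shared fixtures, all built in code.

# one-treatment parameter row with every stochastic dial exposed
one_treatment <- function(label = "HP", ...) {
  treatment_params(label, ...)
}

# a parameter table with no randomness at all: every latent time equals its
# mean, nobody dies, no male eggs
noiseless_params <- function(label = "HP",
                             maturation_mean_h = 15.5,
                             inter_egg_mean_h = 5.3,
                             egg_dev_mean_h = 12.4, ...) {
  treatment_params(label,
    maturation_mean_h = maturation_mean_h, maturation_sd_h = 0,
    inter_egg_mean_h = inter_egg_mean_h, inter_egg_sd_h = 0,
    egg_dev_mean_h = egg_dev_mean_h, egg_dev_sd_h = 0,
    egg_mortality_prob = 0, adult_hazard_h = 0, male_egg_prob = 0,
    body_length_sd_um = 0, body_width_sd_um = 0,
    egg_length_sd_um = 0, egg_width_sd_um = 0,
    algal_cp_se = 0, content_cv = 0, census_sd = 0, ...
  )
}

tiny_design <- function(...) {
  design_config(n_replicates = 1, n_individuals = 1, n_clones = 1, ...)
}

# build a valid event log row-by-row for hand-computed examples;
# each ... argument is c(event_type, time, egg_index or NA)
hand_log <- function(individual_id, events,
                     treatment = "HP", chemostat_replicate = "R1",
                     clone = "D12") {
  purrr::map(events, function(e) {
    tibble::tibble(
      individual_id = individual_id,
      clone = clone, treatment = treatment,
      chemostat_replicate = chemostat_replicate,
      event_type = as.character(e[[1]]),
      event_time_h = as.numeric(e[[2]]),
      egg_index = if (length(e) > 2) as.integer(e[[3]]) else NA_integer_
    )
  }) |>
    purrr::list_rbind()
}

# mean of ceil(X / w) * w for X ~ Normal(mean, sd) truncated at 0; the
# analytic expectation of a grid-rounded latent time, used as an
# independent oracle for parameter recovery
expected_grid_mean <- function(mean, sd, w, kmax = 1000) {
  if (sd == 0) {
    return(ceiling(mean / w) * w)
  }
  k <- seq_len(kmax)
  upper <- pnorm((k * w - mean) / sd)
  lower <- pnorm(((k - 1) * w - mean) / sd)
  p0 <- pnorm((0 - mean) / sd) # mass below 0 is rejected and redrawn
  sum(k * w * (upper - lower)) / (1 - p0)
}
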