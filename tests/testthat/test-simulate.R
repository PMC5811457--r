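test_that("record counts equal the product of design dimensions", {
  log <- simulate_individuals(design_config(), default_params(), seed = 11)
  expect_equal(dplyr::n_distinct(log$individual_id), 225)
  per_cell <- log |>
    dplyr::distinct(individual_id, treatment, chemostat_replicate) |>
    dplyr::count(treatment, chemostat_replicate)
  expect_true(all(per_cell$n == 15))

  small <- simulate_individuals(
    design_config(n_replicates = 2, n_individuals = 3),
    default_params(),
    seed = 11
  )
  expect_equal(dplyr::n_distinct(small$individual_id), 3 * 2 * 3)
})

test_that("unknown treatments and bad design dimensions are rejected", {
  expect_error(design_config(n_individuals = 0), class = "stoichdemo_config_error")
  expect_error(design_config(census_days = 1), class = "stoichdemo_config_error")
  expect_error(
    treatment_params("HP", egg_mortality_prob = 1.2),
    class = "stoichdemo_config_error"
  )
  expect_error(
    params_for(default_params(), "XX"),
    class = "stoichdemo_config_error"
  )
})

test_that("a noiseless individual is observed at its latent means rounded up to the grid", {
  p <- noiseless_params(maturation_mean_h = 15.5, inter_egg_mean_h = 5.3,
                        egg_dev_mean_h = 12.4)
  log <- simulate_individuals(tiny_design(), p, seed = 1)

  w <- 2
  lay_latent <- 15.5 + 5.3 * (0:5)
  hatch_latent <- lay_latent + 12.4
  lay_obs <- ceiling(lay_latent / w) * w
  hatch_obs <- ceiling(hatch_latent / w) * w
  end <- sort(hatch_obs)[4] # monitoring ends at the 4th hatched neonate

  lays <- log$event_time_h[log$event_type == "egg_laid"]
  hatches <- log$event_time_h[log$event_type == "egg_hatched"]
  expect_equal(lays, lay_obs[lay_obs <= end])
  expect_equal(hatches, hatch_obs[hatch_obs <= end])
  expect_equal(max(log$event_time_h), end)
  expect_equal(utils::tail(log$event_type, 1), "censored")
  # identical under a different seed: nothing is random
  expect_identical(log, simulate_individuals(tiny_design(), p, seed = 99))
})

test_that("observed egg-death fraction matches the configured probability at large n", {
  p <- one_treatment("LP",
    maturation_mean_h = 18, maturation_sd_h = 2,
    inter_egg_mean_h = 4, inter_egg_sd_h = 0.5,
    egg_dev_mean_h = 10, egg_dev_sd_h = 1,
    egg_mortality_prob = 0.231, adult_hazard_h = 0, male_egg_prob = 0,
    monitor_rule = "fixed_hours", monitor_hours = 80
  )
  log <- simulate_individuals(
    design_config(n_replicates = 1, n_individuals = 900),
    p,
    seed = 7
  )
  died <- sum(log$event_type == "egg_died")
  resolved <- died + sum(log$event_type == "egg_hatched")
  expect_gt(resolved, 10000)
  se <- sqrt(0.231 * (1 - 0.231) / resolved)
  expect_lt(abs(died / resolved - 0.231), 3 * se)
})

test_that("the generator is deterministic and unit substreams are subset-stable", {
  d <- design_config(n_replicates = 3, n_individuals = 4)
  a <- simulate_individuals(d, default_params(), seed = 5)
  b <- simulate_individuals(d, default_params(), seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_individuals(d, default_params(), seed = 6)))

  # shrinking the design leaves a retained unit's data unchanged
  small <- simulate_individuals(
    design_config(n_replicates = 1, n_individuals = 4),
    default_params(),
    seed = 5
  )
  kept <- dplyr::filter(a, chemostat_replicate == "R1")
  expect_identical(
    dplyr::arrange(kept, individual_id, event_time_h),
    dplyr::arrange(small, individual_id, event_time_h)
  )

  cen_a <- simulate_census(d, default_params(), seed = 5)
  expect_identical(cen_a, simulate_census(d, default_params(), seed = 5))
})

test_that("event logs satisfy the structural invariants", {
  log <- simulate_individuals(
    design_config(n_replicates = 2, n_individuals = 10),
    default_params(),
    seed = 3
  )
  w <- 2
  expect_true(all(abs(log$event_time_h / w - round(log$event_time_h / w)) < 1e-9))
  # no egg hatches before it is laid
  dev <- egg_development(log)
  expect_true(all(dev$development_h >= 0))
  # no event beyond the terminal death/censoring row
  ends <- log |>
    dplyr::filter(event_type %in% c("death", "censored")) |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(end = max(event_time_h), n_terminal = dplyr::n())
  expect_true(all(ends$n_terminal == 1))
  joined <- dplyr::left_join(log, ends, by = "individual_id")
  expect_true(all(joined$event_time_h <= joined$end))
  # validator agrees
  expect_equal(nrow(validate_event_log(log)), 0)
})

test_that("monitoring rules end records where the design says", {
  log <- simulate_individuals(design_config(), default_params(), seed = 21)
  ind <- individual_summaries(log)
  lp <- dplyr::filter(ind, treatment == "LP")
  expect_true(all(lp$end_time_h <= 62))
  expect_true(all(lp$end_reason != "completed_k_neonates"))
  hp_done <- dplyr::filter(ind, treatment == "HP", end_reason == "completed_k_neonates")
  expect_gt(nrow(hp_done), 0)
  expect_true(all(hp_done$n_hatched >= 4))
  # male-egg producers are censored at the male egg
  males <- dplyr::filter(ind, end_reason == "censored_male_egg")
  if (nrow(males) > 0) {
    male_events <- log |>
      dplyr::filter(event_type == "male_egg") |>
      dplyr::group_by(individual_id) |>
      dplyr::summarise(t = max(event_time_h))
    j <- dplyr::inner_join(males, male_events, by = "individual_id")
    expect_equal(j$end_time_h, j$t)
  }
})

test_that("census design count, degenerate series and rate recovery behave", {
  cen <- simulate_census(design_config(), default_params(), seed = 2)
  expect_equal(dplyr::n_distinct(cen$unit_id), 45)
  expect_true(all(dplyr::count(cen, unit_id)$n == 22))

  flat <- one_treatment("HP", growth_rate_d = 0, census_sd = 0)
  cen0 <- simulate_census(design_config(n_clones = 1), flat, seed = 2)
  expect_true(all(cen0$n_end == cen0$n_start))
  expect_true(all(census_growth_rate(cen0)$r_d == 0))

  p <- one_treatment("HP", growth_rate_d = 0.5, census_sd = 0.1)
  cen5 <- simulate_census(
    design_config(n_clones = 1, n_replicates = 5, census_days = 22), p,
    seed = 13
  )
  rates <- census_growth_rate(cen5, window = c(7, 22))$r_d
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.5), 3 * se)
})

test_that("composition tables have the design shape and calibrated C:P", {
  tabs <- simulate_composition(design_config(), default_params(), seed = 4)
  expect_equal(nrow(tabs$morphometry), 75)
  expect_equal(nrow(tabs$elemental), 2 * 3 * 5)
  expect_equal(nrow(tabs$algal_cp), 3 * 5 * 5)

  frozen <- noiseless_params("HP", algal_cp_mean = 112)
  t0 <- simulate_composition(design_config(n_clones = 1), frozen, seed = 4)
  expect_true(all(t0$algal_cp$cp_molar == 112))

  hp <- dplyr::filter(tabs$algal_cp, treatment == "HP")
  expect_equal(nrow(hp), 25)
  se <- stats::sd(hp$cp_molar) / sqrt(nrow(hp))
  expect_lt(abs(mean(hp$cp_molar) - 112), 3 * se)
})
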