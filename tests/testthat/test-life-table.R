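test_that("survivorship and fecundity follow hand counts", {
  # 10 individuals, none die, each hatches one neonate in age class 5
  log <- purrr::map(1:10, function(i) {
    hand_log(sprintf("I%02d", i), list(
      list("hatch", 0), list("egg_laid", 2, 1),
      list("egg_hatched", 10, 1), list("censored", 10)
    ))
  }) |>
    purrr::list_rbind()
  sched <- build_schedule(log, age_class_width = 2)
  expect_equal(sched$lx, rep(1, 5))
  expect_equal(sched$mx, c(0, 0, 0, 0, 1))

  # 4 individuals, one dies entering class 3 (death recorded at the 4-h check)
  log2 <- dplyr::bind_rows(
    hand_log("A", list(list("hatch", 0), list("death", 4))),
    purrr::map(c("B", "C", "D"), function(i) {
      hand_log(i, list(list("hatch", 0), list("censored", 8)))
    }) |> purrr::list_rbind()
  )
  sched2 <- build_schedule(log2, age_class_width = 2)
  expect_equal(sched2$lx, c(1, 1, 0.75, 0.75))
})

test_that("lx stays monotone and bounded under heavy censoring", {
  p <- one_treatment("HP",
    adult_hazard_h = 0.01, male_egg_prob = 0.25,
    egg_mortality_prob = 0.2
  )
  log <- simulate_individuals(
    design_config(n_replicates = 3, n_individuals = 20), p,
    seed = 17
  )
  for (rep_id in unique(log$chemostat_replicate)) {
    sched <- build_schedule(dplyr::filter(log, chemostat_replicate == rep_id))
    expect_true(all(diff(sched$lx) <= 1e-12))
    expect_true(all(sched$lx >= 0 & sched$lx <= 1))
    expect_true(all(sched$mx >= 0))
    expect_equal(sched$lx[1], 1)
  }
})

test_that("halving the age class width preserves total reproductive output", {
  log <- simulate_individuals(
    design_config(n_replicates = 2, n_individuals = 15),
    default_params(),
    seed = 23
  )
  hp <- dplyr::filter(log, treatment == "HP")
  s2 <- build_schedule(hp, age_class_width = 2)
  s1 <- build_schedule(hp, age_class_width = 1)
  expect_equal(sum(s1$mx * s1$n_risk), sum(s2$mx * s2$n_risk))
  expect_equal(sum(s2$mx * s2$n_risk), sum(hp$event_type == "egg_hatched"))
})

test_that("noiseless cohorts reproduce the generator's maturation class exactly", {
  p <- noiseless_params(maturation_mean_h = 15.5, egg_dev_mean_h = 12.4)
  log <- simulate_individuals(
    design_config(n_replicates = 1, n_individuals = 200), p,
    seed = 2
  )
  traits <- extract_traits(log)
  expect_true(all(traits$age_first_egg_h == 16))
  sched <- build_schedule(log)
  first_repro_class <- min(which(sched$mx > 0))
  # first neonates hatch at ceil((15.5 + 12.4) / 2) * 2 = 28 h -> class 14
  expect_equal(first_repro_class, 14)
})

test_that("trait extraction follows the stated arithmetic", {
  log <- hand_log("A", list(
    list("hatch", 0), list("egg_laid", 20, 1), list("egg_laid", 30, 2),
    list("censored", 34)
  ))
  tr <- extract_traits(log)
  expect_equal(tr$age_first_egg_h, 20)
  expect_equal(tr$egg_production_rate_h, 2 / 10)

  single <- hand_log("B", list(
    list("hatch", 0), list("egg_laid", 20, 1), list("censored", 30)
  ))
  expect_true(is.na(extract_traits(single)$egg_production_rate_h))

  four <- hand_log("C", list(
    list("hatch", 0), list("egg_laid", 20, 1), list("egg_laid", 26, 2),
    list("egg_laid", 32, 3), list("egg_laid", 38, 4), list("censored", 40)
  ))
  expect_equal(extract_traits(four)$egg_production_rate_h, 4 / 18)

  # development time is hatch minus lay, per egg
  dev <- hand_log("D", list(
    list("hatch", 0), list("egg_laid", 10, 1), list("egg_hatched", 24, 1),
    list("censored", 24)
  ))
  expect_equal(extract_traits(dev)$first_egg_dev_h, 14)
})

test_that("mortality proportions use resolved-fate denominators", {
  # 75 individuals, 6 deaths -> 8.0%
  log <- purrr::map(1:75, function(i) {
    if (i <= 6) {
      hand_log(sprintf("I%02d", i), list(list("hatch", 0), list("death", 10)),
        treatment = "LP"
      )
    } else {
      hand_log(sprintf("I%02d", i), list(list("hatch", 0), list("censored", 62)),
        treatment = "LP"
      )
    }
  }) |>
    purrr::list_rbind()
  ms <- mortality_summary(log)
  expect_equal(ms$individual_mortality_pct, 8.0)
  expect_true(is.na(ms$egg_mortality_pct)) # no resolved eggs

  # male and unresolved eggs are excluded from the egg-mortality denominator
  log2 <- hand_log("A", list(
    list("hatch", 0), list("egg_laid", 10, 1), list("egg_died", 20, 1),
    list("egg_laid", 16, 2), list("egg_hatched", 28, 2),
    list("egg_laid", 22, 3), # unresolved
    list("male_egg", 28, 4), list("censored", 28)
  ))
  ms2 <- mortality_summary(log2)
  expect_equal(ms2$eggs_resolved, 2)
  expect_equal(ms2$egg_mortality_pct, 50.0)
})

test_that("no deaths gives exactly zero percent mortality", {
  log <- simulate_individuals(
    design_config(n_replicates = 1, n_individuals = 10),
    noiseless_params(),
    seed = 1
  )
  expect_equal(mortality_summary(log)$individual_mortality_pct, 0)
})
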