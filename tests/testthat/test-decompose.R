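test_that("the egg-mortality contrast decomposes on survival", {
  res <- decompose_effects(0, 0, 0.231, trait = "egg mortality", mortality = TRUE)
  expect_equal(res$indirect_pct, 0)
  expect_equal(res$direct_pct, -23.1)
  expect_equal(classify_scenario(res$indirect_pct, res$direct_pct, 1), "I")
})

test_that("relative differences use the stated baselines", {
  res <- decompose_effects(0.80, 0.66, 0.495)
  expect_equal(res$indirect_pct, -17.5)
  expect_equal(res$direct_pct, -25.0)
  expect_equal(res$scenario, "II")
  # equal LP+P and HP means give an exactly zero indirect component
  expect_equal(decompose_effects(0.8, 0.8, 0.5)$indirect_pct, 0)
  expect_equal(decompose_effects(0.8, 0.5, 0.5)$direct_pct, 0)
})

test_that("scenario classification separates direct, indirect and joint control", {
  expect_equal(classify_scenario(0, -23.1, tolerance_pct = 1), "I")
  expect_equal(classify_scenario(-17.5, -25.0), "II")
  expect_equal(classify_scenario(36.2, 2.9, tolerance_pct = 5), "III")
  expect_equal(classify_scenario(1, -2), "none")
  expect_true(is.na(classify_scenario(NA_real_, 3)))
})

test_that("compounding and exact-zero identities hold on random mean triples", {
  withr::local_seed(5)
  for (i in 1:200) {
    m <- runif(3, 0.05, 10)
    res <- suppressWarnings(decompose_effects(m[1], m[2], m[3]))
    expect_equal(
      (1 + res$indirect_pct / 100) * (1 + res$direct_pct / 100),
      m[3] / m[1],
      tolerance = 1e-12
    )
  }
  # sign coherence: benefit ordering HP >= LP+P >= LP gives negative components
  ordered <- decompose_effects(1.0, 0.8, 0.6)
  expect_lte(ordered$indirect_pct, 0)
  expect_lte(ordered$direct_pct, 0)
})

test_that("zero reference means are flagged, not fabricated", {
  expect_warning(res <- decompose_effects(0, 1, 2), "Zero reference")
  expect_true(is.na(res$indirect_pct))
  expect_error(
    decompose_effects(0.5, 0.2, 1.3, mortality = TRUE),
    class = "stoichdemo_domain_error"
  )
})

test_that("replicate bootstrap is deterministic and degenerates correctly", {
  flat <- tibble::tibble(
    treatment = rep(c("HP", "LP", "LP+P"), each = 3),
    value = rep(c(1.0, 0.5, 0.8), each = 3)
  )
  res <- decompose_replicates(flat, n_boot = 200, seed = 3)
  expect_equal(res$indirect_lo, res$indirect_pct)
  expect_equal(res$indirect_hi, res$indirect_pct)
  expect_equal(res$direct_lo, res$direct_pct)

  noisy <- tibble::tibble(
    treatment = rep(c("HP", "LP", "LP+P"), each = 5),
    value = c(1, 1.1, 0.9, 1.05, 0.95, 0.5, 0.55, 0.45, 0.52, 0.48, 0.8, 0.82, 0.78, 0.81, 0.79)
  )
  a <- decompose_replicates(noisy, n_boot = 300, seed = 8)
  b <- decompose_replicates(noisy, n_boot = 300, seed = 8)
  expect_identical(a, b)
  expect_lt(a$indirect_lo, a$indirect_pct)
  expect_gt(a$indirect_hi, a$indirect_pct)

  expect_error(
    decompose_replicates(flat[c(1, 4, 7), ], n_boot = 200),
    class = "stoichdemo_domain_error"
  )
  expect_error(
    decompose_replicates(noisy, n_boot = 50),
    class = "stoichdemo_config_error"
  )
})

test_that("bootstrap interval coverage approaches nominal on simulated replicates", {
  # known truth: replicate means around (1, 0.8, 0.5) with sd 0.08, so the
  # true indirect component is -20%. Percentile intervals resampled from
  # few replicates undercover by O(1/n); at 15 replicates per treatment the
  # coverage should sit between that small-sample deficit and 1, within
  # binomial Monte-Carlo error at 200 simulations.
  withr::local_seed(42)
  true_ind <- 100 * (0.8 - 1) / 1
  n_sim <- 200
  hits <- 0
  for (s in 1:n_sim) {
    d <- tibble::tibble(
      treatment = rep(c("HP", "LP+P", "LP"), each = 15),
      value = rnorm(45, rep(c(1, 0.8, 0.5), each = 15), 0.08)
    )
    res <- decompose_replicates(d, n_boot = 199, seed = s)
    if (res$indirect_lo <= true_ind && true_ind <= res$indirect_hi) {
      hits <- hits + 1
    }
  }
  coverage <- hits / n_sim
  se <- sqrt(0.95 * 0.05 / n_sim)
  expect_gt(coverage, 0.95 - 0.05 - 3 * se)
  expect_lte(coverage, 1)
})

test_that("tidy() reshapes a decomposition into contrast rows", {
  res <- decompose_effects(0.80, 0.66, 0.495, trait = "growth")
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_setequal(td$component, c("indirect", "direct"))
  expect_equal(td$contrast[td$component == "indirect"], "(LP+P)-HP")
  expect_equal(
    td$relative_difference_pct[td$component == "direct"],
    res$direct_pct
  )
})
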