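test_that("single-age schedules match the closed form r = ln(m)/T", {
  for (m in c(0.5, 1, 2, 4)) {
    for (T_d in c(0.5, 1, 2)) {
      sched <- tibble::tibble(x_h = T_d * 24, lx = 1, mx = m)
      fit <- euler_lotka_r(sched)
      expect_lt(abs(fit$r_d - log(m) / T_d), 1e-8)
      expect_lt(fit$residual, 1e-8)
    }
  }
})

test_that("the sign of r follows the net reproductive rate", {
  r0_1 <- euler_lotka_r(tibble::tibble(x_h = 24, lx = 1, mx = 1))
  expect_lt(abs(r0_1$r_d), 1e-8)
  grow <- euler_lotka_r(tibble::tibble(x_h = c(24, 48), lx = c(1, 0.5), mx = c(1, 1)))
  expect_gt(grow$r_d, 0)
  shrink <- euler_lotka_r(tibble::tibble(x_h = c(24, 48), lx = c(1, 0.5), mx = c(0.4, 0.4)))
  expect_lt(shrink$r_d, 0)
  expect_error(
    euler_lotka_r(tibble::tibble(x_h = 24, lx = 1, mx = 0)),
    class = "stoichdemo_no_reproduction_error"
  )
})

test_that("bisection agrees with an independent root finder on random schedules", {
  withr::local_seed(101)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    x_d <- sort(runif(n, 0.2, 6))
    lx <- cumprod(c(1, runif(n - 1, 0.7, 1)))
    mx <- rbinom(n, 1, 0.6) * runif(n, 0, 2)
    if (sum(lx * mx) == 0) mx[n] <- 1
    sched <- tibble::tibble(x_h = x_d * 24, lx = lx, mx = mx)
    fit <- euler_lotka_r(sched, tol = 1e-12)
    f <- function(r) sum(lx * mx * exp(-r * x_d)) - 1
    oracle <- stats::uniroot(f, c(-50, 50), tol = 1e-14)$root
    expect_lt(abs(fit$r_d - oracle), 1e-8)
    expect_lt(abs(f(fit$r_d)), 1e-10)
  }
})

test_that("r is monotone in fecundity and in reproductive timing", {
  withr::local_seed(7)
  for (i in 1:20) {
    x_d <- sort(runif(5, 0.5, 4))
    lx <- cumprod(c(1, runif(4, 0.8, 1)))
    mx <- runif(5, 0.2, 1.5)
    sched <- tibble::tibble(x_h = x_d * 24, lx = lx, mx = mx)
    r0 <- euler_lotka_r(sched)$r_d
    # increasing any mx entry never decreases r
    j <- sample(5, 1)
    up <- sched
    up$mx[j] <- up$mx[j] + 0.5
    expect_gte(euler_lotka_r(up)$r_d, r0 - 1e-12)
    # delaying reproduction never increases r when R0 > 1
    if (sum(lx * mx) > 1) {
      late <- sched
      late$x_h <- late$x_h + 12
      expect_lte(euler_lotka_r(late)$r_d, r0 + 1e-12)
    }
  }
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- euler_lotka_r(tibble::tibble(x_h = 24, lx = 1, mx = 2))
  td <- tidy(fit)
  expect_equal(td$term, "r")
  expect_equal(td$estimate, log(2), tolerance = 1e-8)
  gl <- glance(fit)
  expect_named(
    gl,
    c("r_d", "R0", "generation_days", "residual", "iterations", "n_classes")
  )
  expect_equal(gl$R0, 2)
})

test_that("census growth rates follow the daily log-ratio definition", {
  one <- tibble::tibble(
    unit_id = "u", clone = "D12", treatment = "HP",
    chemostat_replicate = "R1",
    day = 1:2, n_start = c(10L, 10L), n_end = c(20L, 20L)
  )
  expect_equal(census_growth_rate(one, window = c(1, 2))$r_d, log(2))

  flat <- dplyr::mutate(one, n_end = n_start)
  expect_equal(census_growth_rate(flat, window = c(1, 2))$r_d, 0)

  # brute-force re-summation oracle over the default window
  cen <- simulate_census(design_config(n_clones = 1, n_replicates = 1),
    default_params(),
    seed = 31
  )
  got <- census_growth_rate(cen, window = c(7, 22))
  for (u in unique(cen$unit_id)) {
    d <- cen[cen$unit_id == u & cen$day >= 7 & cen$day <= 22, ]
    expect_equal(
      got$r_d[got$unit_id == u],
      mean(log(d$n_end) - log(d$n_start))
    )
  }

  # scale invariance
  scaled <- dplyr::mutate(cen, n_start = n_start * 7L, n_end = n_end * 7L)
  expect_equal(census_growth_rate(scaled)$r_d, got$r_d)

  # zero end counts are excluded and counted
  z <- one
  z$n_end[2] <- 0L
  gz <- census_growth_rate(z, window = c(1, 2))
  expect_equal(gz$n_excluded, 1L)
  expect_equal(gz$r_d, log(2))

  expect_error(
    census_growth_rate(cen, window = c(7, 30)),
    class = "stoichdemo_config_error"
  )
})

test_that("intrinsic rates flag horizon-truncated groups", {
  log <- simulate_individuals(
    design_config(n_replicates = 2, n_individuals = 8),
    default_params(),
    seed = 9
  )
  r <- intrinsic_rates(log)
  expect_true(all(r$residual <= 1e-10))
  expect_true(all(r$truncated[r$treatment == "LP"]))
  expect_false(any(r$truncated[r$treatment == "HP"]))
  # ordering of the design is recovered: HP fastest, LP slowest
  means <- tapply(r$r_d, r$treatment, mean)
  expect_gt(means[["HP"]], means[["LP+P"]])
  expect_gt(means[["LP+P"]], means[["LP"]])
})
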