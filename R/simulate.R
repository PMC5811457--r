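# Individual-based generator for the three-arm P-supplementation design.
# Every experimental unit gets its own RNG substream derived from the master
# seed and a stable hash of the unit's identity, so shrinking the design
# never changes the data of a retained unit.

# deterministic 31-adic string hash, kept below 2^31 - 1
stable_hash <- function(...) {
  s <- paste(c(...), collapse = "\r")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

with_unit_seed <- function(master_seed, id_parts, expr) {
  sub_seed <- (stable_hash(id_parts) + as.integer(master_seed) %% 2147483647) %% 2147483647
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed)
  force(expr)
}

# Gaussian truncated at zero by rejection; degenerates to the mean at sd = 0
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(mean, n))
  }
  out <- rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  out
}

# round a latent time up to the next monitoring check
grid_ceiling <- function(t, w) ceiling(t / w - 1e-9) * w

event_log_columns <- c(
  "individual_id", "clone", "treatment", "chemostat_replicate",
  "event_type", "event_time_h", "egg_index"
)

event_types <- c(
  "hatch", "egg_laid", "egg_hatched", "egg_died", "male_egg",
  "death", "censored"
)

#' Simulate individual life-table event logs
#'
#' Generates one interval-censored event log per experimental unit of the
#' life-table design (treatments x chemostat replicates x individuals).
#' Latent maturation, inter-egg and egg-development times are Gaussian
#' around the treatment means (truncated at zero); an event is only
#' discovered at the first monitoring check at or after its true time, so
#' all recorded times are multiples of `obs_interval_h`. Adult death is a
#' per-check Bernoulli hazard; each egg dies before hatching with the
#' treatment's egg mortality probability; a male egg right-censors the
#' individual at its laying. Monitoring ends at the k-th hatched neonate or
#' at the fixed horizon, per the treatment's monitoring rule.
#'
#' @param design A [design_config()].
#' @param params Parameter table with one row per treatment, see
#'   [default_params()].
#' @param seed Master integer seed; identical inputs reproduce identical
#'   output.
#'
#' @return A tibble, one row per observed event, with columns
#'   `individual_id`, `clone`, `treatment`, `chemostat_replicate`,
#'   `event_type` (one of `hatch`, `egg_laid`, `egg_hatched`, `egg_died`,
#'   `male_egg`, `death`, `censored`),
#'   `event_time_h` (age in hours) and `egg_index` (NA for non-egg events).
#'   Every individual starts with a `hatch` row at age 0 and ends with a
#'   `death` or `censored` row.
#' @export
#' @examples
#' log <- simulate_individuals(design_config(n_replicates = 1, n_individuals = 2))
#' dplyr::count(log, event_type)
simulate_individuals <- function(design = design_config(),
                                 params = default_params(),
                                 seed = 1L) {
  validate_design(design)
  validate_params(params)
  units <- tidyr::expand_grid(
    treatment = params$treatment,
    chemostat_replicate = paste0("R", seq_len(design$n_replicates)),
    individual = seq_len(design$n_individuals)
  )
  purrr::pmap(units, function(treatment, chemostat_replicate, individual) {
    p <- params_for(params, treatment)
    id <- paste(treatment, chemostat_replicate, sprintf("I%02d", individual),
      sep = "."
    )
    with_unit_seed(
      seed, c("lifetable", treatment, chemostat_replicate, individual),
      simulate_one_individual(p, design, id)
    )
  }) |>
    purrr::list_rbind()
}

simulate_one_individual <- function(p, design, id) {
  w <- design$obs_interval_h
  p_check <- 1 - (1 - p$adult_hazard_h)^w

  # death observed at the first check after the fatal interval
  death_obs <- if (p_check > 0) (rgeom(1, p_check) + 1) * w else Inf

  horizon <- if (p$monitor_rule == "fixed_hours") p$monitor_hours else Inf
  latent_cap <- min(death_obs, horizon)

  # generate the egg sequence forward in latent time
  lay <- numeric(0)
  male <- logical(0)
  died <- logical(0)
  hatch <- numeric(0)
  t_next <- rtnorm_pos(1, p$maturation_mean_h, p$maturation_sd_h)
  n_hatched_cap <- Inf
  repeat {
    if (t_next > latent_cap) break
    if (p$monitor_rule == "k_neonates" && sum(!male & !died) >= p$monitor_k) {
      # stop once laying passes the k-th observed hatch
      kth <- sort(grid_ceiling(hatch[!male & !died], w))[p$monitor_k]
      if (t_next > kth) break
    }
    is_male <- runif(1) < p$male_egg_prob
    lay <- c(lay, t_next)
    male <- c(male, is_male)
    if (is_male) {
      died <- c(died, FALSE)
      hatch <- c(hatch, NA_real_)
      break
    }
    egg_dies <- runif(1) < p$egg_mortality_prob
    died <- c(died, egg_dies)
    hatch <- c(hatch, t_next + rtnorm_pos(1, p$egg_dev_mean_h, p$egg_dev_sd_h))
    t_next <- t_next + rtnorm_pos(1, p$inter_egg_mean_h, p$inter_egg_sd_h)
    if (length(lay) >= 500) break # safety cap
  }

  lay_obs <- grid_ceiling(lay, w)
  fate_obs <- grid_ceiling(hatch, w)

  # candidate ends of monitoring
  end_candidates <- c(death = death_obs, horizon = horizon)
  if (any(male)) {
    end_candidates["male"] <- lay_obs[which(male)[1]]
  }
  if (p$monitor_rule == "k_neonates") {
    hatch_times <- sort(fate_obs[!male & !died & !is.na(fate_obs)])
    if (length(hatch_times) >= p$monitor_k) {
      end_candidates["k_neonates"] <- hatch_times[p$monitor_k]
    }
  }
  end_time <- min(end_candidates)
  end_what <- names(end_candidates)[which.min(end_candidates)]
  end_event <- if (end_what == "death") "death" else "censored"

  # eggs observed strictly before a death check, up to and including a censor
  keep <- if (end_what == "death") lay_obs < end_time else lay_obs <= end_time
  lay_obs <- lay_obs[keep]
  male <- male[keep]
  died <- died[keep]
  fate_obs <- fate_obs[keep]
  fate_seen <- !male & !is.na(fate_obs) & fate_obs <= end_time

  n_eggs <- length(lay_obs)
  rows <- list(
    tibble::tibble(
      event_type = "hatch", event_time_h = 0, egg_index = NA_integer_
    )
  )
  if (n_eggs > 0) {
    rows <- c(rows, list(tibble::tibble(
      event_type = ifelse(male, "male_egg", "egg_laid"),
      event_time_h = lay_obs,
      egg_index = seq_len(n_eggs)
    )))
    if (any(fate_seen)) {
      rows <- c(rows, list(tibble::tibble(
        event_type = ifelse(died[fate_seen], "egg_died", "egg_hatched"),
        event_time_h = fate_obs[fate_seen],
        egg_index = which(fate_seen)
      )))
    }
  }
  rows <- c(rows, list(tibble::tibble(
    event_type = end_event, event_time_h = end_time, egg_index = NA_integer_
  )))
  out <- purrr::list_rbind(rows)
  out <- out[order(out$event_time_h, match(out$event_type, event_types)), ]
  tibble::tibble(
    individual_id = id,
    clone = design$life_table_clone,
    treatment = p$treatment,
    chemostat_replicate = sub("\\..*$", "", sub("^[^.]*\\.", "", id)),
    out
  )
}

#' Simulate serial-transfer census series
#'
#' Generates daily counts for the population-level growth experiment:
#' every unit is reseeded with `census_seed_count` individuals each day and
#' the end-of-day count is drawn from a lognormal growth model whose
#' expected per-day log-ratio equals the treatment's configured true rate,
#' then rounded to an integer (floored at zero).
#'
#' @inheritParams simulate_individuals
#' @return A tibble with columns `unit_id`, `clone`, `treatment`,
#'   `chemostat_replicate`, `day`, `n_start`, `n_end`; one row per unit and
#'   day, `design$census_days` days per unit.
#' @export
#' @examples
#' cen <- simulate_census(design_config(n_clones = 1, n_replicates = 2))
#' head(cen)
simulate_census <- function(design = design_config(),
                            params = default_params(),
                            seed = 1L) {
  validate_design(design)
  validate_params(params)
  units <- tidyr::expand_grid(
    clone = design$clone_labels[seq_len(design$n_clones)],
    treatment = params$treatment,
    chemostat_replicate = paste0("R", seq_len(design$n_replicates))
  )
  purrr::pmap(units, function(clone, treatment, chemostat_replicate) {
    p <- params_for(params, treatment)
    n0 <- design$census_seed_count
    with_unit_seed(seed, c("census", clone, treatment, chemostat_replicate), {
      eps <- if (p$census_sd > 0) {
        rnorm(design$census_days, 0, p$census_sd)
      } else {
        rep(0, design$census_days)
      }
      tibble::tibble(
        unit_id = paste(clone, treatment, chemostat_replicate, sep = "."),
        clone = clone,
        treatment = treatment,
        chemostat_replicate = chemostat_replicate,
        day = seq_len(design$census_days),
        n_start = as.integer(n0),
        n_end = as.integer(pmax(0, round(n0 * exp(p$growth_rate_d + eps))))
      )
    })
  }) |>
    purrr::list_rbind()
}

#' Simulate morphometric, elemental and algal C:P tables
#'
#' Generates the three composition tables of the design: the shortened
#' morphometric cohort (`n_morpho_individuals` per treatment x replicate,
#' body and first-egg dimensions in micrometres plus the maturation
#' interval), one pooled rotifer elemental sample (150 individuals) per
#' elemental clone x treatment x replicate, and algal molar C:P batches per
#' treatment x replicate x sampling occasion drawn around the treatment
#' centre with sd `algal_cp_se * sqrt(algal_cp_n)`.
#'
#' @inheritParams simulate_individuals
#' @param n_pooled Individuals pooled per elemental sample.
#' @return A list of three tibbles: `morphometry`, `elemental`, `algal_cp`.
#' @export
#' @examples
#' tabs <- simulate_composition(design_config(n_replicates = 2))
#' names(tabs)
simulate_composition <- function(design = design_config(),
                                 params = default_params(),
                                 seed = 1L,
                                 n_pooled = 150L) {
  validate_design(design)
  validate_params(params)
  w <- design$obs_interval_h

  morpho_units <- tidyr::expand_grid(
    treatment = params$treatment,
    chemostat_replicate = paste0("R", seq_len(design$n_replicates)),
    individual = seq_len(design$n_morpho_individuals)
  )
  morphometry <- purrr::pmap(
    morpho_units,
    function(treatment, chemostat_replicate, individual) {
      p <- params_for(params, treatment)
      with_unit_seed(
        seed, c("morpho", treatment, chemostat_replicate, individual),
        tibble::tibble(
          individual_id = paste(treatment, chemostat_replicate,
            sprintf("M%02d", individual),
            sep = "."
          ),
          treatment = treatment,
          chemostat_replicate = chemostat_replicate,
          body_length_um = rtnorm_pos(1, p$body_length_um, p$body_length_sd_um),
          body_width_um = rtnorm_pos(1, p$body_width_um, p$body_width_sd_um),
          egg_length_um = rtnorm_pos(1, p$egg_length_um, p$egg_length_sd_um),
          egg_width_um = rtnorm_pos(1, p$egg_width_um, p$egg_width_sd_um),
          maturation_interval_h = grid_ceiling(
            rtnorm_pos(1, p$maturation_mean_h, p$maturation_sd_h), w
          )
        )
      )
    }
  ) |>
    purrr::list_rbind()

  elem_units <- tidyr::expand_grid(
    clone = design$clone_labels[seq_len(design$n_clones_elemental)],
    treatment = params$treatment,
    chemostat_replicate = paste0("R", seq_len(design$n_replicates))
  )
  elemental <- purrr::pmap(
    elem_units,
    function(clone, treatment, chemostat_replicate) {
      p <- params_for(params, treatment)
      with_unit_seed(
        seed, c("elemental", clone, treatment, chemostat_replicate),
        tibble::tibble(
          sample_id = paste(clone, treatment, chemostat_replicate, sep = "."),
          clone = clone,
          treatment = treatment,
          chemostat_replicate = chemostat_replicate,
          organism = "rotifer",
          n_individuals = as.integer(n_pooled),
          c_mass_ug = rtnorm_pos(
            1, n_pooled * p$c_per_ind_ug,
            p$content_cv * n_pooled * p$c_per_ind_ug
          ),
          n_mass_ug = rtnorm_pos(
            1, n_pooled * p$n_per_ind_ug,
            p$content_cv * n_pooled * p$n_per_ind_ug
          ),
          p_mass_ug = rtnorm_pos(
            1, n_pooled * p$p_per_ind_ug,
            p$content_cv * n_pooled * p$p_per_ind_ug
          )
        )
      )
    }
  ) |>
    purrr::list_rbind()

  cp_units <- tidyr::expand_grid(
    treatment = params$treatment,
    chemostat_replicate = paste0("R", seq_len(design$n_replicates)),
    occasion = seq_len(design$cp_occasions)
  )
  algal_cp <- purrr::pmap(
    cp_units,
    function(treatment, chemostat_replicate, occasion) {
      p <- params_for(params, treatment)
      with_unit_seed(
        seed, c("algalcp", treatment, chemostat_replicate, occasion),
        tibble::tibble(
          treatment = treatment,
          chemostat_replicate = chemostat_replicate,
          occasion = as.integer(occasion),
          cp_molar = rtnorm_pos(
            1, p$algal_cp_mean, p$algal_cp_se * sqrt(p$algal_cp_n)
          )
        )
      )
    }
  ) |>
    purrr::list_rbind()

  list(morphometry = morphometry, elemental = elemental, algal_cp = algal_cp)
}
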