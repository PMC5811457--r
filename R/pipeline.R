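# End-to-end orchestration: (simulated or read) tables -> schedules and
# traits -> growth estimates -> stoichiometric summaries -> decomposition.

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with documented defaults. With
#' `simulate = TRUE` (default) the synthetic generator supplies all input
#' tables; otherwise the `paths` entries must point to CSV files matching
#' the package schemas.
#'
#' @param design A [design_config()].
#' @param params A parameter table, see [default_params()].
#' @param seed Master seed for simulation and bootstrap.
#' @param age_class_width Life-table class width (hours).
#' @param solver_tol,solver_bracket Euler-Lotka residual tolerance and
#'   initial per-day rate bracket.
#' @param census_window Day range averaged for the census growth rate.
#' @param n_boot Bootstrap draws for decomposition intervals.
#' @param scenario_tolerance_pct Scenario-classification tolerance.
#' @param simulate Use the synthetic generator instead of reading files.
#' @param paths Named list of input CSV paths (`event_log`, `census`,
#'   `morphometry`, `elemental`, `algal_cp`) used when `simulate = FALSE`.
#' @param out_dir Optional directory; when set, all report tables and a
#'   run log are written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_config(),
                            params = default_params(),
                            seed = 1L,
                            age_class_width = 2,
                            solver_tol = 1e-10,
                            solver_bracket = c(-5, 5),
                            census_window = c(7, 22),
                            n_boot = 1000,
                            scenario_tolerance_pct = 5,
                            simulate = TRUE,
                            paths = list(),
                            out_dir = NULL) {
  structure(
    list(
      design = design, params = params, seed = as.integer(seed),
      age_class_width = age_class_width,
      solver_tol = solver_tol, solver_bracket = solver_bracket,
      census_window = census_window, n_boot = as.integer(n_boot),
      scenario_tolerance_pct = scenario_tolerance_pct,
      simulate = isTRUE(simulate), paths = paths, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

# trait metadata used to assemble the replicate-level summary table
trait_catalogue <- tibble::tibble(
  trait = c(
    "population_growth_rate_d", "intrinsic_r_d", "age_first_egg_h",
    "first_egg_dev_h", "egg_production_rate_h", "egg_mortality",
    "somatic_growth_um3_h", "body_volume_um3", "egg_volume_um3",
    "rotifer_cp_molar", "rotifer_c_ug", "rotifer_p_ug"
  ),
  orientation = c(
    "benefit", "benefit", "cost", "cost", "benefit", "cost",
    "benefit", "benefit", "benefit", "cost", "benefit", "benefit"
  ),
  mortality = c(
    FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE
  )
)

#' Replicate-level trait means of a trial
#'
#' Averages every analysed trait within each treatment x chemostat
#' replicate (the true unit of replication) and returns a long table ready
#' for [decompose_traits()].
#'
#' @param events Event log.
#' @param census Census table.
#' @param morpho Morphometry table (raw dimensions).
#' @param elemental Pooled elemental table.
#' @param age_class_width,census_window See [pipeline_config()].
#' @return Long tibble: `trait`, `treatment`, `chemostat_replicate`,
#'   `value`, `orientation`, `mortality`.
#' @export
replicate_trait_means <- function(events, census, morpho, elemental,
                                  age_class_width = 2,
                                  census_window = c(7, 22)) {
  by <- c("treatment", "chemostat_replicate")
  traits <- extract_traits(events)
  base <- traits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      age_first_egg_h = mean(.data$age_first_egg_h, na.rm = TRUE),
      first_egg_dev_h = mean(.data$first_egg_dev_h, na.rm = TRUE),
      egg_production_rate_h = mean(.data$egg_production_rate_h, na.rm = TRUE),
      .groups = "drop"
    )
  mort <- mortality_summary(events, by = by) |>
    dplyr::transmute(
      treatment, chemostat_replicate,
      egg_mortality = dplyr::if_else(
        .data$eggs_resolved > 0,
        .data$eggs_died / .data$eggs_resolved, NA_real_
      )
    )
  rint <- intrinsic_rates(events, age_class_width, by = by) |>
    dplyr::select(dplyr::all_of(by), intrinsic_r_d = "r_d")
  pops <- census_growth_rate(census, census_window) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(population_growth_rate_d = mean(.data$r_d), .groups = "drop")
  morph <- morphometry_volumes(morpho) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      body_volume_um3 = mean(.data$body_vol_um3),
      egg_volume_um3 = mean(.data$egg_vol_um3, na.rm = TRUE),
      somatic_growth_um3_h = mean(.data$somatic_growth_um3_h, na.rm = TRUE),
      .groups = "drop"
    )
  elem <- elemental |>
    elemental_ratios() |>
    per_individual_content() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      rotifer_cp_molar = mean(.data$cp_molar),
      rotifer_c_ug = mean(.data$c_per_ind_ug),
      rotifer_p_ug = mean(.data$p_per_ind_ug),
      .groups = "drop"
    )
  wide <- base |>
    dplyr::full_join(mort, by = by) |>
    dplyr::full_join(rint, by = by) |>
    dplyr::full_join(pops, by = by) |>
    dplyr::full_join(morph, by = by) |>
    dplyr::full_join(elem, by = by)
  wide |>
    tidyr::pivot_longer(-dplyr::all_of(by), names_to = "trait", values_to = "value") |>
    dplyr::inner_join(trait_catalogue, by = "trait")
}

#' Run the full trial analysis
#'
#' Executes, in order: input simulation (or reading and validation) ->
#' life-table schedules and per-individual traits -> intrinsic and census
#' growth rates -> morphometric and stoichiometric summaries -> the
#' direct/indirect decomposition with bootstrap intervals. Identical
#' config and seed reproduce identical output. When `out_dir` is set, all
#' report tables are written there as CSV together with a `run_log.txt`
#' recording config, seed and versions.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `trial_report` holding every intermediate and
#'   final table: `events`, `census`, `morphometry`, `elemental`,
#'   `algal_cp`, `schedules`, `traits`, `mortality`, `intrinsic_rates`,
#'   `census_rates`, `replicate_means`, `decomposition`.
#' @export
#' @examples
#' cfg <- pipeline_config(
#'   design = design_config(n_replicates = 2, n_individuals = 3, n_clones = 1),
#'   n_boot = 100
#' )
#' rep <- run_pipeline(cfg)
#' rep$decomposition[, c("trait", "indirect_pct", "direct_pct", "scenario")]
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(
        paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = "stoichdemo_pipeline_error", parent = e
      )
    })
  }
  if (config$simulate) {
    events <- stage("simulate", simulate_individuals(
      config$design, config$params, config$seed
    ))
    census <- stage("simulate", simulate_census(
      config$design, config$params, config$seed
    ))
    comp <- stage("simulate", simulate_composition(
      config$design, config$params, config$seed
    ))
    morpho <- comp$morphometry
    elemental <- comp$elemental
    algal_cp <- comp$algal_cp
  } else {
    events <- stage("read", read_event_log(config$paths$event_log))
    census <- stage("read", read_census(config$paths$census))
    morpho <- stage("read", readr::read_csv(
      config$paths$morphometry,
      col_types = readr::cols()
    ))
    elemental <- stage("read", readr::read_csv(
      config$paths$elemental,
      col_types = readr::cols()
    ))
    algal_cp <- stage("read", readr::read_csv(
      config$paths$algal_cp,
      col_types = readr::cols()
    ))
  }
  schedules <- stage("life_table", life_schedules(events, config$age_class_width))
  traits <- stage("life_table", extract_traits(events))
  mortality <- stage("life_table", mortality_summary(events))
  rint <- stage("demography", intrinsic_rates(
    events, config$age_class_width,
    tol = config$solver_tol, bracket = config$solver_bracket
  ))
  crate <- stage("demography", census_growth_rate(census, config$census_window))
  repmeans <- stage("summaries", replicate_trait_means(
    events, census, morpho, elemental,
    age_class_width = config$age_class_width,
    census_window = config$census_window
  ))
  decomp <- stage("decomposition", decompose_traits(
    repmeans,
    scenario_tolerance_pct = config$scenario_tolerance_pct,
    n_boot = config$n_boot, seed = config$seed
  ))
  algal_summary <- algal_cp |>
    dplyr::group_by(treatment) |>
    dplyr::summarise(
      cp_mean = mean(.data$cp_molar),
      cp_se = stats::sd(.data$cp_molar) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )
  report <- structure(
    list(
      events = events, census = census, morphometry = morpho,
      elemental = elemental, algal_cp = algal_cp,
      algal_summary = algal_summary,
      schedules = schedules, traits = traits, mortality = mortality,
      intrinsic_rates = rint, census_rates = crate,
      replicate_means = repmeans, decomposition = decomp,
      config = config
    ),
    class = "trial_report"
  )
  if (!is.null(config$out_dir)) {
    write_trial_tables(report[vapply(report, is.data.frame, logical(1))],
      out_dir = config$out_dir
    )
    writeLines(
      c(
        paste0("stoichdemo ", as.character(utils::packageVersion("stoichdemo"))),
        paste0(R.version.string),
        paste0("seed = ", config$seed),
        paste0("age_class_width = ", config$age_class_width),
        paste0(
          "census_window = ",
          paste(config$census_window, collapse = "-")
        ),
        paste0("n_boot = ", config$n_boot),
        paste0("scenario_tolerance_pct = ", config$scenario_tolerance_pct),
        paste0("simulate = ", config$simulate),
        paste0("run at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
      ),
      file.path(config$out_dir, "run_log.txt")
    )
  }
  report
}

#' @export
print.trial_report <- function(x, ...) {
  cat("<trial_report>\n")
  cat(sprintf(
    "  %d individuals, %d census units\n",
    dplyr::n_distinct(x$events$individual_id),
    dplyr::n_distinct(x$census$unit_id)
  ))
  cat("  decomposition:\n")
  print(dplyr::select(
    tibble::as_tibble(x$decomposition),
    dplyr::any_of(c("trait", "indirect_pct", "direct_pct", "scenario"))
  ), n = Inf)
  invisible(x)
}

#' Serialise a pipeline configuration to flat key-value text
#'
#' Writes scalar settings as `key = value` lines, design fields as
#' `design.<field>` and per-treatment parameters as
#' `param.<treatment>.<field>`, and reads them back. Settings absent from
#' the file keep their defaults, so any subset of keys is a valid file.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config()` the path invisibly; `read_config()` a
#'   reconstructed `pipeline_config`.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v)) paste(v, collapse = ",") else paste(signif(v, 15), collapse = ",")
  }
  lines <- c(
    paste0("seed = ", config$seed),
    paste0("age_class_width = ", fmt(config$age_class_width)),
    paste0("solver_tol = ", fmt(config$solver_tol)),
    paste0("solver_bracket = ", fmt(config$solver_bracket)),
    paste0("census_window = ", fmt(config$census_window)),
    paste0("n_boot = ", config$n_boot),
    paste0("scenario_tolerance_pct = ", fmt(config$scenario_tolerance_pct)),
    paste0("simulate = ", config$simulate)
  )
  for (f in setdiff(names(config$design), c("clone_labels", "life_table_clone"))) {
    lines <- c(lines, paste0("design.", f, " = ", fmt(config$design[[f]])))
  }
  lines <- c(
    lines,
    paste0("design.clone_labels = ", fmt(config$design$clone_labels)),
    paste0("design.life_table_clone = ", fmt(config$design$life_table_clone))
  )
  for (i in seq_len(nrow(config$params))) {
    trt <- config$params$treatment[i]
    for (f in setdiff(names(config$params), "treatment")) {
      lines <- c(lines, paste0(
        "param.", trt, ".", f, " = ", fmt(config$params[[f]][i])
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  parse_val <- function(v) {
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else if (all(parts %in% c("TRUE", "FALSE"))) {
      as.logical(parts)
    } else {
      trimws(parts)
    }
  }
  kv <- setNames(lapply(vals, parse_val), keys)
  design_args <- kv[grepl("^design\\.", names(kv))]
  names(design_args) <- sub("^design\\.", "", names(design_args))
  design <- do.call(design_config, design_args)
  param_keys <- grep("^param\\.", names(kv), value = TRUE)
  params <- if (length(param_keys) > 0) {
    trts <- unique(sub("^param\\.([^.]+)\\..*$", "\\1", param_keys))
    purrr::map(trts, function(trt) {
      prefix <- paste0("param.", trt, ".")
      args <- kv[startsWith(names(kv), prefix)]
      names(args) <- substring(names(args), nchar(prefix) + 1)
      do.call(treatment_params, c(list(treatment = trt), args))
    }) |>
      purrr::list_rbind()
  } else {
    default_params()
  }
  scalar <- function(key, default) if (key %in% names(kv)) kv[[key]] else default
  pipeline_config(
    design = design, params = params,
    seed = scalar("seed", 1L),
    age_class_width = scalar("age_class_width", 2),
    solver_tol = scalar("solver_tol", 1e-10),
    solver_bracket = scalar("solver_bracket", c(-5, 5)),
    census_window = scalar("census_window", c(7, 22)),
    n_boot = scalar("n_boot", 1000),
    scenario_tolerance_pct = scalar("scenario_tolerance_pct", 5),
    simulate = scalar("simulate", TRUE)
  )
}
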