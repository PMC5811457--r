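# Delimited-text readers/writers and schema validation for the four tables.
# Readers are strict by default: every violated invariant is reported with
# its row number. A lenient mode drops offending rows with a warning, since
# hand-transcribed feeding-trial logs commonly contain glitches.

event_log_spec <- readr::cols(
  individual_id = readr::col_character(),
  clone = readr::col_character(),
  treatment = readr::col_character(),
  chemostat_replicate = readr::col_character(),
  event_type = readr::col_character(),
  event_time_h = readr::col_double(),
  egg_index = readr::col_integer()
)

census_spec <- readr::cols(
  unit_id = readr::col_character(),
  clone = readr::col_character(),
  treatment = readr::col_character(),
  chemostat_replicate = readr::col_character(),
  day = readr::col_integer(),
  n_start = readr::col_integer(),
  n_end = readr::col_integer()
)

report_problems <- function(problems, what, strict) {
  if (nrow(problems) == 0) {
    return(invisible(NULL))
  }
  msg <- paste0(
    nrow(problems), " invalid row(s) in ", what, ":\n",
    paste0(
      "  row ", problems$row, ": ", problems$problem,
      collapse = "\n"
    )
  )
  if (strict) {
    abort(msg, class = "stoichdemo_validation_error")
  }
  warn(paste0(msg, "\nOffending rows dropped (lenient mode)."))
}

#' Read and validate a life-table event log
#'
#' Reads a comma-separated event log (one row per observation event) and
#' enforces the schema invariants: known event types, non-negative times,
#' egg fates not preceding their laying, and consecutive egg indices per
#' individual. In strict mode (default) any violation aborts with a
#' listing of offending row numbers; in lenient mode offending rows are
#' dropped with a warning.
#'
#' @param path Path to a CSV file with columns `individual_id`, `clone`,
#'   `treatment`, `chemostat_replicate`, `event_type`, `event_time_h`,
#'   `egg_index`.
#' @param strict Abort on invalid rows (`TRUE`) or drop them (`FALSE`).
#' @return A validated event-log tibble.
#' @export
read_event_log <- function(path, strict = TRUE) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols()))
  missing <- setdiff(event_log_columns, header)
  if (length(missing) > 0) {
    abort(paste0(
      "Event log is missing column(s): ",
      paste(missing, collapse = ", ")
    ), class = "stoichdemo_validation_error")
  }
  log <- readr::read_csv(path, col_types = event_log_spec)
  problems <- validate_event_log(log)
  report_problems(problems, paste0("event log '", path, "'"), strict)
  if (!strict && nrow(problems) > 0) {
    log <- log[-problems$row, ]
  }
  log
}

validate_event_log <- function(log) {
  row_id <- seq_len(nrow(log))
  problems <- list()
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems[[length(problems) + 1]] <<- tibble::tibble(
        row = rows, problem = what
      )
    }
  }
  note(
    row_id[!log$event_type %in% event_types],
    "unknown event_type"
  )
  note(
    row_id[!is.finite(log$event_time_h) | log$event_time_h < 0],
    "event_time_h missing or negative"
  )
  egg_rows <- log$event_type %in% c(
    "egg_laid", "egg_hatched", "egg_died", "male_egg"
  )
  note(
    row_id[egg_rows & is.na(log$egg_index)],
    "egg event without egg_index"
  )
  # per-egg: fate must not precede laying
  lays <- log[log$event_type %in% c("egg_laid", "male_egg") & !is.na(log$egg_index), ]
  fates <- log[log$event_type %in% c("egg_hatched", "egg_died") & !is.na(log$egg_index), ]
  if (nrow(fates) > 0 && nrow(lays) > 0) {
    key_l <- paste(lays$individual_id, lays$egg_index)
    key_f <- paste(fates$individual_id, fates$egg_index)
    lay_time <- setNames(lays$event_time_h, key_l)
    bad <- !is.na(lay_time[key_f]) & fates$event_time_h < lay_time[key_f]
    note(
      row_id[log$event_type %in% c("egg_hatched", "egg_died") &
        !is.na(log$egg_index)][which(bad)],
      "egg fate precedes its laying"
    )
    orphan <- is.na(lay_time[key_f])
    note(
      row_id[log$event_type %in% c("egg_hatched", "egg_died") &
        !is.na(log$egg_index)][which(orphan)],
      "egg fate without a matching laying event"
    )
  }
  # egg indices consecutive from 1 within each individual
  bad_ind <- lays |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(
      ok = identical(sort(unique(.data$egg_index)), seq_along(unique(.data$egg_index))),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  note(
    row_id[log$event_type %in% c("egg_laid", "male_egg") &
      log$individual_id %in% bad_ind$individual_id],
    "egg indices not consecutive from 1"
  )
  if (length(problems) == 0) {
    return(tibble::tibble(row = integer(), problem = character()))
  }
  dplyr::arrange(purrr::list_rbind(problems), row)
}

#' Read and validate a census table
#'
#' Reads the serial-transfer census table (one row per unit and day).
#' Duplicate (unit, day) rows, non-increasing days within a unit, negative
#' counts and zero start counts are reported as validation errors.
#'
#' @param path Path to a CSV with columns `unit_id`, `clone`, `treatment`,
#'   `chemostat_replicate`, `day`, `n_start`, `n_end`.
#' @inheritParams read_event_log
#' @return A validated census tibble; an empty (header-only) file yields an
#'   empty tibble with a warning.
#' @export
read_census <- function(path, strict = TRUE) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols()))
  missing <- setdiff(names(census_spec$cols), header)
  if (length(missing) > 0) {
    abort(paste0(
      "Census table is missing column(s): ",
      paste(missing, collapse = ", ")
    ), class = "stoichdemo_validation_error")
  }
  cen <- readr::read_csv(path, col_types = census_spec)
  if (nrow(cen) == 0) {
    warn(paste0("Census file '", path, "' contains a header but no rows."))
    return(cen)
  }
  problems <- validate_census(cen)
  report_problems(problems, paste0("census table '", path, "'"), strict)
  if (!strict && nrow(problems) > 0) {
    cen <- cen[-problems$row, ]
  }
  cen
}

validate_census <- function(cen) {
  row_id <- seq_len(nrow(cen))
  problems <- list()
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems[[length(problems) + 1]] <<- tibble::tibble(
        row = rows, problem = what
      )
    }
  }
  dup <- duplicated(cen[, c("unit_id", "day")]) |
    duplicated(cen[, c("unit_id", "day")], fromLast = TRUE)
  note(row_id[dup], "duplicate (unit_id, day)")
  note(
    row_id[is.na(cen$n_start) | is.na(cen$n_end) |
      cen$n_start < 0 | cen$n_end < 0],
    "negative or missing count"
  )
  note(row_id[!is.na(cen$n_start) & cen$n_start == 0], "n_start is zero")
  if (length(problems) == 0) {
    return(tibble::tibble(row = integer(), problem = character()))
  }
  dplyr::arrange(purrr::list_rbind(problems), row)
}

#' Write pipeline tables as delimited text
#'
#' @param x A tibble (for the single-table writers) or a named list of
#'   tibbles (for [write_trial_tables()]).
#' @param path,out_dir Output file, or directory for the bundle writer.
#' @return The input, invisibly.
#' @export
write_event_log <- function(x, path) {
  readr::write_csv(x[, event_log_columns], path)
  invisible(x)
}

#' @rdname write_event_log
#' @export
write_census <- function(x, path) {
  readr::write_csv(x[, names(census_spec$cols)], path)
  invisible(x)
}

#' @rdname write_event_log
#' @export
write_trial_tables <- function(x, out_dir) {
  stopifnot(is.list(x), !is.null(names(x)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (nm in names(x)) {
    if (is.data.frame(x[[nm]])) {
      readr::write_csv(x[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  invisible(x)
}
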