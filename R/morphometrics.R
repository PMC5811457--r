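# Linear dimensions -> volumes -> somatic growth rate.

check_positive <- function(x, what) {
  if (any(!is.finite(x) | x <= 0)) {
    abort(sprintf("`%s` must be strictly positive.", what),
      class = "stoichdemo_domain_error"
    )
  }
}

#' Body and egg volumes from linear dimensions
#'
#' `body_volume()` treats the body as a cylinder-like solid of revolution,
#' `Vb = pi * Lb * (Wb / 2)^2`; `egg_volume()` uses the ellipsoid formula
#' `Ve = (4/3) * pi * (Le / 2) * (We / 2)^2`. Dimensions in micrometres
#' give volumes in cubic micrometres. Both are vectorised.
#'
#' @param length_um,width_um Length and width (micrometres), > 0.
#' @return Volume(s) in cubic micrometres.
#' @export
#' @examples
#' body_volume(200, 100) # pi * 200 * 50^2
#' egg_volume(100, 100) # sphere: (pi / 6) * 100^3
body_volume <- function(length_um, width_um) {
  check_positive(length_um, "length_um")
  check_positive(width_um, "width_um")
  pi * length_um * (width_um / 2)^2
}

#' @rdname body_volume
#' @export
egg_volume <- function(length_um, width_um) {
  check_positive(length_um, "length_um")
  check_positive(width_um, "width_um")
  (4 / 3) * pi * (length_um / 2) * (width_um / 2)^2
}

#' Somatic growth rate
#'
#' Volume gained per hour from hatching to first reproduction: the body
#' volume at first reproduction minus the volume of the first egg, divided
#' by the maturation interval. A negative value (first egg larger than the
#' body estimate) is returned as-is; callers may flag it.
#'
#' @param body_vol_um3 Body volume at first reproduction (cubic um).
#' @param egg_vol_um3 Volume of the individual's first egg (cubic um).
#' @param maturation_interval_h Hours from hatching to first egg
#'   production; must be > 0.
#' @return Growth rate in cubic micrometres per hour.
#' @export
#' @examples
#' somatic_growth_rate(1.6e6, 3.4e5, 40)
somatic_growth_rate <- function(body_vol_um3, egg_vol_um3,
                                maturation_interval_h) {
  if (any(!is.finite(maturation_interval_h) | maturation_interval_h <= 0)) {
    abort("`maturation_interval_h` must be strictly positive.",
      class = "stoichdemo_domain_error"
    )
  }
  (body_vol_um3 - egg_vol_um3) / maturation_interval_h
}

#' Derive volumes and somatic growth for a morphometry table
#'
#' Adds `body_vol_um3`, `egg_vol_um3` and `somatic_growth_um3_h` to a
#' morphometry table. Rows with missing egg dimensions receive the mean
#' egg volume of their chemostat replicate (flagged in `egg_vol_imputed`)
#' so replicate-level means stay estimable.
#'
#' @param morpho A morphometry tibble with `body_length_um`,
#'   `body_width_um`, `egg_length_um`, `egg_width_um`,
#'   `maturation_interval_h` plus label columns.
#' @return The input with volume, growth-rate and imputation-flag columns.
#' @export
morphometry_volumes <- function(morpho) {
  out <- morpho |>
    dplyr::mutate(
      body_vol_um3 = body_volume(.data$body_length_um, .data$body_width_um),
      egg_vol_um3 = dplyr::if_else(
        !is.na(.data$egg_length_um) & !is.na(.data$egg_width_um),
        (4 / 3) * pi * (.data$egg_length_um / 2) * (.data$egg_width_um / 2)^2,
        NA_real_
      ),
      egg_vol_imputed = is.na(.data$egg_vol_um3)
    ) |>
    dplyr::group_by(treatment, chemostat_replicate) |>
    dplyr::mutate(
      egg_vol_um3 = dplyr::if_else(
        is.na(.data$egg_vol_um3),
        mean(.data$egg_vol_um3, na.rm = TRUE),
        .data$egg_vol_um3
      )
    ) |>
    dplyr::ungroup()
  out$somatic_growth_um3_h <- somatic_growth_rate(
    out$body_vol_um3, out$egg_vol_um3, out$maturation_interval_h
  )
  out
}
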