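# Molar elemental ratios and per-individual composition.

# atomic masses (g/mol), 5 significant figures
atomic_mass <- c(C = 12.011, N = 14.007, P = 30.974)

#' Molar elemental ratio
#'
#' Converts two elemental masses (same mass unit) to a molar ratio
#' `(mass_a / M_a) / (mass_b / M_b)` using atomic masses C 12.011,
#' N 14.007, P 30.974. Vectorised.
#'
#' @param mass_a,mass_b Elemental masses (any common unit).
#' @param element_a,element_b Element symbols, one of `"C"`, `"N"`, `"P"`.
#' @return The dimensionless molar ratio.
#' @export
#' @examples
#' molar_ratio(12.011, 30.974) # 1 mol C per mol P
molar_ratio <- function(mass_a, mass_b, element_a = "C", element_b = "P") {
  if (!element_a %in% names(atomic_mass) || !element_b %in% names(atomic_mass)) {
    abort("Elements must be one of 'C', 'N', 'P'.",
      class = "stoichdemo_domain_error"
    )
  }
  if (any(!is.finite(mass_b) | mass_b <= 0)) {
    abort("Denominator mass must be strictly positive.",
      class = "stoichdemo_domain_error"
    )
  }
  (mass_a / atomic_mass[[element_a]]) / (mass_b / atomic_mass[[element_b]])
}

#' Per-individual elemental content
#'
#' Divides pooled C, N, P masses by the number of pooled individuals,
#' carrying labels through.
#'
#' @param elemental An elemental tibble with `c_mass_ug`, `n_mass_ug`,
#'   `p_mass_ug` and `n_individuals`.
#' @return The input with `c_per_ind_ug`, `n_per_ind_ug`, `p_per_ind_ug`
#'   columns added.
#' @export
per_individual_content <- function(elemental) {
  if (any(elemental$n_individuals < 1)) {
    abort("`n_individuals` must be >= 1.", class = "stoichdemo_domain_error")
  }
  dplyr::mutate(elemental,
    c_per_ind_ug = .data$c_mass_ug / .data$n_individuals,
    n_per_ind_ug = .data$n_mass_ug / .data$n_individuals,
    p_per_ind_ug = .data$p_mass_ug / .data$n_individuals
  )
}

#' Molar ratios for an elemental table
#'
#' Adds molar C:P, C:N and N:P columns to a pooled elemental table.
#'
#' @inheritParams per_individual_content
#' @return The input with `cp_molar`, `cn_molar`, `np_molar` added.
#' @export
elemental_ratios <- function(elemental) {
  dplyr::mutate(elemental,
    cp_molar = molar_ratio(.data$c_mass_ug, .data$p_mass_ug, "C", "P"),
    cn_molar = molar_ratio(.data$c_mass_ug, .data$n_mass_ug, "C", "N"),
    np_molar = molar_ratio(.data$n_mass_ug, .data$p_mass_ug, "N", "P")
  )
}
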