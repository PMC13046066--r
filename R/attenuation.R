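#' Elemental mass attenuation coefficients at 50 and 88 keV
#'
#' Vendored extract of total photon mass attenuation coefficients
#' (coherent scattering included) for H, C, N, O and Ca at the two
#' monoenergetic imaging energies, taken from the standard XCOM/EPDL-class
#' cross-section compilations; the 88 keV values are log-log interpolated
#' from the neighbouring 80 and 100 keV grid points (the `source` column
#' records which). Units are SI: m^2 kg^-1.
#'
#' @param path Optional path to a replacement constants CSV with columns
#'   `element, energy_keV, mu_m_m2_per_kg, source` (for sensitivity
#'   studies); defaults to the packaged extract.
#' @return A tibble with 10 rows.
#' @export
#' @examples
#' attenuation_table()
attenuation_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mass_attenuation_xcom.csv",
                        package = "dectmix", mustWork = TRUE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("element", "energy_keV", "mu_m_m2_per_kg", "source")
  if (!all(needed %in% names(tab))) {
    stop("attenuation table must have columns: ", paste(needed, collapse = ", "))
  }
  if (any(tab$mu_m_m2_per_kg <= 0)) stop("attenuation coefficients must be positive")
  tab
}

#' Mass attenuation coefficient of one element
#'
#' @param element Element symbol, one of H, C, N, O, Ca.
#' @param energy Photon energy in keV, 50 or 88.
#' @param table Constants table, defaults to [attenuation_table()].
#' @return The coefficient in m^2 kg^-1.
#' @export
#' @examples
#' mass_atten_coeff("Ca", 50)
mass_atten_coeff <- function(element, energy, table = attenuation_table()) {
  hit <- table$element == element & table$energy_keV == energy
  if (sum(hit) != 1L) {
    stop("no attenuation constant for element '", element,
         "' at ", energy, " keV")
  }
  table$mu_m_m2_per_kg[hit]
}

# Coefficients for a category's element set at one energy, as a named
# vector in canonical element order.
atten_vector <- function(elements, energy, table = attenuation_table()) {
  vapply(elements, mass_atten_coeff, numeric(1), energy = energy, table = table)
}

#' Harmonic-mean density of a two-component mixture
#'
#' Density of an ideal volumetric mixture of two components with mass
#' fractions `w1` and `1 - w1`:
#' `rho_mix = (w1 / rho1 + (1 - w1) / rho2)^-1`. The mixture volume is the
#' sum of the component volumes, so the mixture density is the harmonic
#' mean of the component densities weighted by mass fraction.
#'
#' @param w1 Mass fraction of component 1, in `[0, 1]` (vectorized).
#' @param rho1,rho2 Component densities in kg m^-3, > 0 (vectorized).
#' @return Mixture density in kg m^-3.
#' @export
#' @examples
#' mixture_density(0.5, 950, 1050)  # 997.5
mixture_density <- function(w1, rho1, rho2) {
  if (any(w1 < 0 | w1 > 1)) stop("w1 must lie in [0, 1]")
  if (any(rho1 <= 0) || any(rho2 <= 0)) stop("densities must be positive")
  1 / (w1 / rho1 + (1 - w1) / rho2)
}

#' Linear attenuation coefficient via the mixture rule
#'
#' `mu(E) = rho * sum_i w_i * mu_m_i(E)`, summed over the modelled element
#' set only. The mass fractions are used as sampled and are deliberately
#' not renormalized to sum to one (reference tissue rows omit trace
#' elements, so the modelled fractions sum to slightly less than one).
#'
#' @param samples Data frame with per-element fraction columns
#'   (`wH`, `wC`, ... on the dimensionless fraction scale) and a `rho`
#'   column (kg m^-3).
#' @param energy Photon energy in keV, 50 or 88.
#' @param elements Element symbols to sum over.
#' @param table Constants table, defaults to [attenuation_table()].
#' @return Numeric vector of LACs in m^-1, one per row of `samples`.
#' @export
linear_attenuation <- function(samples, energy,
                               elements = BONE_ELEMENTS,
                               table = attenuation_table()) {
  cols <- paste0("w", elements)
  missing_cols <- setdiff(c(cols, "rho"), names(samples))
  if (length(missing_cols) > 0) {
    stop("samples lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(vapply(cols, function(cc) any(samples[[cc]] < 0), logical(1)))) {
    stop("mass fractions must be non-negative")
  }
  mu_m <- atten_vector(elements, energy, table)
  W <- as.matrix(samples[, cols, drop = FALSE])
  samples$rho * drop(W %*% mu_m)
}
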