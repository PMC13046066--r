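#' Reference tissue compositions
#'
#' Elemental mass fractions (per cent) and mass densities (kg m^-3) for the
#' eight reference body-tissue rows used to parameterize the generator:
#' three adipose rows and three muscle rows (middle row = mean, outer rows =
#' mean +/- 1 SD where symmetric), plus single rows for cortical bone and
#' red bone marrow. Values follow the Woodard-White compilation of human
#' tissue composition.
#'
#' @param path Optional path to a replacement table with the same columns
#'   (`tissue, wH, wC, wN, wO, wCa, rho`); defaults to the packaged CSV.
#' @return A tibble with 8 rows; mass fractions in per cent, `rho` in
#'   kg m^-3.
#' @export
#' @examples
#' tissue_table()
tissue_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tissue_compositions.csv",
                        package = "dectmix", mustWork = TRUE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("tissue", "wH", "wC", "wN", "wO", "wCa", "rho")
  if (!all(needed %in% names(tab))) {
    stop("tissue table must have columns: ", paste(needed, collapse = ", "))
  }
  tab
}

#' Distribution specification
#'
#' A sampling distribution for one scalar quantity: either
#' `Normal(mean, sd)` (used where the reference table encodes mean +/- 1 SD
#' through three tissue rows) or `Uniform(lower, upper)` (used where only a
#' range can be defined from the numeric precision of a printed value).
#'
#' @param kind `"normal"` or `"uniform"`.
#' @param param1 Mean (normal) or lower bound (uniform).
#' @param param2 SD (normal, must be > 0) or upper bound (uniform, must
#'   exceed `param1`).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(kind, param1, param2) {
  kind <- match.arg(kind, c("normal", "uniform"))
  stopifnot(is.numeric(param1), is.numeric(param2),
            length(param1) == 1L, length(param2) == 1L)
  if (kind == "normal" && param2 <= 0) stop("normal dist_spec requires sd > 0")
  if (kind == "uniform" && param1 >= param2) {
    stop("uniform dist_spec requires param1 < param2")
  }
  structure(list(kind = kind, param1 = param1, param2 = param2),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  lab <- if (x$kind == "normal") "Normal(mean=%g, sd=%g)" else "Uniform(%g, %g)"
  cat(sprintf(lab, x$param1, x$param2), "\n")
  invisible(x)
}

#' Draw from a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
rdist <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    normal  = rnorm(n, spec$param1, spec$param2),
    uniform = runif(n, spec$param1, spec$param2)
  )
}

#' Uniform range implied by the numeric precision of a printed value
#'
#' A value printed with finite precision defines a uniform range of half the
#' last printed digit's place value around it: 3.4 (one decimal) maps to
#' Uniform(3.35, 3.45). Negative `printed_decimals` address place values
#' left of the decimal point, e.g. `-1` treats the tens place as the last
#' significant digit, so 1920 maps to Uniform(1915, 1925).
#'
#' @param printed_value The printed number (any units).
#' @param printed_decimals Number of printed decimal places; may be
#'   negative.
#' @return A uniform [dist_spec()] centred on `printed_value`.
#' @export
#' @examples
#' precision_range(3.4, 1)    # Uniform(3.35, 3.45)
#' precision_range(1920, -1)  # Uniform(1915, 1925)
precision_range <- function(printed_value, printed_decimals) {
  stopifnot(is.numeric(printed_value), length(printed_value) == 1L,
            printed_decimals == round(printed_decimals))
  half <- 0.5 * 10^(-printed_decimals)
  dist_spec("uniform", printed_value - half, printed_value + half)
}

#' Per-tissue sampling specifications for a category
#'
#' Converts the reference table into the two pure-component sampling
#' specifications of a tissue category. For adipose and muscle (three rows
#' each) per-element mass fractions are `Normal(mean = middle row,
#' sd = |row1 - row3| / 2)`; for the single-row tissues (cortical bone, red
#' bone marrow) they are uniform over the printed precision. Densities
#' follow the same reading: the three distinct adipose densities give a
#' normal, all other densities a precision-derived uniform (half-width 5
#' kg m^-3, the tens place being the last significant printed digit).
#'
#' Internally all mass fractions are dimensionless (per cent / 100) and
#' densities are kg m^-3. For soft tissue Ca is identically zero and is
#' excluded from the element set; red-marrow Ca (printed 0.0) is sampled
#' from its precision range with negative draws removed downstream by
#' rejection.
#'
#' @param category `"soft"` or `"bone"`.
#' @param table Reference composition table, defaults to [tissue_table()].
#' @return Named list of two `tissue_component_spec` objects
#'   (`adipose`/`muscle` or `cortical_bone`/`red_marrow`), each with fields
#'   `name`, `elements` (named list of [dist_spec()], fraction scale) and
#'   `density` ([dist_spec()], kg m^-3).
#' @export
#' @examples
#' build_component_specs("soft")$adipose$elements$H
build_component_specs <- function(category, table = tissue_table()) {
  category <- match.arg(category, c("soft", "bone"))
  elems <- element_set(category)
  row_of <- function(name) {
    r <- table[table$tissue == name, , drop = FALSE]
    if (nrow(r) != 1L) stop("tissue row not found: ", name)
    r
  }

  # mean +/- 1 SD encoded across three rows; values on percent scale
  triplet_spec <- function(rows, col) {
    v <- vapply(rows, function(r) r[[col]], numeric(1))
    sdv <- abs(v[1] - v[3]) / 2
    if (sdv > 0) {
      dist_spec("normal", v[2] / 100, sdv / 100)
    } else {
      scale_spec(precision_range(v[2], 1), 1 / 100)
    }
  }
  single_spec <- function(row, col) scale_spec(precision_range(row[[col]], 1), 1 / 100)

  make <- function(name, rows) {
    el <- lapply(elems, function(e) {
      col <- paste0("w", e)
      if (length(rows) == 3L) triplet_spec(rows, col) else single_spec(rows[[1]], col)
    })
    names(el) <- elems
    rho <- vapply(rows, function(r) r$rho, numeric(1))
    density <- if (length(unique(rho)) == 3L) {
      dist_spec("normal", rho[2], abs(rho[1] - rho[3]) / 2)
    } else {
      precision_range(rho[[1]], -1)
    }
    structure(list(name = name, elements = el, density = density),
              class = "tissue_component_spec")
  }

  if (category == "soft") {
    list(
      adipose = make("adipose", lapply(paste("Adipose", 1:3), row_of)),
      muscle  = make("muscle",  lapply(paste("Muscle", 1:3), row_of))
    )
  } else {
    list(
      cortical_bone = make("cortical_bone", list(row_of("Cort. bone"))),
      red_marrow    = make("red_marrow",    list(row_of("Red b. m.")))
    )
  }
}

# Rescale a dist_spec by a positive factor (percent -> fraction).
scale_spec <- function(spec, factor) {
  stopifnot(inherits(spec, "dist_spec"), factor > 0)
  dist_spec(spec$kind, spec$param1 * factor, spec$param2 * factor)
}

#' @export
print.tissue_component_spec <- function(x, ...) {
  cat("<tissue_component_spec>", x$name, "\n")
  for (e in names(x$elements)) {
    s <- x$elements[[e]]
    cat(sprintf("  w%-2s %s(%.5g, %.5g)\n", e, s$kind, s$param1, s$param2))
  }
  cat(sprintf("  rho %s(%.5g, %.5g) kg/m^3\n",
              x$density$kind, x$density$param1, x$density$param2))
  invisible(x)
}
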