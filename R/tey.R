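#' Conversion constants for theoretical ethanol yield
#'
#' The standard stoichiometric/process constants used to convert stem
#' composition into a theoretical ethanol yield (TEY) on a g per kg dry matter
#' basis: 1.11 g sugar per g structural polysaccharide (hydration of glucan /
#' xylan on hydrolysis), 0.51 g ethanol per g fermentable sugar, an assumed
#' process efficiency of 0.85, and the specific gravity of ethanol 0.79 g/mL.
#'
#' @param sugar_conversion polysaccharide-to-sugar hydrolysis factor.
#' @param ethanol_from_sugar stoichiometric ethanol yield per unit sugar.
#' @param process_efficiency fraction of theoretical fermentation achieved.
#' @param ethanol_specific_gravity density of ethanol, g/mL.
#' @param output_scale scale factor taking mass fraction to g/kg.
#' @return A named list of class `tey_parameters`.
#' @export
tey_parameters <- function(sugar_conversion = 1.11,
                           ethanol_from_sugar = 0.51,
                           process_efficiency = 0.85,
                           ethanol_specific_gravity = 0.79,
                           output_scale = 1000) {
  p <- list(sugar_conversion = sugar_conversion,
            ethanol_from_sugar = ethanol_from_sugar,
            process_efficiency = process_efficiency,
            ethanol_specific_gravity = ethanol_specific_gravity,
            output_scale = output_scale)
  if (any(unlist(p) <= 0)) stop("all TEY parameters must be positive")
  structure(p, class = "tey_parameters")
}

check_percent <- function(x, what) {
  if (any(x < 0)) stop(what, " must be non-negative (percent dry weight)")
  if (any(x > 100)) stop(what, " exceeds 100 percent dry weight")
  x
}

#' Theoretical ethanol yield from hexose (C6) sugars
#'
#' `TEY-C6 = (soluble sugar/100 + 1.11 * cellulose/100) * 0.51 * 0.85 *
#' 1000/0.79` in g ethanol per kg dry matter. Percent inputs are converted to
#' mass fractions before the g/kg scale is applied, the only reading under
#' which the printed constants give yields on the observed few-hundred-g/kg
#' scale.
#'
#' @param soluble_sugar soluble sugar, percent of dry weight.
#' @param cellulose cellulose, percent of dry weight.
#' @param params a [tey_parameters()] object.
#' @return TEY-C6 in g/kg dry matter (vectorized).
#' @export
tey_c6 <- function(soluble_sugar, cellulose, params = tey_parameters()) {
  check_percent(soluble_sugar, "soluble_sugar")
  check_percent(cellulose, "cellulose")
  sugar <- soluble_sugar / 100 + params$sugar_conversion * cellulose / 100
  sugar * params$ethanol_from_sugar * params$process_efficiency *
    params$output_scale / params$ethanol_specific_gravity
}

#' Theoretical ethanol yield from pentose (C5) sugars
#'
#' `TEY-C5 = (hemicellulose/100 * 1.11) * 0.51 * 0.85 * 1000/0.79` in g/kg.
#'
#' @param hemicellulose hemicellulose, percent of dry weight.
#' @param params a [tey_parameters()] object.
#' @return TEY-C5 in g/kg dry matter (vectorized).
#' @export
tey_c5 <- function(hemicellulose, params = tey_parameters()) {
  check_percent(hemicellulose, "hemicellulose")
  sugar <- params$sugar_conversion * hemicellulose / 100
  sugar * params$ethanol_from_sugar * params$process_efficiency *
    params$output_scale / params$ethanol_specific_gravity
}

#' Total theoretical ethanol yield
#'
#' The sum of the hexose and pentose contributions, [tey_c6()] + [tey_c5()].
#'
#' @inheritParams tey_c6
#' @inheritParams tey_c5
#' @return Total TEY in g/kg dry matter (vectorized).
#' @export
tey_total <- function(soluble_sugar, cellulose, hemicellulose,
                      params = tey_parameters()) {
  tey_c6(soluble_sugar, cellulose, params) + tey_c5(hemicellulose, params)
}
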