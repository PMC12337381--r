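#' Carbon mass fractions of water-soluble carbohydrates
#'
#' Default mass fraction of carbon in each WSC class: fructan 0.44, sucrose
#' 0.42, glucose and fructose 0.40. Override entries for other assumptions.
#'
#' @param ... Named overrides, e.g. `carbon_fractions(fructan = 0.45)`.
#' @return Named numeric vector of fractions in (0, 1).
#' @export
carbon_fractions <- function(...) {
  fr <- c(fructan = 0.44, sucrose = 0.42, glucose = 0.40, fructose = 0.40)
  dots <- c(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(fr))
    if (length(unknown)) {
      stop("unknown carbohydrate component(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    fr[names(dots)] <- dots
  }
  if (any(fr <= 0 | fr >= 1)) {
    stop("carbon fractions must lie in (0, 1)", call. = FALSE)
  }
  fr
}

#' Carbon mass of a WSC sample from its component masses
#'
#' Sum of component dry masses weighted by their carbon mass fractions.
#'
#' @param component_masses Named numeric vector of component dry masses (g);
#'   names must be known to `fractions`.
#' @param fractions Carbon fractions, see [carbon_fractions()].
#' @return Carbon mass in g.
#' @examples
#' wsc_carbon_mass(c(fructan = 1, sucrose = 0.5))
#' @export
wsc_carbon_mass <- function(component_masses, fractions = carbon_fractions()) {
  if (is.null(names(component_masses)) || any(names(component_masses) == "")) {
    stop("`component_masses` must be a fully named vector", call. = FALSE)
  }
  unknown <- setdiff(names(component_masses), names(fractions))
  if (length(unknown)) {
    stop("unknown carbohydrate component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(component_masses < 0)) {
    stop("component masses must be >= 0", call. = FALSE)
  }
  sum(component_masses * fractions[names(component_masses)])
}

#' delta13C of WSC-free biomass by isotopic mass balance
#'
#' Removes the isotopic contribution of the water-soluble carbohydrates from a
#' bulk biomass measurement:
#' (delta_biomass * W_biomass - delta_wsc * W_wsc) / (W_biomass - W_wsc).
#' This is an extrapolation, so the result may lie outside the range of the
#' two input deltas.
#'
#' @param delta_biomass delta13C of bulk biomass (permil VPDB).
#' @param w_biomass Carbon mass of the biomass sample (g C), > `w_wsc`.
#' @param delta_wsc delta13C of the WSC extracted from that sample (permil).
#' @param w_wsc Carbon mass of the WSC (g C), >= 0.
#' @return delta13C of the WSC-free residue (permil VPDB).
#' @examples
#' wsc_free_biomass_delta(-30, 1.0, -28, 0.25)
#' @export
wsc_free_biomass_delta <- function(delta_biomass, w_biomass, delta_wsc, w_wsc) {
  check_delta(delta_biomass, "delta_biomass")
  if (any(w_wsc < 0) || any(w_biomass <= 0)) {
    stop("carbon masses must satisfy w_biomass > 0 and w_wsc >= 0",
         call. = FALSE)
  }
  if (any(w_wsc >= w_biomass)) {
    stop("mass-balance violation: w_wsc must be < w_biomass", call. = FALSE)
  }
  # w_wsc = 0 degenerates cleanly to delta_biomass before delta_wsc matters
  if (all(w_wsc == 0)) return(delta_biomass + 0 * w_wsc)
  check_delta(delta_wsc, "delta_wsc")
  (delta_biomass * w_biomass - delta_wsc * w_wsc) / (w_biomass - w_wsc)
}

#' Carbon-weighted pooled delta13C of WSC components
#'
#' Forms the bulk-WSC delta13C needed by [wsc_free_biomass_delta()] from
#' per-fraction measurements, weighting each component delta by its carbon
#' mass.
#'
#' @param component_deltas Named delta13C per component (permil VPDB).
#' @param component_carbon Carbon mass per component (g C), same names/order;
#'   positive total.
#' @return Pooled delta13C (permil VPDB).
#' @examples
#' pooled_wsc_delta(c(fructan = -26, sucrose = -27),
#'                  c(fructan = 0.44, sucrose = 0.42))
#' @export
pooled_wsc_delta <- function(component_deltas, component_carbon) {
  check_delta(component_deltas, "component_deltas")
  if (length(component_deltas) != length(component_carbon)) {
    stop("deltas and carbon masses must have equal length", call. = FALSE)
  }
  if (any(component_carbon < 0) || sum(component_carbon) <= 0) {
    stop("component carbon must be >= 0 with positive total", call. = FALSE)
  }
  if (!is.null(names(component_deltas)) && !is.null(names(component_carbon))) {
    component_carbon <- component_carbon[names(component_deltas)]
  }
  sum(component_deltas * component_carbon) / sum(component_carbon)
}
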