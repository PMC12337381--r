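#' Molar 13C/12C ratio of the VPDB standard
#'
#' The Vienna-Pee Dee Belemnite reference ratio used to interconvert
#' delta-notation values and molar isotope ratios. The ratio cancels in every
#' difference-based statistic in this package; it is exposed for completeness
#' and for users who need absolute ratios.
#'
#' @format A length-one numeric, 0.0111802 (dimensionless molar ratio).
#' @export
vpdb_ratio <- 0.0111802

# delta values at or below -1000 permil imply zero (or negative) 13C
check_delta <- function(delta, arg = "delta") {
  if (!is.numeric(delta) || any(!is.finite(delta))) {
    stop("`", arg, "` must be finite numeric (permil VPDB)", call. = FALSE)
  }
  if (any(delta <= -1000)) {
    stop("invalid delta13C: `", arg, "` must be > -1000 permil ",
         "(-1000 permil implies zero 13C)", call. = FALSE)
  }
  invisible(delta)
}

check_disc <- function(disc, warn = TRUE) {
  if (!is.numeric(disc) || any(!is.finite(disc))) {
    stop("`disc` must be finite numeric (permil)", call. = FALSE)
  }
  if (warn && any(disc < 0 | disc > 40)) {
    warning("discrimination outside the typical biological range 0-40 permil",
            call. = FALSE)
  }
  invisible(disc)
}

#' Convert delta13C to a molar 13C/12C ratio
#'
#' Delta notation expresses an isotope ratio R relative to a standard ratio
#' R_s as delta = (R/R_s - 1) * 1000. These two functions convert back and
#' forth; they are exact inverses.
#'
#' @param delta delta13C in permil relative to VPDB. Must be > -1000.
#' @param ratio Molar 13C/12C ratio, > 0.
#' @param r_standard Molar ratio of the standard (default [vpdb_ratio]).
#' @return `delta_to_ratio()` a molar ratio; `ratio_to_delta()` a delta13C in
#'   permil.
#' @examples
#' delta_to_ratio(0)                     # the standard itself
#' ratio_to_delta(delta_to_ratio(-43.5)) # round trip
#' @export
delta_to_ratio <- function(delta, r_standard = vpdb_ratio) {
  check_delta(delta)
  if (!is.numeric(r_standard) || any(r_standard <= 0)) {
    stop("`r_standard` must be > 0", call. = FALSE)
  }
  r_standard * (1 + delta / 1000)
}

#' @rdname delta_to_ratio
#' @export
ratio_to_delta <- function(ratio, r_standard = vpdb_ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("`ratio` must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(r_standard) || any(r_standard <= 0)) {
    stop("`r_standard` must be > 0", call. = FALSE)
  }
  (ratio / r_standard - 1) * 1000
}

#' delta13C of tissue formed from a CO2 source under a given discrimination
#'
#' The Farquhar relation between the delta13C of source CO2 and the delta13C
#' of plant material formed from it under photosynthetic discrimination
#' Delta13C: delta_tissue = (delta_CO2 - Delta) / (1 + Delta/1000). All
#' arguments are in permil; the division by 1000 is internal.
#'
#' @param delta_co2 delta13C of the source CO2 (permil VPDB).
#' @param disc Carbon isotope discrimination Delta13C (permil). Values outside
#'   0-40 permil trigger a warning (not an error).
#' @return delta13C of the tissue (permil VPDB).
#' @seealso [discrimination_from_sample()] for the inverse.
#' @examples
#' tissue_delta_from_source(-5.6, 21)   # mineral CO2, C3 grass
#' tissue_delta_from_source(-43.5, 21)  # fossil-organic CO2
#' @export
tissue_delta_from_source <- function(delta_co2, disc) {
  check_delta(delta_co2, "delta_co2")
  check_disc(disc)
  if (any(disc == -1000)) {
    stop("disc = -1000 permil: division by zero", call. = FALSE)
  }
  (delta_co2 - disc) / (1 + disc / 1000)
}

#' Carbon isotope discrimination expressed in a sample
#'
#' Discrimination recovered from the delta13C of the air a sample grew in
#' (chamber outlet air) and the delta13C of the sample itself:
#' Delta13C_X = (delta_outlet - delta_X) / (1 + delta_X/1000). Exact inverse
#' of [tissue_delta_from_source()] when `delta_outlet` is the chamber-air
#' delta13C.
#'
#' @param delta_outlet delta13C of chamber (outlet) air CO2 (permil VPDB).
#' @param delta_x delta13C of the sample (permil VPDB), > -1000.
#' @return Discrimination Delta13C (permil).
#' @examples
#' discrimination_from_sample(-3.04, tissue_delta_from_source(-3.04, 21))
#' @export
discrimination_from_sample <- function(delta_outlet, delta_x) {
  check_delta(delta_outlet, "delta_outlet")
  check_delta(delta_x, "delta_x")
  (delta_outlet - delta_x) / (1 + delta_x / 1000)
}
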