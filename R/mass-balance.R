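#' Convert a standard-litre-per-minute air flow to a molar flow
#'
#' SLPM is referenced here to 0 degC / 101.325 kPa, i.e. a molar volume of
#' 22.414 L mol-1. Mass-flow-controller vendors differ in their "standard"
#' conditions; `molar_volume_l` is exposed so another convention can be
#' declared. Difference-ratio statistics (the contamination fraction) are
#' insensitive to this constant, but absolute fluxes are not.
#'
#' @param flow_slpm Air flow in standard litres per minute, >= 0.
#' @param molar_volume_l Molar volume of air at the declared standard
#'   conditions (L mol-1), default 22.414.
#' @return Molar air flow in umol s-1.
#' @examples
#' slpm_to_molar_flow(1)    # ~743.7 umol s-1
#' slpm_to_molar_flow(750)
#' @export
slpm_to_molar_flow <- function(flow_slpm, molar_volume_l = 22.414) {
  if (!is.numeric(flow_slpm) || any(!is.finite(flow_slpm)) || any(flow_slpm < 0)) {
    stop("`flow_slpm` must be finite and >= 0", call. = FALSE)
  }
  flow_slpm / molar_volume_l * 1e6 / 60
}

#' CO2 flux carried by an air stream
#'
#' The molar CO2 flux entering or leaving a chamber: air molar flow times CO2
#' mole fraction.
#'
#' @inheritParams slpm_to_molar_flow
#' @param co2_umol_mol CO2 mole fraction in umol mol-1, >= 0.
#' @return CO2 flux in umol s-1.
#' @examples
#' co2_flux(500, 400)  # ~148.7 umol s-1
#' @export
co2_flux <- function(flow_slpm, co2_umol_mol, molar_volume_l = 22.414) {
  if (!is.numeric(co2_umol_mol) || any(!is.finite(co2_umol_mol)) ||
      any(co2_umol_mol < 0)) {
    stop("`co2_umol_mol` must be finite and >= 0", call. = FALSE)
  }
  slpm_to_molar_flow(flow_slpm, molar_volume_l) * co2_umol_mol * 1e-6
}

#' Ratio of CO2 entry rate to net CO2 exchange rate (xi)
#'
#' xi = C_inlet / (C_inlet - C_outlet), the Evans open-system parameter that
#' governs how strongly photosynthetic uptake shifts the chamber-air delta13C.
#' Positive in the light (drawdown), negative in the dark (respiratory
#' enrichment); both are returned as-is and callers select phase from the
#' photoperiod schedule, not from the sign.
#'
#' @param c_inlet,c_outlet CO2 mole fractions at chamber inlet and outlet
#'   (umol mol-1); `c_inlet` > 0.
#' @return Dimensionless xi.
#' @examples
#' chamber_xi(400, 350)  # 12.5 % drawdown -> 8
#' chamber_xi(200, 172)  # the 14 % drawdown operating limit -> 7.14
#' @export
chamber_xi <- function(c_inlet, c_outlet) {
  if (!is.numeric(c_inlet) || any(!is.finite(c_inlet)) || any(c_inlet <= 0)) {
    stop("`c_inlet` must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(c_outlet) || any(!is.finite(c_outlet))) {
    stop("`c_outlet` must be finite numeric", call. = FALSE)
  }
  if (any(c_inlet == c_outlet)) {
    stop("degenerate exchange: c_inlet equals c_outlet, xi undefined",
         call. = FALSE)
  }
  c_inlet / (c_inlet - c_outlet)
}

#' Uncontaminated chamber-outlet delta13C
#'
#' The delta13C that chamber-outlet CO2 would have if all CO2 exchange were
#' photosynthetic uptake with discrimination `disc` (the Evans open-system
#' relation solved for the outlet delta):
#' (Delta + xi * d_in * Delta/1000 + xi * d_in) / ((Delta/1000)(xi - 1) + xi).
#' With `disc = 0` the outlet equals the inlet exactly.
#'
#' @param disc Assumed discrimination Delta13C (permil).
#' @param xi Dimensionless xi from [chamber_xi()].
#' @param delta_inlet delta13C of inlet CO2 (permil VPDB).
#' @return delta13C of uncontaminated outlet CO2 (permil VPDB).
#' @examples
#' delta_outlet_pure(21, 8, -5.6)   # -3.0368
#' delta_outlet_pure(21, 8, -43.5)  # -41.0345
#' @export
delta_outlet_pure <- function(disc, xi, delta_inlet) {
  check_disc(disc)
  check_delta(delta_inlet, "delta_inlet")
  if (!is.numeric(xi) || any(!is.finite(xi))) {
    stop("`xi` must be finite numeric", call. = FALSE)
  }
  denom <- (disc / 1000) * (xi - 1) + xi
  if (any(denom == 0)) {
    stop("singular configuration: (disc/1000)(xi - 1) + xi = 0", call. = FALSE)
  }
  (disc + xi * delta_inlet * disc / 1000 + xi * delta_inlet) / denom
}

#' Contamination-free reference delta13C of assimilated carbon
#'
#' Flux-weighted isotope mass balance over the chamber in the light: the
#' delta13C of the CO2 removed by the stand,
#' (d_in * F_in - d_out_pure * F_out) / (F_in - F_out). When the pure outlet
#' delta comes from [delta_outlet_pure()] with consistent xi this equals the
#' Farquhar tissue delta [tissue_delta_from_source()] applied to chamber air
#' (algebraic identity, enforced by the test suite).
#'
#' @param delta_inlet delta13C of inlet CO2 (permil).
#' @param delta_outlet_pure delta13C of uncontaminated outlet CO2 (permil).
#' @param f_inlet,f_outlet CO2 fluxes in and out (umol s-1); light phase
#'   requires `f_inlet > f_outlet`.
#' @return Reference delta13C (permil VPDB).
#' @examples
#' delta_ref(-5.6, -3.0368, 8, 7)  # -23.5424
#' @export
delta_ref <- function(delta_inlet, delta_outlet_pure, f_inlet, f_outlet) {
  check_delta(delta_inlet, "delta_inlet")
  check_delta(delta_outlet_pure, "delta_outlet_pure")
  if (any(f_inlet == f_outlet)) {
    stop("degenerate exchange: f_inlet equals f_outlet", call. = FALSE)
  }
  if (any(f_inlet < f_outlet)) {
    warning("f_inlet < f_outlet: not a light-phase (net uptake) configuration",
            call. = FALSE)
  }
  (delta_inlet * f_inlet - delta_outlet_pure * f_outlet) / (f_inlet - f_outlet)
}

#' delta13C of respired CO2 from dark-period mass balance
#'
#' In the dark the chamber adds respiratory CO2 to the air stream; inverting
#' the linear delta-weighted two-stream mixing gives the delta13C of the
#' respired CO2: (d_in * F_in - d_out * F_out) / (F_in - F_out).
#'
#' @param delta_inlet,delta_outlet Measured delta13C at inlet and outlet
#'   (permil).
#' @param f_inlet,f_outlet CO2 fluxes (umol s-1); dark phase has
#'   `f_outlet > f_inlet` (a warning is raised otherwise).
#' @return delta13C of respired CO2 (permil VPDB).
#' @examples
#' # forward-mix 10 umol/s at -5.6 with 2 umol/s respired at -26, then invert:
#' out <- (10 * -5.6 + 2 * -26) / 12
#' delta_respired(-5.6, out, 10, 12)  # -26
#' @export
delta_respired <- function(delta_inlet, delta_outlet, f_inlet, f_outlet) {
  check_delta(delta_inlet, "delta_inlet")
  check_delta(delta_outlet, "delta_outlet")
  if (any(f_inlet == f_outlet)) {
    stop("degenerate exchange: f_inlet equals f_outlet", call. = FALSE)
  }
  if (any(f_outlet < f_inlet)) {
    warning("f_outlet < f_inlet: not a dark-phase (net efflux) configuration",
            call. = FALSE)
  }
  (delta_inlet * f_inlet - delta_outlet * f_outlet) / (f_inlet - f_outlet)
}

#' Ground-area-based CO2 exchange rate
#'
#' (F_inlet - F_outlet) / A. Positive values are net uptake (whole-stand net
#' photosynthesis N, light phase); in the dark the rate is negative and its
#' magnitude is the stand respiration rate R_n.
#'
#' @param f_inlet,f_outlet CO2 fluxes (umol s-1).
#' @param area Chamber ground area (m2), > 0.
#' @return Signed exchange rate in umol m-2 s-1.
#' @examples
#' exchange_rate(148.7, 130, 1.5)
#' @export
exchange_rate <- function(f_inlet, f_outlet, area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0)) {
    stop("`area` must be finite and > 0", call. = FALSE)
  }
  (f_inlet - f_outlet) / area
}

#' Mean chamber residence time
#'
#' Chamber volume divided by volumetric air flow; the washout time constant
#' after a perturbation of chamber air.
#'
#' @param volume_l Chamber volume (L), > 0.
#' @param flow_slpm Air flow (SLPM), > 0.
#' @return Residence time in minutes.
#' @examples
#' residence_time(3000, 250)  # 12 min
#' residence_time(3000, 750)  # 4 min
#' @export
residence_time <- function(volume_l, flow_slpm) {
  if (!is.numeric(volume_l) || any(!is.finite(volume_l)) || any(volume_l <= 0)) {
    stop("`volume_l` must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(flow_slpm) || any(!is.finite(flow_slpm)) || any(flow_slpm <= 0)) {
    stop("`flow_slpm` must be finite and > 0", call. = FALSE)
  }
  volume_l / flow_slpm
}

#' Mix CO2 streams isotopically
#'
#' Combine streams with carbon fluxes (or masses) `weights` and isotopic
#' compositions `deltas`. `method = "linear"` is the delta-weighted mean used
#' by the printed mass balances; `method = "exact"` mixes molar 13C and 12C
#' amounts and re-expresses the result in delta notation. At natural-abundance
#' delta ranges the two differ by well under 0.01 permil (quantified by the
#' test suite).
#'
#' @param deltas delta13C of each stream (permil VPDB).
#' @param weights Non-negative carbon amounts or fluxes; at least one > 0.
#' @param method "linear" (default) or "exact".
#' @return delta13C of the mixture (permil VPDB).
#' @examples
#' mix_delta(c(-20, -30), c(1, 1))
#' @export
mix_delta <- function(deltas, weights, method = c("linear", "exact")) {
  method <- match.arg(method)
  check_delta(deltas, "deltas")
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("`weights` must be >= 0 with positive total", call. = FALSE)
  }
  if (method == "linear") {
    sum(deltas * weights) / sum(weights)
  } else {
    r <- delta_to_ratio(deltas)
    c12 <- weights / (1 + r)
    c13 <- weights * r / (1 + r)
    ratio_to_delta(sum(c13) / sum(c12))
  }
}

#' Pair inlet and outlet records of a chamber log
#'
#' Chamber logs are long-format tables with one row per measurement at either
#' the inlet or the outlet. Analysis needs them paired: each outlet record is
#' matched to the nearest-in-time inlet record of the same chamber within
#' `window_min` minutes (facility sampling alternates the two within a few
#' minutes). Unmatched outlet records are dropped with a warning.
#'
#' @param records Chamber log tibble with columns `timestamp`, `chamber_id`,
#'   `location` ("inlet"/"outlet"), `co2_umol_mol`, `flow_slpm`,
#'   `d13c_permil`. A `retained` column (from [qc_flags()]) is honoured if
#'   present.
#' @param window_min Maximum pairing separation in minutes (default 3).
#' @return Tibble with one row per pair: `timestamp` (outlet time),
#'   `chamber_id`, `c_inlet`, `c_outlet`, `delta_inlet`, `delta_outlet`,
#'   `flow_slpm`.
#' @export
pair_chamber_records <- function(records, window_min = 3) {
  stopifnot(is.data.frame(records))
  if ("retained" %in% names(records)) {
    records <- records[records$retained, , drop = FALSE]
  }
  out <- lapply(split(records, records$chamber_id), function(rec) {
    inl <- rec[rec$location == "inlet", , drop = FALSE]
    outl <- rec[rec$location == "outlet", , drop = FALSE]
    if (nrow(inl) == 0L || nrow(outl) == 0L) return(NULL)
    it <- as.numeric(inl$timestamp)
    ot <- as.numeric(outl$timestamp)
    idx <- vapply(ot, function(t) which.min(abs(it - t)), integer(1))
    sep_min <- abs(it[idx] - ot) / 60
    keep <- sep_min <= window_min
    if (!all(keep)) {
      warning(sum(!keep), " outlet record(s) without an inlet match within ",
              window_min, " min were dropped", call. = FALSE)
    }
    tibble::tibble(
      timestamp = outl$timestamp[keep],
      chamber_id = outl$chamber_id[keep],
      c_inlet = inl$co2_umol_mol[idx][keep],
      c_outlet = outl$co2_umol_mol[keep],
      delta_inlet = inl$d13c_permil[idx][keep],
      delta_outlet = outl$d13c_permil[keep],
      flow_slpm = inl$flow_slpm[idx][keep]
    )
  })
  dplyr::bind_rows(out)
}

#' Per-pair chamber fluxes and exchange rates
#'
#' Augments a paired chamber log (see [pair_chamber_records()]) with CO2
#' fluxes, xi and the ground-area exchange rate. Outlet air flow is assumed
#' equal to inlet air flow unless a `flow_outlet_slpm` column is present.
#'
#' @param paired Output of [pair_chamber_records()].
#' @param area Chamber ground area (m2).
#' @param molar_volume_l See [slpm_to_molar_flow()].
#' @return `paired` with added columns `f_inlet`, `f_outlet`, `xi`,
#'   `rate_per_area`.
#' @export
chamber_fluxes <- function(paired, area = 1.5, molar_volume_l = 22.414) {
  flow_out <- if ("flow_outlet_slpm" %in% names(paired)) {
    paired$flow_outlet_slpm
  } else {
    paired$flow_slpm
  }
  paired$f_inlet <- co2_flux(paired$flow_slpm, paired$c_inlet, molar_volume_l)
  paired$f_outlet <- co2_flux(flow_out, paired$c_outlet, molar_volume_l)
  paired$xi <- chamber_xi(paired$c_inlet, paired$c_outlet)
  paired$rate_per_area <- exchange_rate(paired$f_inlet, paired$f_outlet, area)
  paired
}
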