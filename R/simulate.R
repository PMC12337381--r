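#' Configuration of a virtual two-chamber labelling experiment
#'
#' Describes a pair of parallel chambers identical in every respect except the
#' delta13C of the CO2 supplied to them (defaults: mineral -5.6 permil vs
#' fossil-organic -43.5 permil). Defaults emulate the mesocosm facility the
#' package models: 3000 L chambers with 1.5 m2 ground area, 250-750 SLPM air
#' supply, target CO2 of 200/400/800 umol mol-1 with photosynthetic drawdown
#' capped at 14 %, a 16 h / 8 h photoperiod, ~30 min measurement cycles, and
#' instrument noise of ~0.2 permil on gas delta13C.
#'
#' @param target_co2 Inlet CO2 mole fraction (umol mol-1).
#' @param source_delta_enriched,source_delta_depleted delta13C of the two CO2
#'   supplies (permil VPDB).
#' @param true_discrimination Ground-truth Delta13C (permil).
#' @param drawdown_fraction Photosynthetic CO2 drawdown, in (0, 0.14].
#'   Default 0.125 (typical operation below the 14 % cap; gives xi = 8).
#' @param flow_slpm Air supply (SLPM).
#' @param volume_l Chamber volume (L).
#' @param ground_area_m2 Ground area (m2).
#' @param pp A [photoperiod()].
#' @param sampling_interval_min Measurement cycle length (minutes).
#' @param days Number of simulated days.
#' @param start First lights-on instant (POSIXct, UTC).
#' @param noise_delta_gas SD of gas delta13C measurement noise (permil).
#' @param noise_co2 SD of CO2 measurement noise (umol mol-1).
#' @param noise_delta_sample SD of sample delta13C noise (permil); the
#'   whole-system value integrating chamber operation and sample processing.
#' @param true_f_contam Ground-truth contamination fraction shared by all
#'   sample kinds (and, by default, by the respiratory substrate).
#' @param extraneous_delta delta13C of contaminating CO2 (permil). `NULL`
#'   uses the fifty-fifty source mixture plus the ~3 permil photosynthetic
#'   chamber enrichment: 0.5*(-43.5) + 0.5*(-5.6) + 3 = -21.55 permil.
#' @param injection_fraction Fraction of chamber CO2 replaced by extraneous
#'   CO2 at each door-opening bout (washout perturbation of the gas record).
#' @param bout_start_min Start times of daytime chamber-access bouts, in
#'   minutes after lights-on. Each bout is three door openings 10 min apart
#'   (entering, sampling, leaving).
#' @param respiration_rate Dark-period stand respiration (umol m-2 s-1).
#' @param f_substrate Contamination fraction of the respiratory substrate
#'   (`NULL` = `true_f_contam`, respiration of in vivo contaminated WSC).
#' @param n_replicates Plant sample replicates per chamber and kind.
#' @param seed Integer RNG seed; identical seeds give identical experiments.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(target_co2 = 400,
                              source_delta_enriched = -5.6,
                              source_delta_depleted = -43.5,
                              true_discrimination = 21,
                              drawdown_fraction = 0.125,
                              flow_slpm = 500,
                              volume_l = 3000,
                              ground_area_m2 = 1.5,
                              pp = photoperiod(),
                              sampling_interval_min = 30,
                              days = 3,
                              start = as.POSIXct("2021-06-01 06:00:00", tz = "UTC"),
                              noise_delta_gas = 0.2,
                              noise_co2 = 1,
                              noise_delta_sample = 0.4,
                              true_f_contam = 0.033,
                              extraneous_delta = NULL,
                              injection_fraction = 0.1,
                              bout_start_min = c(360, 900),
                              respiration_rate = 4,
                              f_substrate = NULL,
                              n_replicates = 2,
                              seed = 1L) {
  if (drawdown_fraction <= 0 || drawdown_fraction > 0.14) {
    stop("`drawdown_fraction` must lie in (0, 0.14]", call. = FALSE)
  }
  if (source_delta_enriched <= source_delta_depleted) {
    stop("`source_delta_enriched` must exceed `source_delta_depleted`",
         call. = FALSE)
  }
  if (true_f_contam < 0 || true_f_contam > 1) {
    stop("`true_f_contam` must lie in [0, 1]", call. = FALSE)
  }
  if (injection_fraction < 0 || injection_fraction >= 1) {
    stop("`injection_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(extraneous_delta)) {
    extraneous_delta <-
      0.5 * source_delta_depleted + 0.5 * source_delta_enriched + 3
  }
  cfg <- list(
    target_co2 = target_co2,
    source_delta_enriched = source_delta_enriched,
    source_delta_depleted = source_delta_depleted,
    true_discrimination = true_discrimination,
    drawdown_fraction = drawdown_fraction,
    flow_slpm = flow_slpm, volume_l = volume_l,
    ground_area_m2 = ground_area_m2, pp = pp,
    sampling_interval_min = sampling_interval_min,
    days = days, start = start,
    noise_delta_gas = noise_delta_gas, noise_co2 = noise_co2,
    noise_delta_sample = noise_delta_sample,
    true_f_contam = true_f_contam,
    extraneous_delta = extraneous_delta,
    injection_fraction = injection_fraction,
    bout_start_min = bout_start_min,
    respiration_rate = respiration_rate,
    f_substrate = f_substrate %||% true_f_contam,
    n_replicates = n_replicates,
    seed = as.integer(seed)
  )
  structure(cfg, class = "simulation_config")
}

# chamber ids and steady-state (noise-free) per-chamber truths
sim_chambers <- function(cfg) {
  tibble::tibble(
    chamber_id = c(paste0("ENR", cfg$target_co2), paste0("DEP", cfg$target_co2)),
    role = c("enriched", "depleted"),
    source_delta = c(cfg$source_delta_enriched, cfg$source_delta_depleted),
    target_co2 = cfg$target_co2
  )
}

sim_truth_chamber <- function(cfg) {
  ch <- sim_chambers(cfg)
  xi_true <- 1 / cfg$drawdown_fraction
  ch$xi_true <- xi_true
  ch$c_outlet_true <- cfg$target_co2 * (1 - cfg$drawdown_fraction)
  ch$delta_outlet_pure_true <-
    delta_outlet_pure(cfg$true_discrimination, xi_true, ch$source_delta)
  ch$tissue_delta_true <-
    tissue_delta_from_source(ch$delta_outlet_pure_true, cfg$true_discrimination)
  ch
}

# door-opening times (seconds offsets into one day) for the default bouts
sim_door_offsets <- function(cfg) {
  as.vector(outer(c(0, 10, 20), cfg$bout_start_min, `+`)) * 60
}

#' Simulate one light period of the chamber pair
#'
#' Steady-state open-system records at the sampling interval: outlet CO2 is
#' inlet times (1 - drawdown) and outlet delta13C follows the Evans relation
#' at the true discrimination, plus Gaussian measurement noise. Door-opening
#' bouts inject extraneous CO2 that washes out exponentially with time
#' constant volume/flow (see [inject_contamination()]).
#'
#' @param cfg A [simulation_config()].
#' @param day Day index (1-based).
#' @return Long-format chamber log tibble (both chambers, inlet and outlet
#'   rows).
#' @export
simulate_steady_day <- function(cfg, day = 1) {
  truth <- sim_truth_chamber(cfg)
  day0 <- cfg$start + (day - 1) * 86400
  t_off <- seq(0, cfg$pp$light_hours * 60 - 1, by = cfg$sampling_interval_min) * 60
  times <- day0 + t_off
  tau_min <- residence_time(cfg$volume_l, cfg$flow_slpm)
  ev_off <- sim_door_offsets(cfg)

  rows <- lapply(seq_len(nrow(truth)), function(i) {
    n <- length(times)
    dop <- truth$delta_outlet_pure_true[i] +
      inject_contamination(t_off, ev_off, cfg$injection_fraction,
                           cfg$extraneous_delta,
                           truth$delta_outlet_pure_true[i], tau_min)
    inlet <- tibble::tibble(
      timestamp = times, chamber_id = truth$chamber_id[i], location = "inlet",
      co2_umol_mol = cfg$target_co2 + stats::rnorm(n, 0, cfg$noise_co2),
      flow_slpm = cfg$flow_slpm,
      d13c_permil = truth$source_delta[i] + stats::rnorm(n, 0, cfg$noise_delta_gas)
    )
    outlet <- tibble::tibble(
      timestamp = times + 90, chamber_id = truth$chamber_id[i],
      location = "outlet",
      co2_umol_mol = truth$c_outlet_true[i] + stats::rnorm(n, 0, cfg$noise_co2),
      flow_slpm = cfg$flow_slpm,
      d13c_permil = dop + stats::rnorm(n, 0, cfg$noise_delta_gas)
    )
    dplyr::bind_rows(inlet, outlet)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$timestamp, .data$chamber_id)
}

#' Washout perturbation of chamber-air delta13C after injection events
#'
#' A door opening instantaneously replaces fraction `phi` of the well-mixed
#' chamber CO2 with extraneous CO2 of delta13C `delta_c`; the perturbation
#' then relaxes exponentially toward supply conditions with the residence
#' time constant tau = volume/flow. Returns the summed perturbation (permil)
#' at each requested time.
#'
#' @param t_sec Times at which to evaluate (seconds, same clock as
#'   `event_sec`).
#' @param event_sec Event instants (seconds).
#' @param phi Injected fraction in `[0, 1)`.
#' @param delta_c delta13C of the extraneous CO2 (permil).
#' @param delta_ss Unperturbed chamber-air delta13C (permil).
#' @param tau_min Washout time constant (minutes).
#' @return Numeric perturbation vector (permil), zero before each event.
#' @export
inject_contamination <- function(t_sec, event_sec, phi, delta_c, delta_ss,
                                 tau_min) {
  if (phi < 0 || phi >= 1) stop("invalid event: phi must be in [0, 1)", call. = FALSE)
  if (!length(event_sec) || phi == 0) return(rep(0, length(t_sec)))
  amp <- phi * (delta_c - delta_ss)
  pert <- rep(0, length(t_sec))
  for (e in event_sec) {
    dt <- t_sec - e
    pert <- pert + ifelse(dt >= 0, amp * exp(-dt / (tau_min * 60)), 0)
  }
  pert
}

#' Simulate one dark period of the chamber pair
#'
#' Respiration adds CO2 to the air stream at `respiration_rate`; the outlet
#' CO2 rises above the inlet accordingly and the outlet delta13C is the
#' flux-weighted mixture of supply CO2 and respired CO2. The respired
#' delta13C reflects a substrate formed from chamber air under the true
#' discrimination, with fraction `f_substrate` of contaminant-derived carbon.
#'
#' @inheritParams simulate_steady_day
#' @return Long-format chamber log tibble (dark phase).
#' @export
simulate_night <- function(cfg, day = 1) {
  stopifnot(cfg$respiration_rate > 0)
  truth <- sim_truth_chamber(cfg)
  day0 <- cfg$start + (day - 1) * 86400
  light_min <- cfg$pp$light_hours * 60
  t_off <- seq(light_min, 1440 - 1, by = cfg$sampling_interval_min) * 60
  times <- day0 + t_off
  air_molar <- slpm_to_molar_flow(cfg$flow_slpm)
  f_in <- co2_flux(cfg$flow_slpm, cfg$target_co2)
  r_flux <- cfg$respiration_rate * cfg$ground_area_m2
  f_out <- f_in + r_flux
  c_out <- f_out / air_molar * 1e6

  rows <- lapply(seq_len(nrow(truth)), function(i) {
    n <- length(times)
    tissue_air <- tissue_delta_from_source(truth$delta_outlet_pure_true[i],
                                           cfg$true_discrimination)
    tissue_cont <- tissue_delta_from_source(cfg$extraneous_delta,
                                            cfg$true_discrimination)
    delta_resp <- (1 - cfg$f_substrate) * tissue_air +
      cfg$f_substrate * tissue_cont
    delta_out <- (truth$source_delta[i] * f_in + delta_resp * r_flux) / f_out
    inlet <- tibble::tibble(
      timestamp = times, chamber_id = truth$chamber_id[i], location = "inlet",
      co2_umol_mol = cfg$target_co2 + stats::rnorm(n, 0, cfg$noise_co2),
      flow_slpm = cfg$flow_slpm,
      d13c_permil = truth$source_delta[i] + stats::rnorm(n, 0, cfg$noise_delta_gas)
    )
    outlet <- tibble::tibble(
      timestamp = times + 90, chamber_id = truth$chamber_id[i],
      location = "outlet",
      co2_umol_mol = c_out + stats::rnorm(n, 0, cfg$noise_co2),
      flow_slpm = cfg$flow_slpm,
      d13c_permil = delta_out + stats::rnorm(n, 0, cfg$noise_delta_gas)
    )
    dplyr::bind_rows(inlet, outlet)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$timestamp, .data$chamber_id)
}

# nominal plant-sample composition: dry mass (g) per kind, and the carbon
# fraction used to derive sample carbon mass
sim_sample_masses <- function() {
  tibble::tibble(
    sample_kind = c("shoot", "root", "fructan", "sucrose", "glucose", "fructose"),
    dry_mass_g = c(10, 3, 1.5, 0.5, 0.25, 0.25),
    c_fraction = c(0.42, 0.42, unname(carbon_fractions()[c("fructan", "sucrose",
                                                           "glucose", "fructose")]))
  )
}

#' Simulate the plant and carbohydrate sample set
#'
#' Each sample's delta13C is the contamination-weighted mixture of tissue
#' formed from chamber air and tissue formed from the extraneous CO2, both
#' under the true discrimination, plus whole-system measurement noise. Both
#' chambers receive the identical contamination fraction and extraneous
#' delta13C (the defining property of the paired-chamber design).
#'
#' @param cfg A [simulation_config()].
#' @return Sample table tibble: `sample_id`, `chamber_id`, `sample_kind`,
#'   `replicate`, `dry_mass_g`, `carbon_mass_g`, `d13c_permil`.
#' @export
simulate_samples <- function(cfg) {
  truth <- sim_truth_chamber(cfg)
  kinds <- sim_sample_masses()
  tissue_cont <- tissue_delta_from_source(cfg$extraneous_delta,
                                          cfg$true_discrimination)
  grid <- expand.grid(ki = seq_len(nrow(kinds)), rep = seq_len(cfg$n_replicates),
                      ci = seq_len(nrow(truth)))
  f <- cfg$true_f_contam
  delta_true <- (1 - f) * truth$tissue_delta_true[grid$ci] + f * tissue_cont
  tibble::tibble(
    sample_id = sprintf("%s_%s_r%d", truth$chamber_id[grid$ci],
                        kinds$sample_kind[grid$ki], grid$rep),
    chamber_id = truth$chamber_id[grid$ci],
    sample_kind = kinds$sample_kind[grid$ki],
    replicate = grid$rep,
    dry_mass_g = kinds$dry_mass_g[grid$ki],
    carbon_mass_g = kinds$dry_mass_g[grid$ki] * kinds$c_fraction[grid$ki],
    d13c_permil = delta_true +
      stats::rnorm(nrow(grid), 0, cfg$noise_delta_sample)
  )
}

#' Run a complete virtual two-chamber experiment
#'
#' Seeds the RNG from `cfg$seed` and generates the full data products of one
#' paired-chamber run: multi-day chamber logs (light and dark), the
#' door-opening event log, the plant and carbohydrate sample table, the
#' chamber description table, and the ground truth against which estimates
#' can be validated. Identical seeds give identical outputs.
#'
#' @param cfg A [simulation_config()].
#' @return A `virtual_experiment` list with elements `chamber_log`, `events`,
#'   `samples`, `chambers`, `truth` (list of per-chamber truths, sample-kind
#'   contamination, extraneous delta13C, and the true reference difference)
#'   and `config`.
#' @export
run_virtual_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  logs <- lapply(seq_len(cfg$days), function(d) {
    dplyr::bind_rows(simulate_steady_day(cfg, d), simulate_night(cfg, d))
  })
  chamber_log <- dplyr::bind_rows(logs)

  truth <- sim_truth_chamber(cfg)
  ev_off <- sim_door_offsets(cfg)
  events <- do.call(rbind, lapply(seq_len(cfg$days), function(d) {
    expand.grid(off = ev_off, chamber_id = truth$chamber_id,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  events$timestamp <- rep(cfg$start, nrow(events)) +
    rep((seq_len(cfg$days) - 1) * 86400, each = length(ev_off) * nrow(truth)) +
    events$off
  events <- tibble::tibble(timestamp = events$timestamp,
                           chamber_id = events$chamber_id,
                           event_kind = "door_opening")

  samples <- simulate_samples(cfg)

  d_delta_ref_true <- truth$tissue_delta_true[truth$role == "enriched"] -
    truth$tissue_delta_true[truth$role == "depleted"]
  structure(list(
    chamber_log = chamber_log,
    events = events,
    samples = samples,
    chambers = sim_chambers(cfg),
    truth = list(
      chamber = truth,
      f_contam = cfg$true_f_contam,
      f_substrate = cfg$f_substrate,
      extraneous_delta = cfg$extraneous_delta,
      d_delta_ref = d_delta_ref_true
    ),
    config = cfg
  ), class = "virtual_experiment")
}

#' @export
print.virtual_experiment <- function(x, ...) {
  cat("<virtual_experiment>\n")
  cat(sprintf("  target CO2 %g umol/mol, %d day(s), %d chamber-log records\n",
              x$config$target_co2, x$config$days, nrow(x$chamber_log)))
  cat(sprintf("  true f_contam %.4f, true d_delta_ref %.4f permil\n",
              x$truth$f_contam, x$truth$d_delta_ref))
  invisible(x)
}
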