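# shared deterministic fixtures for the suite

# a quiet, measurement-noise-free experiment: the generator's exact inverse
noise_free_config <- function(f = 0.03, target_co2 = 400, days = 1,
                              seed = 101, ...) {
  simulation_config(target_co2 = target_co2, days = days,
                    noise_delta_gas = 0, noise_co2 = 0,
                    noise_delta_sample = 0,
                    true_f_contam = f, seed = seed, ...)
}

run_noise_free <- function(f = 0.03, target_co2 = 400, ...) {
  run_virtual_experiment(noise_free_config(f = f, target_co2 = target_co2, ...))
}

estimate_quiet <- function(ex, ...) {
  suppressWarnings(estimate_contamination(ex$chamber_log, ex$samples,
                                          ex$chambers, ex$events, ...))
}

# small synthetic chamber log without the simulator, for QC unit tests
tiny_log <- function(times_min, chamber_id = "A", location = "outlet",
                     co2 = 400, d13c = -5, day0 = as.POSIXct("2021-06-01 06:00:00",
                                                             tz = "UTC")) {
  tibble::tibble(
    timestamp = day0 + times_min * 60,
    chamber_id = chamber_id, location = location,
    co2_umol_mol = co2, flow_slpm = 500, d13c_permil = d13c
  )
}
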