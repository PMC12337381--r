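test_that("config validation enforces the operating envelope", {
  expect_error(simulation_config(drawdown_fraction = 0.2), "0.14")
  expect_error(simulation_config(drawdown_fraction = 0), "0.14")
  expect_error(simulation_config(true_f_contam = 1.5), "0, 1")
  expect_error(simulation_config(injection_fraction = 1), "0, 1")
  expect_error(simulation_config(source_delta_enriched = -50), "exceed")
  # fifty-fifty mixture default for the extraneous CO2
  cfg <- simulation_config()
  expect_equal(cfg$extraneous_delta, 0.5 * -43.5 + 0.5 * -5.6 + 3)
  expect_equal(cfg$extraneous_delta, -21.55)
})

test_that("steady light-phase records carry the Evans outlet enrichment", {
  cfg <- noise_free_config()
  day <- simulate_steady_day(cfg)
  # photosynthesis enriches chamber air by roughly 3 permil
  enr <- day[day$chamber_id == "ENR400", ]
  d_in <- mean(enr$d13c_permil[enr$location == "inlet"])
  d_out <- mean(enr$d13c_permil[enr$location == "outlet"])
  expect_gt(d_out - d_in, 2); expect_lt(d_out - d_in, 3.5)
  expect_equal(d_in, -5.6)

  # without injections the noise-free outlet equals the worked value at xi = 8
  clean <- simulate_steady_day(noise_free_config(injection_fraction = 0))
  d_out_clean <- unique(clean$d13c_permil[clean$chamber_id == "ENR400" &
                                            clean$location == "outlet"])
  expect_equal(d_out_clean, -3.0368, tolerance = 1e-4)

  # with no injections and f = 0, the sample and the outlet air recover the
  # true discrimination exactly
  cfg0 <- noise_free_config(f = 0, injection_fraction = 0)
  day0 <- simulate_steady_day(cfg0)
  s0 <- simulate_samples(cfg0)
  out0 <- day0$d13c_permil[day0$chamber_id == "ENR400" &
                             day0$location == "outlet"][1]
  shoot0 <- s0$d13c_permil[s0$chamber_id == "ENR400" &
                             s0$sample_kind == "shoot"][1]
  expect_equal(discrimination_from_sample(out0, shoot0), 21, tolerance = 1e-9)
})

test_that("injection washout follows the closed-form exponential", {
  # tau at 250 SLPM and 3000 L is 12 min; residual after 45 min ~ 2.4 %
  expect_equal(residence_time(3000, 250), 12)
  pert <- inject_contamination(c(0, 45 * 60), 0, 0.5, -21.55, -3, 12)
  expect_equal(pert[1], 0.5 * (-21.55 - -3))
  expect_equal(pert[2] / pert[1], exp(-45 / 12), tolerance = 1e-12)
  expect_lt(abs(exp(-45 / 12) - 0.024), 1e-3)

  # zero injected fraction leaves the trajectory unchanged
  expect_equal(inject_contamination(0:10, 0, 0, -21.55, -3, 12), rep(0, 11))
  # before the event there is no perturbation
  expect_equal(inject_contamination(-5, 0, 0.3, -21.55, -3, 12), 0)
  expect_error(inject_contamination(0, 0, 1, -21.55, -3, 12), "invalid event")
})

test_that("simulated samples encode the contamination mixture exactly", {
  cfg <- noise_free_config(f = 0)
  s0 <- simulate_samples(cfg)
  truth <- isocontam:::sim_truth_chamber(cfg)
  for (ch in truth$chamber_id) {
    expect_equal(
      unique(s0$d13c_permil[s0$chamber_id == ch]),
      truth$tissue_delta_true[truth$chamber_id == ch])
  }
  # full contamination: identical sample delta in both chambers
  cfg1 <- noise_free_config(f = 1)
  s1 <- simulate_samples(cfg1)
  shoot <- s1[s1$sample_kind == "shoot" & s1$replicate == 1, ]
  expect_equal(diff(shoot$d13c_permil), 0)
})

test_that("dark-phase mass balance returns the respired substrate delta", {
  cfg <- noise_free_config(f = 0.04)
  night <- simulate_night(cfg)
  truth <- isocontam:::sim_truth_chamber(cfg)
  p <- pair_chamber_records(night)
  p <- chamber_fluxes(p)
  p$delta_rn <- delta_respired(p$delta_inlet, p$delta_outlet,
                               p$f_inlet, p$f_outlet)
  for (ch in truth$chamber_id) {
    tissue_air <- tissue_delta_from_source(
      truth$delta_outlet_pure_true[truth$chamber_id == ch], 21)
    tissue_cont <- tissue_delta_from_source(cfg$extraneous_delta, 21)
    want <- 0.96 * tissue_air + 0.04 * tissue_cont
    expect_equal(unique(round(p$delta_rn[p$chamber_id == ch], 10)),
                 round(want, 10))
  }
  # outlet CO2 rises above inlet in the dark
  expect_true(all(p$c_outlet > p$c_inlet))
})

test_that("identical seeds give identical experiments, different seeds differ", {
  cfg <- simulation_config(days = 1, seed = 77)
  a <- run_virtual_experiment(cfg)
  b <- run_virtual_experiment(cfg)
  expect_identical(a$chamber_log, b$chamber_log)
  expect_identical(a$samples, b$samples)
  expect_identical(a$events, b$events)
  cfg2 <- simulation_config(days = 1, seed = 78)
  c <- run_virtual_experiment(cfg2)
  expect_false(identical(a$chamber_log, c$chamber_log))
})

test_that("noise-free pipeline recovers injected contamination exactly", {
  for (f in c(0, 0.01, 0.1, 0.5)) {
    ex <- run_noise_free(f = f)
    an <- estimate_quiet(ex)
    expect_lt(max(abs(an$estimates$f_contam - f)), 1e-9)
  }
})

test_that("respiration contamination tracks biomass contamination", {
  # substrate drawn from the in vivo contaminated WSC pool: the respiration
  # estimate equals the biomass estimate at matched settings
  ex <- run_noise_free(f = 0.06)
  an <- estimate_quiet(ex)
  resp <- an$estimates$f_contam[an$estimates$sample_kind == "respiration"]
  shoot <- an$estimates$f_contam[an$estimates$sample_kind == "shoot"]
  expect_equal(mean(resp), mean(shoot), tolerance = 1e-9)
})
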