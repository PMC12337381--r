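test_that("SLPM conversion and CO2 flux follow the declared standard", {
  expect_equal(slpm_to_molar_flow(0), 0)
  expect_equal(slpm_to_molar_flow(1), 1e6 / 22.414 / 60)
  expect_equal(slpm_to_molar_flow(1), 743.58, tolerance = 1e-5)
  expect_equal(slpm_to_molar_flow(750), 5.5769e5, tolerance = 1e-4)
  expect_error(slpm_to_molar_flow(-1), ">= 0")

  expect_equal(co2_flux(500, 0), 0)
  expect_equal(co2_flux(500, 400), 148.7, tolerance = 1e-3)
  # same product from different factors
  expect_equal(co2_flux(500, 400), co2_flux(250, 800))
  # a different vendor molar volume scales the flux
  expect_equal(co2_flux(500, 400, molar_volume_l = 24.0),
               co2_flux(500, 400) * 22.414 / 24.0)
})

test_that("xi follows the drawdown ratio and rejects zero net exchange", {
  expect_equal(chamber_xi(400, 350), 8)
  expect_equal(chamber_xi(200, 172), 200 / 28)  # the 14 % drawdown cap
  expect_error(chamber_xi(400, 400), "degenerate exchange")
  # dark-phase enrichment gives a negative xi, returned as-is
  expect_lt(chamber_xi(400, 420), 0)
})

test_that("pure outlet delta13C reproduces the worked chamber values", {
  expect_equal(delta_outlet_pure(0, 8, -5.6), -5.6)
  expect_equal(delta_outlet_pure(21, 8, -5.6), -3.0368, tolerance = 1e-4)
  expect_equal(delta_outlet_pure(21, 8, -43.5), -41.0345, tolerance = 1e-4)
  # singular denominator: (disc/1000)(xi-1) + xi = 0
  disc <- 21
  xi_bad <- (disc / 1000) / (disc / 1000 + 1)  # solves the denominator = 0
  expect_error(delta_outlet_pure(disc, xi_bad, -5.6), "singular")
})

test_that("reference delta13C matches the flux mass balance worked values", {
  expect_equal(delta_ref(-10, -10, 8, 7), -10)
  expect_equal(delta_ref(-5.6, -3.0368, 8, 7), 8 * -5.6 - 7 * -3.0368)
  expect_equal(delta_ref(-5.6, -3.0368, 8, 7), -23.5424, tolerance = 1e-4)
  expect_equal(delta_ref(-43.5, -41.0345, 8, 7), -60.7585, tolerance = 1e-4)
  expect_error(delta_ref(-5.6, -3, 8, 8), "degenerate exchange")
  expect_warning(delta_ref(-5.6, -3, 7, 8), "light-phase")
})

test_that("flux route and Farquhar relation agree on the reference delta", {
  grid <- expand.grid(disc = seq(0, 40, by = 2), xi = seq(2, 100, by = 7),
                      din = seq(-50, 0, by = 10))
  dop <- delta_outlet_pure(grid$disc, grid$xi, grid$din)
  ref_flux <- delta_ref(grid$din, dop, grid$xi, grid$xi - 1)
  ref_farq <- tissue_delta_from_source(dop, grid$disc)
  expect_lt(max(abs(ref_flux - ref_farq)), 1e-9)
})

test_that("respired delta13C inverts forward two-stream mixing exactly", {
  # mix 10 umol/s at -5.6 with 2 umol/s respired at -26
  out <- (10 * -5.6 + 2 * -26) / 12
  expect_equal(out, -9.0)
  expect_equal(delta_respired(-5.6, out, 10, 12), -26)
  # second worked mix
  out2 <- (100 * -43.5 + 5 * -63) / 105
  expect_equal(out2, -44.4286, tolerance = 1e-4)
  expect_equal(delta_respired(-43.5, out2, 100, 105), -63)
  # respiration at inlet delta leaves the outlet at inlet delta
  expect_equal(delta_respired(-5.6, -5.6, 10, 12), -5.6)
  expect_warning(delta_respired(-5.6, -6, 12, 10), "dark-phase")

  # randomised forward-mix / invert round trip to 1e-10 permil
  set.seed(42)
  for (i in 1:50) {
    f_in <- runif(1, 50, 200); r <- runif(1, 1, 20)
    d_in <- runif(1, -45, -5); d_resp <- runif(1, -70, -20)
    d_out <- (d_in * f_in + d_resp * r) / (f_in + r)
    expect_equal(delta_respired(d_in, d_out, f_in, f_in + r), d_resp,
                 tolerance = 1e-10)
  }
})

test_that("exchange rate carries the uptake sign convention", {
  expect_equal(exchange_rate(148.7, 130.0, 1.5), 18.7 / 1.5)
  expect_equal(exchange_rate(100, 100, 2), 0)
  expect_equal(exchange_rate(10, 12, 1.5), -2 / 1.5)
  expect_error(exchange_rate(10, 12, 0), "> 0")
})

test_that("residence time spans the facility's design range", {
  expect_equal(residence_time(3000, 250), 12)
  expect_equal(residence_time(3000, 750), 4)
  expect_equal(residence_time(3000, 3000), 1)
  expect_error(residence_time(3000, 0), "> 0")
})

test_that("xi from concentrations equals the flux ratio form", {
  set.seed(7)
  for (i in 1:30) {
    c_in <- runif(1, 150, 900); dd <- runif(1, 0.01, 0.14)
    c_out <- c_in * (1 - dd); flow <- runif(1, 250, 750)
    f_in <- co2_flux(flow, c_in); f_out <- co2_flux(flow, c_out)
    expect_equal(chamber_xi(c_in, c_out), f_in / (f_in - f_out),
                 tolerance = 1e-12)
  }
})

test_that("linear and exact isotope mixing differ below 0.01 permil here", {
  set.seed(8)
  for (i in 1:40) {
    d <- runif(3, -65, 0); w <- runif(3, 0.1, 10)
    lin <- mix_delta(d, w, "linear"); exa <- mix_delta(d, w, "exact")
    expect_lt(abs(lin - exa), 0.01)
  }
  # equal-weight symmetry
  expect_equal(mix_delta(c(-20, -30), c(1, 1)), -25)
})

test_that("inlet/outlet pairing matches nearest records within the window", {
  day0 <- as.POSIXct("2021-06-01 06:00:00", tz = "UTC")
  log <- dplyr::bind_rows(
    tiny_log(c(0, 30, 60), location = "inlet", co2 = 400, d13c = -5.6),
    tiny_log(c(1.5, 31.5, 61.5), location = "outlet", co2 = 350, d13c = -3)
  )
  p <- pair_chamber_records(log)
  expect_equal(nrow(p), 3)
  expect_equal(p$c_inlet, rep(400, 3))
  expect_equal(p$c_outlet, rep(350, 3))

  # an outlet 10 min from any inlet is dropped with a warning
  log2 <- dplyr::bind_rows(log, tiny_log(100, location = "outlet"))
  expect_warning(p2 <- pair_chamber_records(log2), "dropped")
  expect_equal(nrow(p2), 3)

  fl <- chamber_fluxes(p, area = 1.5)
  expect_equal(fl$xi, rep(8, 3))
  expect_true(all(fl$f_inlet > fl$f_outlet))
})
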