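ref21 <- function(xi = 8) {
  chamber_reference(-5.6, xi, 21) - chamber_reference(-43.5, xi, 21)
}

test_that("reference difference matches the worked chamber values", {
  expect_equal(reference_difference(-23.5424, -60.7585), 37.2161)
  expect_warning(d0 <- reference_difference(-20, -20), "swapped")
  expect_equal(d0, 0)
  # small-drawdown limit: straight Farquhar difference
  expect_equal(tissue_delta_from_source(-5.6, 21) -
                 tissue_delta_from_source(-43.5, 21),
               37.9 / 1.021)
  expect_equal(37.9 / 1.021, 37.12, tolerance = 1e-4)
})

test_that("contamination fraction behaves at its anchors and rejects bad refs", {
  expect_equal(contamination_fraction(37.2161, 37.2161), 0)
  expect_equal(contamination_fraction(0, 37.2161), 1)
  expect_equal(contamination_fraction(35.70, 37.2161), 0.0407, tolerance = 1e-3)
  # noise can push the estimate negative; it is reported, not clipped
  expect_lt(contamination_fraction(38, 37.2161), 0)
  expect_error(contamination_fraction(35, 0), "invalid reference")
  expect_error(contamination_fraction(35, -2), "invalid reference")
})

test_that("signal, propagated SD and CV reproduce the error-budget numbers", {
  dref <- ref21()
  expect_equal(dref, 37.2161, tolerance = 1e-4)
  expect_equal(signal_for_fraction(0.03, dref), 1.1, tolerance = 0.02)
  expect_equal(signal_for_fraction(0, dref), 0)
  expect_equal(signal_for_fraction(1, dref), dref)

  expect_equal(whole_system_sd(0.4), 0.4 * sqrt(2))
  expect_equal(round(whole_system_sd(0.4), 2), 0.57)
  expect_equal(whole_system_sd(0), 0)
  expect_equal(whole_system_sd(1), sqrt(2))

  # paper-reproduction path from rounded inputs, analysis path at full precision
  expect_equal(contamination_cv(0.57, 1.1), 51.8, tolerance = 1e-3)
  expect_equal(round(contamination_cv(0.57, 1.1)), 52)
  expect_equal(contamination_cv(0.57, dref), 1.53, tolerance = 1e-2)
  expect_equal(contamination_cv(0, 1.1), 0)
  expect_error(contamination_cv(0.5, 0), "> 0")
})

test_that("sensitivity sweep is anchored, monotone and matches the analytic limit", {
  grid <- seq(18, 24, by = 0.25)
  # anchor the measured difference so f(21) = 4.05 %
  d_x <- (1 - 0.0405) * ref21()
  curve <- sensitivity_sweep(d_x, grid, -5.6, -43.5, 8)
  expect_true(all(curve$ok))
  expect_equal(curve$f_contam[curve$disc == 21], 0.0405, tolerance = 1e-12)
  # strictly decreasing in the assumed discrimination
  expect_true(all(diff(curve$f_contam) < 0))

  # analytic small-drawdown closed form in the large-xi limit (the finite-xi
  # deviation scales as disc/1000/xi, so xi must exceed ~1e8 for 1e-9)
  xi_big <- 1e9
  d_x2 <- 35
  curve2 <- sensitivity_sweep(d_x2, grid, -5.6, -43.5, xi_big)
  closed <- 1 - d_x2 * (1 + grid / 1000) / (-5.6 - -43.5)
  expect_lt(max(abs(curve2$f_contam - closed)), 1e-9)

  # crossing property: where the reference equals the measurement, f = 0
  dref20 <- chamber_reference(-5.6, 8, 20) - chamber_reference(-43.5, 8, 20)
  curve3 <- sensitivity_sweep(dref20, c(19, 20, 21), -5.6, -43.5, 8)
  expect_equal(curve3$f_contam[curve3$disc == 20], 0, tolerance = 1e-12)
  expect_gt(curve3$f_contam[curve3$disc == 19], 0)
  expect_lt(curve3$f_contam[curve3$disc == 21], 0)
})

test_that("a shared calibration offset on both chambers cancels", {
  ex <- run_noise_free(f = 0.05)
  base <- estimate_quiet(ex)
  ex_off <- ex
  ex_off$samples$d13c_permil <- ex_off$samples$d13c_permil + 5
  shifted <- estimate_quiet(ex_off)
  expect_lt(max(abs(base$estimates$f_contam - shifted$estimates$f_contam)),
            1e-12)
  ex_off$samples$d13c_permil <- ex_off$samples$d13c_permil - 10
  shifted2 <- estimate_quiet(ex_off)
  expect_lt(max(abs(base$estimates$f_contam - shifted2$estimates$f_contam)),
            1e-12)
})

test_that("estimates are invariant to which chamber is listed first", {
  ex <- run_noise_free(f = 0.04)
  base <- estimate_quiet(ex)
  flipped <- ex
  flipped$chambers <- flipped$chambers[rev(seq_len(nrow(flipped$chambers))), ]
  swap <- estimate_quiet(flipped)
  est_a <- dplyr::arrange(base$estimates, .data$sample_kind, .data$replicate)
  est_b <- dplyr::arrange(swap$estimates, .data$sample_kind, .data$replicate)
  expect_equal(est_a$f_contam, est_b$f_contam, tolerance = 1e-12)
})

test_that("group summaries are descriptive means, SDs and counts", {
  est <- tibble::tibble(
    sample_kind = c("shoot", "shoot", "shoot", "root"),
    co2_level = c(400, 400, 400, 400),
    f_contam = c(0.039, 0.041, 0.027, 0.02)
  )
  s <- group_summary(est)
  shoot <- s[s$sample_kind == "shoot", ]
  expect_equal(100 * shoot$mean_f, 3.57, tolerance = 1e-2)
  expect_equal(100 * shoot$sd_f, 0.76, tolerance = 1e-2)
  expect_equal(shoot$n, 3)
  # single estimate: SD reported absent
  root <- s[s$sample_kind == "root", ]
  expect_true(is.na(root$sd_f))
  expect_equal(root$mean_f, 0.02)
  # partition preserves the total count
  expect_equal(sum(s$n), nrow(est))
})
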