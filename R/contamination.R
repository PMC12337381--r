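#' Contamination-free reference delta13C difference between paired chambers
#'
#' The difference between the reference delta13C of the 13C-enriched-fed and
#' the 13C-depleted-fed chamber. Orientation is enriched minus depleted; a
#' non-positive result almost always means the two chambers were passed in
#' the wrong order, so it warns.
#'
#' @param ref_enriched,ref_depleted Reference delta13C (permil) of the
#'   enriched- and depleted-source chambers, computed with the same Delta13C
#'   assumption.
#' @return d_delta13C_Ref in permil.
#' @examples
#' reference_difference(-23.5424, -60.7585)
#' @export
reference_difference <- function(ref_enriched, ref_depleted) {
  check_delta(ref_enriched, "ref_enriched")
  check_delta(ref_depleted, "ref_depleted")
  d <- ref_enriched - ref_depleted
  if (any(d <= 0)) {
    warning("non-positive reference difference: chamber sources likely swapped",
            call. = FALSE)
  }
  d
}

#' Fraction of contaminating carbon in a sample
#'
#' The headline two-chamber statistic: f_contam = 1 - d_delta_x / d_delta_ref,
#' where d_delta_x is the measured between-chamber delta13C difference of a
#' sample kind and d_delta_ref the contamination-free reference difference.
#' f = 0 means fully source-derived carbon, f = 1 means the sample is
#' isotopically independent of the labelling sources (fully contaminated).
#' Sampling noise can push estimates slightly negative; negative values are
#' returned unchanged, not clipped.
#'
#' @param d_delta_x Measured enriched-minus-depleted delta13C difference
#'   (permil).
#' @param d_delta_ref Reference difference (permil), > 0.
#' @return Contamination fraction (dimensionless, may be negative, <= 1 when
#'   `d_delta_x >= 0`).
#' @examples
#' contamination_fraction(35.70, 37.2161)
#' @export
contamination_fraction <- function(d_delta_x, d_delta_ref) {
  if (!is.numeric(d_delta_ref) || any(!is.finite(d_delta_ref)) ||
      any(d_delta_ref <= 0)) {
    stop("invalid reference: `d_delta_ref` must be finite and > 0",
         call. = FALSE)
  }
  1 - d_delta_x / d_delta_ref
}

#' delta13C-difference signal produced by a given contamination fraction
#'
#' The shrinkage of the between-chamber delta13C difference caused by a
#' contamination fraction `f`: signal = f * d_delta_ref. Useful for judging
#' detectability of a contamination level against measurement error.
#'
#' @param f Contamination fraction.
#' @param d_delta_ref Reference difference (permil), > 0.
#' @return Signal in permil.
#' @examples
#' signal_for_fraction(0.03, 37.2161)  # ~1.1 permil
#' @export
signal_for_fraction <- function(f, d_delta_ref) {
  if (!is.numeric(d_delta_ref) || any(d_delta_ref <= 0)) {
    stop("`d_delta_ref` must be > 0", call. = FALSE)
  }
  f * d_delta_ref
}

#' Whole-system SD of a between-chamber difference
#'
#' Error propagation for the difference of two independent measurements of
#' equal SD: SD(d) = sqrt(2) * SD(single). With a whole-system per-sample SD
#' of 0.4 permil this gives 0.57 permil for the paired difference.
#'
#' @param per_sample_sd SD of a single chamber's measurement (permil), >= 0.
#' @return SD of the difference (permil).
#' @examples
#' whole_system_sd(0.4)
#' @export
whole_system_sd <- function(per_sample_sd) {
  if (!is.numeric(per_sample_sd) || any(!is.finite(per_sample_sd)) ||
      any(per_sample_sd < 0)) {
    stop("`per_sample_sd` must be finite and >= 0", call. = FALSE)
  }
  per_sample_sd * sqrt(2)
}

#' Coefficient of variation of a contamination estimate
#'
#' CV (in percent) of the contamination estimate implied by a difference SD
#' and the delta-difference signal of the contamination level of interest:
#' 100 * sd / signal.
#'
#' @param whole_system_sd SD of the paired difference (permil).
#' @param signal Signal in permil (see [signal_for_fraction()]), > 0.
#' @return CV in percent.
#' @examples
#' contamination_cv(0.57, 1.1)  # ~52 %
#' @export
contamination_cv <- function(whole_system_sd, signal) {
  if (!is.numeric(signal) || any(!is.finite(signal)) || any(signal <= 0)) {
    stop("`signal` must be finite and > 0", call. = FALSE)
  }
  if (any(whole_system_sd < 0)) {
    stop("`whole_system_sd` must be >= 0", call. = FALSE)
  }
  100 * whole_system_sd / signal
}

#' Sensitivity of the contamination estimate to the assumed discrimination
#'
#' Recomputes the full reference chain (pure outlet delta13C, reference
#' delta13C, reference difference) and the contamination fraction for each
#' candidate Delta13C, at fixed measured `d_delta_x`. The curve decreases
#' strictly with Delta13C. Grid points where the chamber configuration is
#' singular are flagged (`ok = FALSE`) and skipped, not fatal.
#'
#' @param d_delta_x Measured enriched-minus-depleted difference (permil).
#' @param disc_grid Candidate Delta13C values (permil).
#' @param delta_inlet_enriched,delta_inlet_depleted Inlet delta13C of the two
#'   chambers (permil).
#' @param xi_enriched,xi_depleted xi of the two chambers (default equal).
#' @return Tibble with columns `disc`, `d_delta_ref`, `f_contam`, `ok`.
#' @examples
#' sensitivity_sweep(35.7, seq(18, 24, 0.5), -5.6, -43.5, 8, 8)
#' @export
sensitivity_sweep <- function(d_delta_x, disc_grid,
                              delta_inlet_enriched, delta_inlet_depleted,
                              xi_enriched, xi_depleted = xi_enriched) {
  res <- lapply(disc_grid, function(disc) {
    tryCatch({
      ref_e <- chamber_reference(delta_inlet_enriched, xi_enriched, disc)
      ref_d <- chamber_reference(delta_inlet_depleted, xi_depleted, disc)
      dref <- ref_e - ref_d
      tibble::tibble(disc = disc, d_delta_ref = dref,
                     f_contam = contamination_fraction(d_delta_x, dref),
                     ok = TRUE)
    }, error = function(e) {
      tibble::tibble(disc = disc, d_delta_ref = NA_real_,
                     f_contam = NA_real_, ok = FALSE)
    })
  })
  dplyr::bind_rows(res)
}

#' Reference delta13C of one chamber from its inlet delta and xi
#'
#' Convenience composition of [delta_outlet_pure()] and the flux mass balance
#' under the equal-air-flow assumption, where F_inlet/F_outlet = xi/(xi - 1).
#' Evaluated through the algebraically identical Farquhar form
#' [tissue_delta_from_source()] applied to the pure outlet delta, which stays
#' numerically stable at large xi where the literal flux difference
#' xi*d_in - (xi-1)*d_op cancels catastrophically; the equivalence of the two
#' forms is enforced by the test suite over the operating range.
#'
#' @param delta_inlet Inlet delta13C (permil).
#' @param xi Chamber xi.
#' @param disc Assumed discrimination (permil).
#' @return Reference delta13C (permil VPDB).
#' @export
chamber_reference <- function(delta_inlet, xi, disc) {
  dop <- delta_outlet_pure(disc, xi, delta_inlet)
  tissue_delta_from_source(dop, disc)
}

#' Descriptive summary of contamination estimates by group
#'
#' Mean, SD and n of contamination estimates per sample kind and CO2 level.
#' Descriptive only; no inferential testing. Single-member groups report an
#' absent (NA) SD; empty groups are omitted.
#'
#' @param estimates Tibble with at least `sample_kind`, `co2_level`,
#'   `f_contam` columns (per-replicate estimates, as fractions).
#' @return Tibble with `sample_kind`, `co2_level`, `mean_f`, `sd_f`, `n`.
#' @export
group_summary <- function(estimates) {
  stopifnot(all(c("sample_kind", "co2_level", "f_contam") %in% names(estimates)))
  estimates |>
    dplyr::filter(!is.na(.data$f_contam)) |>
    dplyr::group_by(.data$sample_kind, .data$co2_level) |>
    dplyr::summarise(
      mean_f = mean(.data$f_contam),
      sd_f = if (dplyr::n() > 1) stats::sd(.data$f_contam) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}
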