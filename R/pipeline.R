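#' Estimate contamination fractions from chamber logs and sample tables
#'
#' The full paired-chamber analysis: QC-filter the chamber logs, pair inlet
#' and outlet records, compute each chamber's contamination-free reference
#' delta13C per light-phase measurement (pure outlet delta13C via the Evans
#' relation at the assumed discrimination, then the flux mass balance) and
#' aggregate it; form the reference difference d_delta13C_Ref between the
#' enriched- and depleted-source chamber of each CO2 level; difference the
#' matched sample delta13C values; and return per-replicate contamination
#' fractions with descriptive group summaries. Dark-phase records yield
#' respired delta13C per night, entering the estimates as the "respiration"
#' kind. When shoot samples carry WSC component rows, the WSC-free shoot
#' delta13C is derived by isotopic mass balance and estimated as its own kind.
#'
#' @param chamber_log Chamber log tibble (`timestamp`, `chamber_id`,
#'   `location`, `co2_umol_mol`, `flow_slpm`, `d13c_permil`).
#' @param samples Sample table tibble (`sample_id`, `chamber_id`,
#'   `sample_kind`, `replicate`, `dry_mass_g`, `carbon_mass_g`,
#'   `d13c_permil`).
#' @param chambers Chamber description tibble (`chamber_id`, `source_delta`,
#'   `target_co2`).
#' @param events Optional event log for QC.
#' @param pp A [photoperiod()].
#' @param disc Assumed discrimination Delta13C (permil), default 21.
#' @param reference_mode "global" (one d_delta13C_Ref, the mean over CO2
#'   levels, used for every sample — mirroring a single constant-Delta
#'   reference) or "per-treatment" (each CO2 level uses its own).
#' @param qc Apply [qc_flags()] before pairing (default TRUE).
#' @param area Chamber ground area (m2).
#' @param pair_window_min Inlet/outlet pairing window (minutes).
#' @param ... Further arguments passed to [qc_flags()].
#' @return A `contamination_analysis` list with elements `references` (per
#'   CO2 level), `d_delta_ref_global`, `estimates` (per replicate) and
#'   `summary` (per kind x CO2 level).
#' @export
estimate_contamination <- function(chamber_log, samples, chambers,
                                   events = NULL, pp = photoperiod(),
                                   disc = 21,
                                   reference_mode = c("global", "per-treatment"),
                                   qc = TRUE, area = 1.5,
                                   pair_window_min = 3, ...) {
  reference_mode <- match.arg(reference_mode)
  stopifnot(all(c("chamber_id", "source_delta", "target_co2") %in% names(chambers)))

  flagged <- if (qc) {
    qc_flags(chamber_log, events = events, pp = pp, ...)
  } else {
    chamber_log$phase <- phase_of(chamber_log$timestamp, pp)
    chamber_log$exp_day <- day_of(chamber_log$timestamp, pp)
    chamber_log$retained <- TRUE
    chamber_log
  }

  paired <- pair_chamber_records(flagged, window_min = pair_window_min)
  paired$phase <- phase_of(paired$timestamp, pp)
  paired$exp_day <- day_of(paired$timestamp, pp)
  paired <- chamber_fluxes(paired, area = area)

  roles <- chambers |>
    dplyr::group_by(.data$target_co2) |>
    dplyr::mutate(role = ifelse(.data$source_delta ==
                                  max(.data$source_delta),
                                "enriched", "depleted")) |>
    dplyr::ungroup() |>
    dplyr::select("chamber_id", "source_delta", "target_co2", "role")

  # per-chamber reference delta13C from light-phase pairs (per-measurement,
  # then aggregated)
  light <- paired[paired$phase == "light", , drop = FALSE]
  light$delta_ref_i <- delta_ref(
    light$delta_inlet,
    delta_outlet_pure(disc, light$xi, light$delta_inlet),
    light$f_inlet, light$f_outlet
  )
  ref_by_chamber <- light |>
    dplyr::group_by(.data$chamber_id) |>
    dplyr::summarise(delta_ref = mean(.data$delta_ref_i),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(roles, by = "chamber_id")

  references <- ref_by_chamber |>
    dplyr::select("target_co2", "role", "delta_ref") |>
    tidyr::pivot_wider(names_from = "role", values_from = "delta_ref") |>
    dplyr::mutate(d_delta_ref = reference_difference(.data$enriched,
                                                     .data$depleted)) |>
    dplyr::rename(co2_level = "target_co2")
  d_delta_ref_global <- mean(references$d_delta_ref)
  ref_used <- function(co2_level) {
    if (reference_mode == "global") {
      rep(d_delta_ref_global, length(co2_level))
    } else {
      references$d_delta_ref[match(co2_level, references$co2_level)]
    }
  }

  samples <- dplyr::left_join(samples, roles, by = "chamber_id")
  samples <- dplyr::rename(samples, co2_level = "target_co2")
  samples <- derive_wsc_free_shoot(samples)

  pairs_x <- samples |>
    dplyr::select("sample_kind", "co2_level", "replicate", "role",
                  "d13c_permil") |>
    tidyr::pivot_wider(names_from = "role", values_from = "d13c_permil") |>
    dplyr::filter(!is.na(.data$enriched) & !is.na(.data$depleted)) |>
    dplyr::mutate(d_delta_x = .data$enriched - .data$depleted)

  resp <- respiration_deltas(paired, roles)
  if (nrow(resp)) pairs_x <- dplyr::bind_rows(pairs_x, resp)

  pairs_x$d_delta_ref <- ref_used(pairs_x$co2_level)
  pairs_x$f_contam <- contamination_fraction(pairs_x$d_delta_x,
                                             pairs_x$d_delta_ref)

  smry <- group_summary(pairs_x)
  structure(list(
    references = references,
    d_delta_ref_global = d_delta_ref_global,
    disc = disc,
    reference_mode = reference_mode,
    estimates = pairs_x,
    summary = smry
  ), class = "contamination_analysis")
}

# carbon-weighted WSC pooling + isotopic mass balance per shoot sample
derive_wsc_free_shoot <- function(samples) {
  wsc_kinds <- c("fructan", "sucrose", "glucose", "fructose")
  has <- samples$sample_kind %in% wsc_kinds
  if (!any(has) || !any(samples$sample_kind == "shoot")) return(samples)
  wsc <- samples[has, , drop = FALSE] |>
    dplyr::group_by(.data$chamber_id, .data$replicate) |>
    dplyr::summarise(
      delta_wsc = pooled_wsc_delta(.data$d13c_permil, .data$carbon_mass_g),
      w_wsc = sum(.data$carbon_mass_g), .groups = "drop")
  shoot <- samples[samples$sample_kind == "shoot", , drop = FALSE]
  joined <- dplyr::inner_join(shoot, wsc, by = c("chamber_id", "replicate"))
  if (!nrow(joined)) return(samples)
  joined$d13c_permil <- wsc_free_biomass_delta(
    joined$d13c_permil, joined$carbon_mass_g, joined$delta_wsc, joined$w_wsc)
  joined$sample_kind <- "wsc_free_shoot"
  joined$sample_id <- sub("shoot", "wsc_free_shoot", joined$sample_id)
  joined$carbon_mass_g <- joined$carbon_mass_g - joined$w_wsc
  dplyr::bind_rows(samples,
                   joined[, setdiff(names(joined), c("delta_wsc", "w_wsc"))])
}

# nightly respired delta13C per chamber, paired across roles by day
respiration_deltas <- function(paired, roles) {
  dark <- paired[paired$phase == "dark", , drop = FALSE]
  if (!nrow(dark)) return(tibble::tibble())
  dark$delta_rn <- delta_respired(dark$delta_inlet, dark$delta_outlet,
                                  dark$f_inlet, dark$f_outlet)
  nightly <- dark |>
    dplyr::group_by(.data$chamber_id, .data$exp_day) |>
    dplyr::summarise(delta_rn = mean(.data$delta_rn), .groups = "drop") |>
    dplyr::left_join(roles, by = "chamber_id")
  nightly |>
    dplyr::select("exp_day", "target_co2", "role", "delta_rn") |>
    tidyr::pivot_wider(names_from = "role", values_from = "delta_rn") |>
    dplyr::filter(!is.na(.data$enriched) & !is.na(.data$depleted)) |>
    dplyr::transmute(
      sample_kind = "respiration",
      co2_level = .data$target_co2,
      replicate = as.integer(factor(.data$exp_day)),
      enriched = .data$enriched, depleted = .data$depleted,
      d_delta_x = .data$enriched - .data$depleted
    )
}

#' @export
print.contamination_analysis <- function(x, ...) {
  cat("<contamination_analysis>\n")
  cat(sprintf("  Delta13C assumption: %g permil; reference mode: %s\n",
              x$disc, x$reference_mode))
  cat(sprintf("  d_delta13C_Ref (global): %.4f permil\n", x$d_delta_ref_global))
  cat("  group means (f_contam, %):\n")
  print(report_table(x$summary), row.names = FALSE)
  invisible(x)
}

#' Sample-kind by CO2-level report of contamination estimates
#'
#' Formats a [group_summary()] table in the conventional layout of labelling
#' studies: one row per sample kind, one column per CO2 level, entries
#' "mean (SD)" in percent.
#'
#' @param smry Output of [group_summary()] (fractions).
#' @return A data.frame of formatted strings.
#' @export
report_table <- function(smry) {
  smry |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$sd_f),
      sprintf("%.1f", 100 * .data$mean_f),
      sprintf("%.1f (%.1f)", 100 * .data$mean_f, 100 * .data$sd_f))) |>
    dplyr::select("sample_kind", "co2_level", "cell") |>
    tidyr::pivot_wider(names_from = "co2_level", values_from = "cell") |>
    as.data.frame()
}
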