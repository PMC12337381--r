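#' Photoperiod schedule of a labelling chamber
#'
#' Daily light schedule in chamber-local clock time. The experimental day is
#' anchored at lights-on, so dark-period records after midnight still belong
#' to the day whose light period they follow.
#'
#' @param lights_on_hour Clock hour of lights-on (default 6, i.e. 06:00).
#' @param light_hours Length of the light period in hours (default 16).
#' @return A `photoperiod` object.
#' @export
photoperiod <- function(lights_on_hour = 6, light_hours = 16) {
  stopifnot(lights_on_hour >= 0, lights_on_hour < 24,
            light_hours > 0, light_hours < 24)
  structure(list(lights_on_hour = lights_on_hour, light_hours = light_hours),
            class = "photoperiod")
}

#' @export
print.photoperiod <- function(x, ...) {
  cat(sprintf("<photoperiod> lights on %02d:00, %g h light / %g h dark\n",
              x$lights_on_hour, x$light_hours, 24 - x$light_hours))
  invisible(x)
}

# minutes since the most recent lights-on, in [0, 1440)
minutes_since_lights_on <- function(timestamp, pp) {
  lt <- as.POSIXlt(timestamp)
  mod <- lt$hour * 60 + lt$min + lt$sec / 60
  (mod - pp$lights_on_hour * 60) %% 1440
}

#' Phase and experimental-day assignment for timestamps
#'
#' @param timestamp POSIXct vector.
#' @param pp A [photoperiod()].
#' @return `phase_of()`: character vector "light"/"dark". `day_of()`: the
#'   experimental day (a Date), with the day boundary at lights-on.
#' @export
phase_of <- function(timestamp, pp = photoperiod()) {
  msl <- minutes_since_lights_on(timestamp, pp)
  ifelse(msl < pp$light_hours * 60, "light", "dark")
}

#' @rdname phase_of
#' @export
day_of <- function(timestamp, pp = photoperiod()) {
  as.Date(timestamp - pp$lights_on_hour * 3600, tz = attr(timestamp, "tzone") %||% "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag records in the first minutes of the light period
#'
#' Chamber air needs time to re-equilibrate after the dark-to-light
#' transition, so records with timestamps in the half-open window
#' `[lights_on, lights_on + window_min)` are flagged for exclusion.
#'
#' @param records Chamber log tibble with a `timestamp` column.
#' @param pp A [photoperiod()].
#' @param window_min Exclusion window length in minutes (default 45).
#' @return Logical vector, `TRUE` for records to exclude.
#' @export
flag_photoperiod_start <- function(records, pp = photoperiod(), window_min = 45) {
  msl <- minutes_since_lights_on(records$timestamp, pp)
  msl < window_min
}

#' Flag records following chamber door openings
#'
#' Each door opening perturbs chamber air; records of the same chamber within
#' the half-open recovery window `[event, event + recovery_min)` are flagged.
#' Overlapping windows merge naturally.
#'
#' @param records Chamber log tibble (`timestamp`, `chamber_id`).
#' @param events Event log tibble (`timestamp`, `chamber_id`, `event_kind`);
#'   only `door_opening` events open windows.
#' @param recovery_min Recovery window in minutes (default 45, the washout
#'   scale of a 3000 L chamber at 250 SLPM).
#' @return Logical vector, `TRUE` for records to exclude.
#' @export
flag_post_event <- function(records, events, recovery_min = 45) {
  if (is.null(events) || nrow(events) == 0L) {
    return(rep(FALSE, nrow(records)))
  }
  doors <- events[events$event_kind == "door_opening", , drop = FALSE]
  flag <- rep(FALSE, nrow(records))
  for (ch in unique(records$chamber_id)) {
    ev <- as.numeric(doors$timestamp[doors$chamber_id == ch])
    if (!length(ev)) next
    idx <- which(records$chamber_id == ch)
    t <- as.numeric(records$timestamp[idx])
    hit <- vapply(t, function(ti) any(ti >= ev & ti < ev + recovery_min * 60),
                  logical(1))
    flag[idx] <- hit
  }
  flag
}

#' Interquartile-range outlier flags for a numeric series
#'
#' Flags values falling strictly outside `center +/- k * IQR`, with quartiles
#' by linear interpolation (R quantile type 7). The default centre is the
#' series mean; `center = "median"` gives the Tukey-style variant. Series
#' shorter than 4 values yield no flags (quartiles are not meaningful) with a
#' warning.
#'
#' @param values Numeric series.
#' @param k Fence multiplier (default 1.5).
#' @param center "mean" (default) or "median".
#' @return Logical vector, `TRUE` for outliers.
#' @examples
#' flag_iqr_outliers(c(10, 10, 10, 10, 10, 50), center = "median")
#' @export
flag_iqr_outliers <- function(values, k = 1.5, center = c("mean", "median")) {
  center <- match.arg(center)
  ok <- is.finite(values)
  flag <- rep(FALSE, length(values))
  if (sum(ok) < 4) {
    warning("fewer than 4 values: IQR outlier rule not applied", call. = FALSE)
    return(flag)
  }
  v <- values[ok]
  iqr <- stats::IQR(v, type = 7)
  ctr <- if (center == "mean") mean(v) else stats::median(v)
  if (iqr == 0) {
    # degenerate spread: the median still marks the majority value, so
    # deviations from it are outliers; the mean is itself displaced by any
    # outlier, so the mean-centred rule collapses and flags nothing
    if (center == "median") flag[ok] <- v != ctr
    return(flag)
  }
  flag[ok] <- v < ctr - k * iqr | v > ctr + k * iqr
  flag
}

#' Apply the full chamber-log cleaning chain
#'
#' Adds the three exclusion flags and the combined `retained` column to a
#' chamber log: records in the first `window_min` minutes of the light period,
#' records within `recovery_min` minutes after a door opening, and IQR
#' outliers. The IQR rule runs per chamber x experimental day x location on
#' each series named in `iqr_on`, among records passing the first two rules
#' (outliers are judged against the event-clean series). The chain is
#' idempotent: re-running it on its own output reproduces identical flags.
#'
#' @param records Chamber log tibble (see [pair_chamber_records()] for the
#'   schema).
#' @param events Optional event log tibble.
#' @param pp A [photoperiod()].
#' @param window_min,recovery_min Exclusion windows in minutes.
#' @param iqr_k Fence multiplier for the IQR rule.
#' @param iqr_on Character vector of column names the IQR rule applies to.
#' @param iqr_center Centre convention for the IQR rule.
#' @param iqr_scope "day" (default, per chamber x day x location series) or
#'   "all" (whole period per chamber x location).
#' @return `records` with added columns `phase`, `exp_day`,
#'   `within_45min_of_lights_on`, `post_door_opening`, `iqr_outlier`,
#'   `retained`.
#' @export
qc_flags <- function(records, events = NULL, pp = photoperiod(),
                     window_min = 45, recovery_min = 45, iqr_k = 1.5,
                     iqr_on = c("co2_umol_mol", "d13c_permil"),
                     iqr_center = "mean", iqr_scope = c("day", "all")) {
  iqr_scope <- match.arg(iqr_scope)
  records$phase <- phase_of(records$timestamp, pp)
  records$exp_day <- day_of(records$timestamp, pp)
  records$within_45min_of_lights_on <-
    flag_photoperiod_start(records, pp, window_min)
  records$post_door_opening <- flag_post_event(records, events, recovery_min)
  clean <- !records$within_45min_of_lights_on & !records$post_door_opening

  records$iqr_outlier <- FALSE
  grp <- if (iqr_scope == "day") {
    interaction(records$chamber_id, records$exp_day, records$location,
                records$phase, drop = TRUE)
  } else {
    interaction(records$chamber_id, records$location, records$phase,
                drop = TRUE)
  }
  for (g in levels(grp)) {
    idx <- which(grp == g & clean)
    if (length(idx) < 4) next
    hit <- rep(FALSE, length(idx))
    for (v in iqr_on) {
      hit <- hit | suppressWarnings(
        flag_iqr_outliers(records[[v]][idx], k = iqr_k, center = iqr_center))
    }
    records$iqr_outlier[idx] <- hit
  }
  records$retained <- clean & !records$iqr_outlier
  records
}

#' Daily summary of retained chamber records
#'
#' Mean, SD and n of CO2 concentration and delta13C per chamber x
#' experimental day x location among retained records. Days with a single
#' record report an absent (NA) SD; empty days are omitted.
#'
#' @param records Output of [qc_flags()].
#' @param phase Which phase(s) to aggregate (default "light").
#' @return Tibble keyed by `chamber_id`, `exp_day`, `location`.
#' @export
daily_aggregate <- function(records, phase = "light") {
  stopifnot("retained" %in% names(records))
  keep_phase <- phase
  records |>
    dplyr::filter(.data$retained, .data$phase %in% keep_phase) |>
    dplyr::group_by(.data$chamber_id, .data$exp_day, .data$location) |>
    dplyr::summarise(
      co2_mean = mean(.data$co2_umol_mol),
      co2_sd = if (dplyr::n() > 1) stats::sd(.data$co2_umol_mol) else NA_real_,
      d13c_mean = mean(.data$d13c_permil),
      d13c_sd = if (dplyr::n() > 1) stats::sd(.data$d13c_permil) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}
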