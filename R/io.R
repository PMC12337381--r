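schema_chamber_log <- c("timestamp", "chamber_id", "location", "co2_umol_mol",
                        "flow_slpm", "d13c_permil")
schema_event_log <- c("timestamp", "chamber_id", "event_kind")
schema_samples <- c("sample_id", "chamber_id", "sample_kind", "replicate",
                    "dry_mass_g", "carbon_mass_g", "d13c_permil")
schema_chambers <- c("chamber_id", "source_delta", "target_co2")

# comment-prefixed provenance header written at the top of every output file
provenance_header <- function(provenance = NULL) {
  c(sprintf("# isocontam v%s schema v1",
            as.character(utils::packageVersion("isocontam"))),
    if (!is.null(provenance)) paste0("# ", names(provenance), "=", provenance))
}

check_schema <- function(df, schema, path) {
  missing <- setdiff(schema, names(df))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

read_table_checked <- function(path, schema, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # parse issues are re-reported below as explicit row rejections
  df <- withCallingHandlers(
    readr::read_csv(path, col_types = col_types, comment = "#",
                    progress = FALSE),
    warning = function(w) {
      if (grepl("parsing issues", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  check_schema(df, schema, path)
  probs <- readr::problems(df)
  bad <- integer(0)
  if (nrow(probs)) bad <- unique(probs$row)
  # rows where a required field failed to parse are rejected, not silently kept
  incomplete <- !stats::complete.cases(df[, schema, drop = FALSE])
  bad <- sort(unique(c(bad, which(incomplete))))
  rejected <- df[incomplete, , drop = FALSE]
  if (length(bad)) {
    warning(length(bad), " malformed row(s) rejected from ", path,
            call. = FALSE)
    df <- df[-which(incomplete), , drop = FALSE]
  }
  attr(df, "rejected") <- rejected
  df
}

#' Read and write chamber gas-exchange logs
#'
#' Delimited-text (CSV) chamber logs with ISO 8601 timestamps, one row per
#' inlet or outlet measurement. Malformed rows are rejected with a warning
#' and returned in the `rejected` attribute, never silently dropped. Writers
#' prepend a comment provenance header (package version plus any named
#' entries in `provenance`, e.g. seed and config hash); readers skip comment
#' lines.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @param provenance Optional named character vector recorded in the header.
#' @return The tibble read (with a `rejected` attribute), or for writers the
#'   input invisibly.
#' @export
read_chamber_log <- function(path) {
  df <- read_table_checked(path, schema_chamber_log, readr::cols(
    timestamp = readr::col_datetime(), chamber_id = readr::col_character(),
    location = readr::col_character(), co2_umol_mol = readr::col_double(),
    flow_slpm = readr::col_double(), d13c_permil = readr::col_double()))
  bad_loc <- !df$location %in% c("inlet", "outlet")
  if (any(bad_loc)) {
    warning(sum(bad_loc), " row(s) with unknown location rejected from ",
            path, call. = FALSE)
    attr_rej <- rbind(attr(df, "rejected"), df[bad_loc, , drop = FALSE])
    df <- df[!bad_loc, , drop = FALSE]
    attr(df, "rejected") <- attr_rej
  }
  df
}

#' @rdname read_chamber_log
#' @export
write_chamber_log <- function(x, path, provenance = NULL) {
  check_schema(x, schema_chamber_log, path)
  writeLines(provenance_header(provenance), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(x)
}

#' @rdname read_chamber_log
#' @export
read_event_log <- function(path) {
  read_table_checked(path, schema_event_log, readr::cols(
    timestamp = readr::col_datetime(), chamber_id = readr::col_character(),
    event_kind = readr::col_character()))
}

#' @rdname read_chamber_log
#' @export
write_event_log <- function(x, path, provenance = NULL) {
  check_schema(x, schema_event_log, path)
  writeLines(provenance_header(provenance), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(x)
}

#' @rdname read_chamber_log
#' @export
read_sample_table <- function(path) {
  read_table_checked(path, schema_samples, readr::cols(
    sample_id = readr::col_character(), chamber_id = readr::col_character(),
    sample_kind = readr::col_character(), replicate = readr::col_integer(),
    dry_mass_g = readr::col_double(), carbon_mass_g = readr::col_double(),
    d13c_permil = readr::col_double()))
}

#' @rdname read_chamber_log
#' @export
write_sample_table <- function(x, path, provenance = NULL) {
  check_schema(x, schema_samples, path)
  writeLines(provenance_header(provenance), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(x)
}

#' @rdname read_chamber_log
#' @export
read_chamber_table <- function(path) {
  read_table_checked(path, schema_chambers, readr::cols(
    chamber_id = readr::col_character(), source_delta = readr::col_double(),
    target_co2 = readr::col_double()))
}

#' @rdname read_chamber_log
#' @export
write_chamber_table <- function(x, path, provenance = NULL) {
  check_schema(x, schema_chambers, path)
  writeLines(provenance_header(provenance), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(x)
}

#' Write estimation results
#'
#' Writes the per-replicate estimate table of a [estimate_contamination()]
#' result in a stable, round-trippable column layout.
#'
#' @param analysis A `contamination_analysis`.
#' @param path Output CSV path.
#' @param provenance Optional named character vector for the header.
#' @return The estimates tibble, invisibly.
#' @export
write_estimates <- function(analysis, path, provenance = NULL) {
  est <- analysis$estimates |>
    dplyr::left_join(analysis$summary,
                     by = c("sample_kind", "co2_level")) |>
    dplyr::transmute(
      sample_kind = .data$sample_kind, co2_level = .data$co2_level,
      replicate = .data$replicate,
      d_delta_x = .data$d_delta_x, d_delta_ref = .data$d_delta_ref,
      f_contam_pct = 100 * .data$f_contam,
      sd_pct = 100 * .data$sd_f,
      cv_pct = ifelse(.data$mean_f > 0,
                      100 * .data$sd_f / abs(.data$mean_f), NA_real_),
      n = .data$n)
  writeLines(provenance_header(provenance), path)
  readr::write_csv(est, path, append = TRUE, col_names = TRUE)
  invisible(est)
}

#' Write all files of a virtual experiment
#'
#' Emits the chamber log, event log, sample table and chamber table of a
#' [run_virtual_experiment()] result into a directory, plus the ground-truth
#' table for test harnesses.
#'
#' @param exp A `virtual_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_virtual_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(seed = as.character(exp$config$seed),
            target_co2 = as.character(exp$config$target_co2))
  write_chamber_log(exp$chamber_log, file.path(dir, "chamber_log.csv"), prov)
  write_event_log(exp$events, file.path(dir, "events.csv"), prov)
  write_sample_table(exp$samples, file.path(dir, "samples.csv"), prov)
  write_chamber_table(exp$chambers, file.path(dir, "chambers.csv"), prov)
  truth <- exp$truth$chamber |>
    dplyr::transmute(sample_kind = "all", chamber_id = .data$chamber_id,
                     true_f_contam = exp$truth$f_contam,
                     true_delta = .data$tissue_delta_true)
  writeLines(provenance_header(prov), file.path(dir, "ground_truth.csv"))
  readr::write_csv(truth, file.path(dir, "ground_truth.csv"),
                   append = TRUE, col_names = TRUE)
  invisible(dir)
}
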