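# File formats: the cohort CSV (canonical measurement columns, period
# decimal separator regardless of locale), the model-set JSON (same schema
# as the registry asset plus fitted fields), and the JSON/markdown case
# report.

#' Read a cohort CSV
#'
#' Expects the canonical column set: `id`, optional `sex`, `age_years`,
#' `stature_cm`, measurement columns `<bone>_<measurement>_mm` and optional
#' `<bone>_<measurement>_kind` columns (`diaphyseal`/`maximum`). Unknown
#' columns are rejected with a listing. Rows with invalid values
#' (measurements outside (0, 700) mm, stature outside (30, 230) cm) are
#' dropped with a per-row warning naming row and column; the read fails if
#' more than 10% of rows are invalid. Empty cells are missing values.
#' Composite limb lengths are NOT derived here (prediction and fitting do
#' that).
#'
#' @param path CSV file path.
#' @return A validated cohort tibble; rejected-row messages are attached as
#'   the `"validation_errors"` attribute.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  if (!"id" %in% names(raw)) abort("Cohort CSV must have an `id` column.")
  for (col in setdiff(names(raw), c("id", "sex", kind_columns()))) {
    raw[[col]][raw[[col]] == ""] <- NA
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  checked <- validate_cohort(raw)
  if (length(checked$errors) > 0) {
    if (length(checked$bad_rows) > 0.1 * nrow(raw)) {
      abort(paste0("More than 10% of rows are invalid:\n  ",
                   paste(checked$errors, collapse = "\n  ")))
    }
    warn(paste0("Dropped ", length(checked$bad_rows), " invalid row(s):\n  ",
                paste(checked$errors, collapse = "\n  ")))
  }
  out <- checked$data
  if (length(checked$bad_rows) > 0) out <- out[-checked$bad_rows, , drop = FALSE]
  attr(out, "validation_errors") <- checked$errors
  out
}

#' Write a cohort CSV
#'
#' Locale-independent (period decimal separator), UTF-8, comma-separated;
#' round-trips through [read_cohort()] at full numeric precision.
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  df <- as.data.frame(data)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(v) {
        if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
      }, character(1))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# one serializable list per model row (registry JSON schema + fitted fields)
model_to_list <- function(m) {
  list(
    bone = m$bone, measurement = m$measurement, family = m$family,
    coefficients = as.list(m$coefficients),
    n = if (is.na(m$n)) NULL else m$n,
    residual_sd_cm = if (is.na(m$residual_sd)) NULL else m$residual_sd,
    x_mean = if (is.na(m$x_mean)) NULL else m$x_mean,
    sxx = if (is.na(m$sxx)) NULL else m$sxx,
    param_covariance = if (!is.null(m$cov_unscaled) && !is.na(m$residual_sd)) {
      m$residual_sd^2 * m$cov_unscaled
    } else NULL,
    cov_unscaled = m$cov_unscaled,
    x_range = m$x_range,
    converged = m$converged, sanity_flag = m$sanity_flag, source = m$source
  )
}

#' Serialize a fitted model set to JSON
#'
#' Same schema as the registry asset, extended with the fitted fields
#' (`n`, residual SD, scaled and unscaled parameter covariance, training
#' x range, convergence status).
#'
#' @param models Model table from [fit_stature_models()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  entries <- map(models$model[!map_lgl(models$model, is.null)], model_to_list)
  jsonlite::write_json(
    list(schema = "staturekit-models", version = "1.0.0", entries = entries),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null",
    matrix = "rowmajor"
  )
  invisible(path)
}

#' Read a model set from JSON
#'
#' @param path JSON written by [write_models()].
#' @return A model table usable by [estimate_stature()] and
#'   [evaluate_models()].
#' @export
read_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- jsonlite::read_json(path)
  rows <- map(raw$entries, function(e) {
    cov <- if (!is.null(e$cov_unscaled)) {
      do.call(rbind, map(e$cov_unscaled, unlist))
    } else NULL
    m <- stature_model(
      e$bone, e$measurement, e$family, unlist(e$coefficients),
      n = e$n %||% NA_integer_,
      residual_sd = e$residual_sd_cm %||% NA_real_,
      x_mean = e$x_mean %||% NA_real_,
      sxx = e$sxx %||% NA_real_,
      cov_unscaled = cov,
      x_range = if (!is.null(e$x_range)) unlist(e$x_range) else NULL,
      converged = isTRUE(e$converged),
      sanity_flag = isTRUE(e$sanity_flag),
      source = e$source %||% "fitted"
    )
    tibble(bone = m$bone, measurement = m$measurement, family = m$family,
           n = as.integer(m$n), converged = m$converged,
           residual_sd_cm = m$residual_sd, model = list(m))
  })
  list_rbind(rows)
}

#' Build a case report from stature estimates
#'
#' Bundles the inputs, per-measurement prediction results and warnings into
#' a recordkeeping structure, written as JSON with a human-readable
#' markdown twin. The markdown is derived deterministically from the JSON,
#' so the report can be regenerated bit-identically.
#'
#' @param estimates Output of [estimate_stature()].
#' @param input The cohort tibble the estimates came from.
#' @param path Output path for the JSON (`.md` twin written alongside);
#'   `NULL` to just return the report list.
#' @param registry_version Registry version string to record.
#' @param timestamp Timestamp string recorded in the report (defaults to
#'   the current UTC time; pass a fixed value for reproducible output).
#' @return The report list, invisibly when writing.
#' @export
case_report <- function(estimates, input, path = NULL,
                        registry_version = attr(load_registry(), "registry_version"),
                        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) {
  est <- estimates
  est$warnings <- map(est$warnings, as.character)
  report <- list(
    artifact = "staturekit",
    artifact_version = as.character(utils::packageVersion("staturekit")),
    registry_version = registry_version,
    timestamp = timestamp,
    input = as.list(as.data.frame(input)),
    results = est,
    warnings = unique(unlist(est$warnings))
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", dataframe = "rows")
    writeLines(case_report_markdown(jsonlite::read_json(path)),
               sub("\\.json$", ".md", path))
    return(invisible(report))
  }
  report
}

#' Render a case report (parsed JSON) as markdown
#'
#' @param report A report list as read back by `jsonlite::read_json()`.
#' @return Character vector of markdown lines.
#' @export
case_report_markdown <- function(report) {
  lines <- c(
    "# Stature estimation case report",
    "",
    sprintf("- artifact: %s %s", report$artifact, report$artifact_version),
    sprintf("- registry version: %s", report$registry_version),
    sprintf("- generated: %s", report$timestamp),
    "",
    "## Estimates",
    "",
    "| id | measurement | model | x (mm) | stature (cm) | PI (cm) | method |",
    "|----|-------------|-------|--------|--------------|---------|--------|"
  )
  for (r in report$results) {
    lines <- c(lines, sprintf(
      "| %s | %s %s | %s | %.1f | %.1f | [%.1f, %.1f] | %s |",
      r$id, r$bone, r$measurement, r$family, r$x_mm, r$point_cm,
      r$pi_lower_cm %||% NA, r$pi_upper_cm %||% NA, r$method
    ))
  }
  w <- unlist(report$warnings)
  if (length(w) > 0) {
    lines <- c(lines, "", "## Warnings", "", paste0("- ", w))
  }
  lines
}
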