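# Canonical measurement dictionary: which (bone, measurement) pairs exist,
# and the cohort-table column each maps to.

#' Canonical long-bone measurement dictionary
#'
#' The 20 measurements the models cover: 18 single-bone measurements
#' (humerus, radius, ulna, femur, tibia, fibula; not every bone admits every
#' breadth) plus the two composite limb lengths, upper limb (humerus + radius)
#' and lower limb (femur + tibia).
#'
#' @return A tibble with columns `bone`, `measurement`, `type`
#'   (`"length"`/`"breadth"`), `composite` (logical) and `column`, the
#'   canonical cohort-table column name (`<bone>_<measurement>_mm`).
#' @examples
#' measurement_dictionary()
#' @export
measurement_dictionary <- function() {
  single <- list(
    humerus = c("length", "proximal_breadth", "midshaft_breadth", "distal_breadth"),
    radius  = c("length", "proximal_breadth", "midshaft_breadth", "distal_breadth"),
    ulna    = c("length", "midshaft_breadth"),
    femur   = c("length", "midshaft_breadth", "distal_breadth"),
    tibia   = c("length", "proximal_breadth", "midshaft_breadth", "distal_breadth"),
    fibula  = "length"
  )
  out <- tibble(
    bone = rep(names(single), lengths(single)),
    measurement = unlist(single, use.names = FALSE),
    composite = FALSE
  )
  out <- bind_rows(out, tibble(
    bone = c("upper_limb", "lower_limb"),
    measurement = "length",
    composite = TRUE
  ))
  out$type <- ifelse(out$measurement == "length", "length", "breadth")
  out$column <- paste0(out$bone, "_", out$measurement, "_mm")
  out[, c("bone", "measurement", "type", "composite", "column")]
}

#' @rdname measurement_dictionary
#' @export
measurement_columns <- function() measurement_dictionary()$column

# metadata columns a cohort table may carry besides measurements
cohort_meta_columns <- function() c("id", "sex", "age_years", "stature_cm")

kind_columns <- function() sub("_mm$", "_kind", measurement_columns())

# Table-6-style grouping: lengths (incl. composites), proximal/midshaft/distal
measurement_group <- function(measurement) {
  sub("_breadth$", "", measurement)
}

#' Add composite limb lengths to a cohort table
#'
#' Upper limb length is humerus length + radius length; lower limb length is
#' femur length + tibia length. A composite is filled only where both
#' components are present, and an existing composite value is never
#' overwritten. Rows missing a component are left unchanged for that
#' composite; absence is not an error.
#'
#' @param data A cohort tibble (see [read_cohort()]) with canonical
#'   measurement columns in millimetres.
#' @return `data` with `upper_limb_length_mm` and `lower_limb_length_mm`
#'   columns populated where computable.
#' @examples
#' add_composite_lengths(
#'   tibble::tibble(id = "a", humerus_length_mm = 300, radius_length_mm = 220)
#' )
#' @export
add_composite_lengths <- function(data) {
  stopifnot(is.data.frame(data))
  data <- as_tibble(data)
  fill_composite <- function(data, target, part1, part2) {
    if (!target %in% names(data)) data[[target]] <- NA_real_
    if (all(c(part1, part2) %in% names(data))) {
      computable <- is.na(data[[target]]) &
        !is.na(data[[part1]]) & !is.na(data[[part2]])
      data[[target]][computable] <- data[[part1]][computable] + data[[part2]][computable]
    }
    data
  }
  data <- fill_composite(data, "upper_limb_length_mm", "humerus_length_mm", "radius_length_mm")
  fill_composite(data, "lower_limb_length_mm", "femur_length_mm", "tibia_length_mm")
}

# Validate one cohort table; returns list(data = cleaned tibble, errors =
# character vector of row-level problems). Measurement values must be finite,
# > 0 and < 700 mm; known stature in (30, 230) cm.
validate_cohort <- function(data) {
  data <- as_tibble(data)
  errors <- character()
  known <- c(cohort_meta_columns(), measurement_columns(), kind_columns())
  unknown <- setdiff(names(data), known)
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown cohort column(s): ", paste(unknown, collapse = ", "),
      ". Valid columns are id, sex, age_years, stature_cm, the ",
      "<bone>_<measurement>_mm measurement columns and their _kind twins."
    ))
  }
  if (!"id" %in% names(data)) abort("Cohort table must have an `id` column.")
  meas_cols <- intersect(measurement_columns(), names(data))
  dict <- measurement_dictionary()
  bad_rows <- rep(FALSE, nrow(data))
  for (col in meas_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      data[[col]] <- v
    }
    # single bones top out below 700 mm; a composite is a sum of two bones
    cap <- if (dict$composite[dict$column == col]) 1400 else 700
    bad <- !is.na(v) & (!is.finite(v) | v <= 0 | v >= cap)
    for (i in which(bad)) {
      errors <- c(errors, sprintf("row %d: %s = %s outside (0, %d) mm", i, col, format(data[[col]][i]), cap))
    }
    data[[col]][bad] <- NA_real_
    bad_rows <- bad_rows | bad
  }
  if ("stature_cm" %in% names(data)) {
    v <- suppressWarnings(as.numeric(data$stature_cm))
    data$stature_cm <- v
    bad <- !is.na(v) & (v <= 30 | v >= 230)
    for (i in which(bad)) {
      errors <- c(errors, sprintf("row %d: stature_cm = %s outside (30, 230) cm", i, format(v[i])))
    }
    data$stature_cm[bad] <- NA_real_
    bad_rows <- bad_rows | bad
  }
  list(data = data, errors = errors, bad_rows = which(bad_rows))
}
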