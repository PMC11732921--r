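# Embedded registry of the 38 published stature models, shipped as a JSON
# asset. Coefficients are stored exactly as printed (~3 significant figures);
# registry predictions are defined by those printed values, not by refits.

registry_md5 <- "65f0e9a25c3a408c025e3ce2d667c36d"

#' Load the published model registry
#'
#' Returns the 38 published pooled-sex regression models: a linear model for
#' each of the 20 measurements plus a nonlinear model (asymptotic exponential
#' for lengths, three-parameter logistic for breadths) for 18 of them — the
#' tibia and radius distal-breadth nonlinear models never converged and are
#' absent. Each entry carries the published per-model performance metrics
#' (Kendall's tau, residual SD, Kolmogorov–Smirnov D, 95%-PI test accuracy,
#' MAD). Two entries whose printed `c` coefficients are an order of magnitude
#' below all sibling breadth models (tibia midshaft, radius proximal
#' logistic) are kept verbatim but carry `sanity_flag = TRUE`; predictions
#' from them attach a warning.
#'
#' @param path Path to a registry JSON asset; defaults to the one shipped
#'   with the package (whose MD5 checksum is verified at load).
#' @return A tibble with one row per model: `bone`, `measurement`, `family`,
#'   coefficient columns `a`, `b`, `c` (`c` is `NA` for linear models), the
#'   printed metric columns (`kendall_tau`, `residual_sd_cm`, `ks_D`,
#'   `test_accuracy_pct`, `mad_cm`), `sanity_flag`, and a `model` list-column
#'   of [stature_model()] objects. The registry version is attached as the
#'   `registry_version` attribute.
#' @examples
#' reg <- load_registry()
#' nrow(reg) # 38
#' @export
load_registry <- function(path = NULL) {
  default <- is.null(path)
  if (default) path <- system.file("extdata", "registry.json", package = "staturekit")
  if (!nzchar(path) || !file.exists(path)) abort("Registry asset not found.")
  if (default && unname(tools::md5sum(path)) != registry_md5) {
    abort("Registry asset failed its integrity check (MD5 mismatch).")
  }
  raw <- jsonlite::read_json(path)
  entries <- raw$entries
  rows <- map(entries, function(e) {
    co <- unlist(e$coefficients)
    tibble(
      bone = e$bone, measurement = e$measurement, family = e$family,
      a = co[["a"]], b = co[["b"]],
      c = if ("c" %in% names(co)) co[["c"]] else NA_real_,
      kendall_tau = e$printed_metrics$kendall_tau %||% NA_real_,
      residual_sd_cm = e$printed_metrics$residual_sd_cm %||% NA_real_,
      ks_D = e$printed_metrics$ks_D %||% NA_real_,
      test_accuracy_pct = e$printed_metrics$test_accuracy_pct %||% NA_real_,
      mad_cm = e$printed_metrics$mad_cm %||% NA_real_,
      sanity_flag = isTRUE(e$sanity_flag)
    )
  })
  out <- list_rbind(rows)
  out$model <- pmap(out[, c("bone", "measurement", "family", "a", "b", "c",
                            "residual_sd_cm", "sanity_flag")],
    function(bone, measurement, family, a, b, c, residual_sd_cm, sanity_flag) {
      co <- if (family == "linear") c(a = a, b = b) else c(a = a, b = b, c = c)
      stature_model(bone, measurement, family, co,
                    residual_sd = residual_sd_cm,
                    sanity_flag = sanity_flag, source = "registry")
    }
  )
  if (nrow(out) != 38) abort("Registry asset is malformed: expected 38 entries.")
  attr(out, "registry_version") <- raw$registry_version
  out
}

#' Default plausible-adult reference measurements
#'
#' One typical adult value (mm) per measurement, used by
#' [registry_sanity_check()] to probe each registry model for implausible
#' output.
#'
#' @return Named numeric vector keyed by canonical column name.
#' @export
reference_measurements <- function() {
  c(
    humerus_length_mm = 320, humerus_proximal_breadth_mm = 44,
    humerus_midshaft_breadth_mm = 21, humerus_distal_breadth_mm = 60,
    radius_length_mm = 240, radius_proximal_breadth_mm = 22,
    radius_midshaft_breadth_mm = 15, radius_distal_breadth_mm = 31,
    ulna_length_mm = 255, ulna_midshaft_breadth_mm = 14,
    femur_length_mm = 450, femur_midshaft_breadth_mm = 25,
    femur_distal_breadth_mm = 79,
    tibia_length_mm = 370, tibia_proximal_breadth_mm = 70,
    tibia_midshaft_breadth_mm = 25, tibia_distal_breadth_mm = 49,
    fibula_length_mm = 365,
    upper_limb_length_mm = 555, lower_limb_length_mm = 815
  )
}

#' Sanity-check registry models at reference adult measurements
#'
#' Evaluates every registry model at a typical adult value of its measurement
#' and flags entries whose predicted stature falls outside the plausible
#' adult band of 140–200 cm — a guard against transcription errors in the
#' printed coefficients.
#'
#' @param registry A registry tibble from [load_registry()].
#' @param reference_inputs Named vector of typical adult measurements (mm)
#'   keyed by canonical column name; must cover all 20 measurements.
#'   Defaults to [reference_measurements()].
#' @return The flagged subset of the registry, with the probe input
#'   (`reference_mm`) and its prediction (`reference_pred_cm`) appended.
#' @examples
#' registry_sanity_check(load_registry())
#' @export
registry_sanity_check <- function(registry = load_registry(),
                                  reference_inputs = reference_measurements()) {
  need <- measurement_columns()
  if (!all(need %in% names(reference_inputs))) {
    abort(paste0("reference_inputs must cover all 20 measurements; missing: ",
                 paste(setdiff(need, names(reference_inputs)), collapse = ", ")))
  }
  key <- paste0(registry$bone, "_", registry$measurement, "_mm")
  registry$reference_mm <- unname(reference_inputs[key])
  registry$reference_pred_cm <- map_dbl(
    seq_len(nrow(registry)),
    function(i) evaluate_model(registry$model[[i]], registry$reference_mm[i])
  )
  out_of_band <- registry$reference_pred_cm < 140 | registry$reference_pred_cm > 200
  registry$sanity_flag <- registry$sanity_flag | out_of_band
  for (i in seq_len(nrow(registry))) {
    registry$model[[i]]$sanity_flag <- registry$sanity_flag[i]
  }
  registry[registry$sanity_flag, , drop = FALSE]
}
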