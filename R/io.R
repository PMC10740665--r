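pkg_version_string <- function() {
  as.character(utils::packageVersion("abvisc"))
}

read_numeric_column <- function(df, col, path) {
  raw <- df[[col]]
  if (is.null(raw)) return(NULL)
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & trimws(raw) != "" & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparseable number in %s, column '%s', row %d: \"%s\"",
                 path, col, bad[1], raw[bad[1]]), call. = FALSE)
  }
  out[trimws(as.character(raw)) == ""] <- NA_real_
  out
}

#' Read a cohort from CSV files
#'
#' Reads the molecules table and (optionally) the long-format viscosity
#' table, validates them and assembles an [ab_cohort()]. Duplicate
#' molecule ids and unparseable numbers are hard errors naming the
#' offender; readings outside the plausible instrument ranges (D_np
#' outside 0-20 um^2/s, |kD| > 200 mL/g) only raise warnings.
#'
#' Expected columns — molecules: `molecule_id` plus any of
#' `dnp_um2_per_s`, `kd_ml_per_g`, `plasmon_shift_nm`, `split`;
#' viscosity: `molecule_id`, `conc_mg_ml`, `visc_cP`. Units are part of
#' the column names.
#'
#' @param molecules_path Path to the molecules CSV (UTF-8, header row,
#'   decimal point).
#' @param viscosity_path Optional path to the viscosity CSV; omitted or
#'   empty gives records with empty profiles.
#' @return An [ab_cohort()].
#' @export
read_cohort <- function(molecules_path, viscosity_path = NULL) {
  mol <- utils::read.csv(molecules_path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (!"molecule_id" %in% names(mol)) {
    stop(sprintf("%s lacks required column 'molecule_id'", molecules_path),
         call. = FALSE)
  }
  for (col in c("dnp_um2_per_s", "kd_ml_per_g", "plasmon_shift_nm")) {
    if (col %in% names(mol)) {
      mol[[col]] <- read_numeric_column(mol, col, molecules_path)
    }
  }
  visc <- NULL
  if (!is.null(viscosity_path)) {
    visc <- utils::read.csv(viscosity_path, stringsAsFactors = FALSE,
                            colClasses = "character",
                            fileEncoding = "UTF-8")
    if (nrow(visc) == 0) {
      visc <- data.frame(molecule_id = character(), conc_mg_ml = numeric(),
                         visc_cP = numeric())
    } else {
      for (col in c("conc_mg_ml", "visc_cP")) {
        visc[[col]] <- read_numeric_column(visc, col, viscosity_path)
      }
    }
  }
  cohort <- ab_cohort(mol, visc)
  m <- cohort$molecules
  odd_dnp <- !is.na(m$dnp_um2_per_s) &
    (m$dnp_um2_per_s < 0 | m$dnp_um2_per_s > 20)
  if (any(odd_dnp)) {
    warning("D_np outside the plausible 0-20 um^2/s range for: ",
            paste(m$molecule_id[odd_dnp], collapse = ", "), call. = FALSE)
  }
  odd_kd <- !is.na(m$kd_ml_per_g) & abs(m$kd_ml_per_g) > 200
  if (any(odd_kd)) {
    warning("|kD| above 200 mL/g (implausible for an antibody) for: ",
            paste(m$molecule_id[odd_kd], collapse = ", "), call. = FALSE)
  }
  cohort
}

#' Write a cohort to CSV files
#'
#' @param cohort An [ab_cohort()].
#' @param molecules_path Output path for the molecules table.
#' @param viscosity_path Optional output path for the viscosity table.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, molecules_path, viscosity_path = NULL) {
  stopifnot(inherits(cohort, "ab_cohort"))
  utils::write.csv(cohort$molecules, molecules_path, row.names = FALSE,
                   quote = FALSE, na = "")
  if (!is.null(viscosity_path)) {
    utils::write.csv(cohort$viscosity, viscosity_path, row.names = FALSE,
                     quote = FALSE, na = "")
  }
  invisible(cohort)
}

#' Default configuration
#'
#' All tunable constants of the pipeline in one nested list: the viscosity
#' law (`model`), the exclusion thresholds (`exclusions`), the calibration
#' line coefficients (`lines`, defaulting to the published reference
#' values), the screening settings (`screening`: cutoff and prediction
#' grid) and the `seed`.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    model = list(A = 5.4e-8, nu = 0.6),
    exclusions = list(dnp_min = 1.0, kd_abs_max = 60,
                      k_branching_max = 0.01, entanglement_floor = 100,
                      ht_separator = NULL),
    lines = list(acsins = list(intercept = 4.9, slope = 2045),
                 dls = list(intercept = 56.03, slope = 15000)),
    screening = list(cutoff_cP = 20,
                     grid = list(from = 70, to = 250, by = 10)),
    seed = NULL
  )
}

check_config_keys <- function(config, template, path = "") {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && length(names(template[[nm]])) &&
        !is.null(config[[nm]])) {
      if (!is.list(config[[nm]])) {
        stop(sprintf("config key '%s%s' must be a mapping", path, nm),
             call. = FALSE)
      }
      check_config_keys(config[[nm]], template[[nm]],
                        paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]) &&
        length(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]])
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

validate_config <- function(config) {
  # constructing the parameter objects runs their invariant checks
  model_params(config$model$A, config$model$nu)
  exclusion_config(
    dnp_min = config$exclusions$dnp_min,
    kd_abs_max = config$exclusions$kd_abs_max,
    k_branching_max = config$exclusions$k_branching_max,
    ht_separator = config$exclusions$ht_separator,
    entanglement_floor = config$exclusions$entanglement_floor
  )
  for (src in c("acsins", "dls")) {
    calibration_line(src, config$lines[[src]]$intercept,
                     config$lines[[src]]$slope)
  }
  if (config$screening$cutoff_cP <= 0) {
    stop("screening cutoff must be positive", call. = FALSE)
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_config()]; unknown keys are an
#' error listing them; value constraints (positive `A`, `nu` > 1/3, finite
#' thresholds, positive cutoff) are enforced on read.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return Validated nested config list.
#' @export
read_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      check_config_keys(user, config)
      config <- merge_config(config, user)
    }
  }
  validate_config(config)
  config
}

#' Write a pipeline configuration to YAML
#'
#' Writing then reading yields an identical configuration (round-trip
#' stable); a version string is embedded as a comment header.
#'
#' @param config Nested config list as from [read_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  txt <- yaml::as.yaml(config)
  writeLines(c(sprintf("# abvisc config (version %s)",
                       pkg_version_string()), txt), path)
  invisible(path)
}

config_params <- function(config) model_params(config$model$A, config$model$nu)

config_exclusions <- function(config) {
  exclusion_config(
    dnp_min = config$exclusions$dnp_min,
    kd_abs_max = config$exclusions$kd_abs_max,
    k_branching_max = config$exclusions$k_branching_max,
    ht_separator = config$exclusions$ht_separator,
    entanglement_floor = config$exclusions$entanglement_floor
  )
}

config_lines <- function(config) {
  list(acsins = calibration_line("acsins", config$lines$acsins$intercept,
                                 config$lines$acsins$slope),
       dls = calibration_line("dls", config$lines$dls$intercept,
                              config$lines$dls$slope))
}

config_grid <- function(config) {
  g <- config$screening$grid
  seq(g$from, g$to, by = g$by)
}

#' Write a calibration report to JSON (and optionally the ledger to CSV)
#'
#' @param calibration An `"ab_calibration"` from [calibrate_cohort()].
#' @param json_path Output JSON path (line coefficients, diagnostics,
#'   exclusion ledger, version string).
#' @param ledger_path Optional CSV path for the exclusion ledger alone.
#' @return Invisibly, `json_path`.
#' @export
write_calibration <- function(calibration, json_path, ledger_path = NULL) {
  stopifnot(inherits(calibration, "ab_calibration"))
  line_payload <- function(l) {
    list(source = l$source, intercept = l$intercept, slope = l$slope,
         n_used = l$n_used, residual_sd = l$residual_sd,
         excluded = l$excluded)
  }
  payload <- list(
    abvisc_version = pkg_version_string(),
    acsins = line_payload(calibration$acsins),
    dls = line_payload(calibration$dls),
    suspected_ht = calibration$ht_ids
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(ledger_path)) {
    ledger <- do.call(rbind, lapply(c("acsins", "dls"), function(src) {
      ex <- calibration[[src]]$excluded
      data.frame(source = rep(src, nrow(ex)), ex)
    }))
    utils::write.csv(ledger, ledger_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}

#' Read calibration lines from a JSON report
#'
#' @param json_path Path written by [write_calibration()] (or any JSON
#'   with `acsins`/`dls` objects holding `intercept` and `slope`).
#' @return Named list of two [calibration_line()]s.
#' @export
read_calibration <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  mk <- function(src) {
    l <- payload[[src]]
    if (is.null(l)) stop(sprintf("no '%s' line in %s", src, json_path),
                         call. = FALSE)
    calibration_line(src, l$intercept, l$slope,
                     n_used = if (is.null(l$n_used)) NA_integer_ else l$n_used,
                     residual_sd = if (is.null(l$residual_sd)) NA_real_
                                   else l$residual_sd)
  }
  list(acsins = mk("acsins"), dls = mk("dls"))
}

#' Write screening results to CSV
#'
#' Column order is fixed and documented in [screen_cohort()]; one row per
#' molecule.
#'
#' @param screening An `"ab_screening"` from [screen_cohort()].
#' @param results_path Output CSV path for the per-molecule results.
#' @param curves_path Optional CSV path for the long-format predicted
#'   curves.
#' @return Invisibly, `results_path`.
#' @export
write_results <- function(screening, results_path, curves_path = NULL) {
  stopifnot(inherits(screening, "ab_screening"))
  cols <- c("molecule_id", "dnp_um2_per_s", "kd_ml_per_g",
            "K_acsins", "K_dls", "flags_acsins", "flags_dls",
            "eta150_acsins", "eta150_dls",
            "class_acsins", "class_dls", "class_combined")
  res <- screening$results
  extra <- setdiff(names(res), cols)
  utils::write.csv(res[, c(cols, extra), drop = FALSE], results_path,
                   row.names = FALSE, na = "")
  if (!is.null(curves_path)) {
    utils::write.csv(screening$curves, curves_path, row.names = FALSE,
                     na = "")
  }
  invisible(results_path)
}

#' Bundled example panels
#'
#' Two small published evaluation panels shipped with the package:
#' a 17-molecule validation panel (`"validation"`) carrying experimental
#' concentration and viscosity plus AC-SINS and DLS viscosity predictions
#' at both the experimental concentration and 150 mg/mL, and a 9-molecule
#' test panel (`"test"`) with experimental and predicted viscosity at
#' 150 mg/mL. Both include the published performance labels. All
#' viscosities are in cP, concentrations in mg/mL.
#'
#' @param which `"validation"` or `"test"`.
#' @return Data frame.
#' @export
example_panel <- function(which = c("validation", "test")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0(which, "_panel.csv"), package = "abvisc",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
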