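#' A linear calibration between a dilute measurement and the dimerization constant
#'
#' Represents `measurement = intercept - slope * K`: as self-association
#' strengthens (larger K, mL/mg), both AC-SINS nanoparticle diffusion and
#' the DLS interaction parameter decrease, so `slope` is positive under
#' this sign convention. At `K = 0` the line returns the measurement of a
#' non-associating molecule (`intercept`).
#'
#' @param source `"acsins"` (measurement is D_np, um^2/s) or `"dls"`
#'   (measurement is kD, mL/g).
#' @param intercept Measurement at K = 0, in measurement units.
#' @param slope Decline per unit K, measurement units per (mL/mg). Positive
#'   under the sign convention above.
#' @param n_used Number of molecules behind the fit (`NA` for published
#'   reference coefficients).
#' @param excluded Data frame (`molecule_id`, `reason`) of molecules
#'   excluded from the fit.
#' @param residual_sd Residual standard deviation of the fit, measurement
#'   units.
#' @return Object of class `"calibration_line"`.
#' @export
calibration_line <- function(source, intercept, slope, n_used = NA_integer_,
                             excluded = NULL,
                             residual_sd = NA_real_) {
  source <- match.arg(source, c("acsins", "dls"))
  if (!is.finite(intercept) || !is.finite(slope)) {
    stop("'intercept' and 'slope' must be finite", call. = FALSE)
  }
  if (slope <= 0) {
    warning("calibration slope is not positive: the measurement should ",
            "decrease with increasing K; check the input pairs",
            call. = FALSE)
  }
  if (is.null(excluded)) {
    excluded <- data.frame(molecule_id = character(), reason = character())
  }
  structure(list(source = source, intercept = intercept, slope = slope,
                 n_used = as.integer(n_used), excluded = excluded,
                 residual_sd = residual_sd),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  unit <- if (x$source == "acsins") "um^2/s" else "mL/g"
  meas <- if (x$source == "acsins") "D_np" else "kD"
  cat(sprintf("Calibration line [%s]: %s = %g - %g * K   (%s; K in mL/mg)\n",
              x$source, meas, x$intercept, x$slope, unit))
  if (!is.na(x$n_used)) {
    cat(sprintf("  fitted on %d molecule(s), %d excluded, residual sd %.3g %s\n",
                x$n_used, nrow(x$excluded), x$residual_sd, unit))
  }
  invisible(x)
}

#' Published reference calibration lines
#'
#' The calibration coefficients reported for an 89-mAb development cohort:
#' `D_np = 4.9 - 2045 K` (AC-SINS) and `kD = 56.03 - 15000 K` (DLS), with
#' K in mL/mg, D_np in um^2/s and kD in mL/g. Shipped as constants so
#' prediction works without refitting a training cohort.
#'
#' @return Named list with `calibration_line` elements `acsins` and `dls`.
#' @export
reference_lines <- function() {
  list(
    acsins = calibration_line("acsins", intercept = 4.9, slope = 2045),
    dls = calibration_line("dls", intercept = 56.03, slope = 15000)
  )
}

#' Fit the dimerization constant for every molecule in a training cohort
#'
#' Runs [fit_k_profile()] on each molecule's viscosity profile. Molecules
#' whose fitted K is not positive are flagged `non_entangled` (their
#' viscosity sits at or below the monomer baseline, so the reptation law
#' does not apply); molecules with no usable points at or above the
#' entanglement floor are skipped with a recorded reason rather than an
#' error.
#'
#' @param cohort An [ab_cohort()].
#' @param params A [model_params()] object.
#' @param exclusions An [exclusion_config()]; only `entanglement_floor` is
#'   used here.
#' @return Data frame with one row per molecule: `molecule_id`,
#'   `K_ml_per_mg`, `non_entangled`, `n_points`, `used`, `reason`.
#' @export
fit_training_k <- function(cohort, params = model_params(),
                           exclusions = exclusion_config()) {
  stopifnot(inherits(cohort, "ab_cohort"))
  ids <- cohort$molecules$molecule_id
  out <- lapply(ids, function(id) {
    prof <- molecule_profile(cohort, id)
    prof <- prof[is.finite(prof$conc_mg_ml) & is.finite(prof$visc_cP), ]
    if (nrow(prof) == 0) {
      return(data.frame(molecule_id = id, K_ml_per_mg = NA_real_,
                        non_entangled = NA, n_points = 0L, used = FALSE,
                        reason = "no_viscosity_data"))
    }
    if (!any(prof$conc_mg_ml >= exclusions$entanglement_floor)) {
      return(data.frame(molecule_id = id, K_ml_per_mg = NA_real_,
                        non_entangled = NA, n_points = 0L, used = FALSE,
                        reason = "below_entanglement_floor"))
    }
    est <- suppressWarnings(
      fit_k_profile(prof, params, exclusions$entanglement_floor)
    )
    data.frame(molecule_id = id, K_ml_per_mg = est$value,
               non_entangled = has_flag(est, "non_entangled"),
               n_points = est$details$n_used, used = TRUE,
               reason = NA_character_)
  })
  do.call(rbind, out)
}

#' Flag suspected head-to-tail binders from the D_np vs kD relation
#'
#' AC-SINS tethers antibodies to nanoparticles, which can sterically hide
#' a head-to-tail (CDR-to-framework) binding site; DLS sees the untethered
#' molecule. A head-to-tail binder therefore shows anomalously fast
#' nanoparticle diffusion relative to its kD. Molecules above a separator
#' line in (kD, D_np) space — `D_np > intercept + slope * kD` — are flagged
#' as suspected head-to-tail binders.
#'
#' The separator must be supplied by the user (placed between the main
#' trend and the outlying population); when it is unset the function warns
#' and flags nothing.
#'
#' @param cohort An [ab_cohort()]; molecules missing either measurement are
#'   never flagged.
#' @param separator `NULL`, or a list/vector with `slope` and `intercept`
#'   (D_np units: um^2/s; kD units: mL/g). Usually taken from
#'   `exclusion_config()$ht_separator`.
#' @return Character vector of flagged `molecule_id`s (possibly empty).
#' @export
detect_ht_outliers <- function(cohort, separator = NULL) {
  stopifnot(inherits(cohort, "ab_cohort"))
  if (is.null(separator)) {
    warning("HT separator is unset: no head-to-tail outliers will be ",
            "flagged (the separator must be placed by inspection of the ",
            "D_np vs kD scatter)", call. = FALSE)
    return(character())
  }
  separator <- as.list(separator)
  m <- cohort$molecules
  ok <- !is.na(m$dnp_um2_per_s) & !is.na(m$kd_ml_per_g)
  above <- ok & m$dnp_um2_per_s >
    separator$intercept + separator$slope * m$kd_ml_per_g
  m$molecule_id[above]
}

#' Fit one calibration line with the screening exclusion rules
#'
#' Ordinary least squares of the dilute measurement on K — the orientation
#' `measurement = intercept - slope * K` in which the calibration is
#' expressed — after applying the per-assay exclusion rules:
#' \itemize{
#'   \item both assays: drop `non_entangled` molecules (fitted K <= 0, the
#'     reptation law is inapplicable) and missing measurements;
#'   \item AC-SINS: drop molecules with `D_np <= dnp_min` (sensitivity
#'     breakdown in the strong-interaction regime) and suspected
#'     head-to-tail binders;
#'   \item DLS: drop `|kD| > kd_abs_max` (implausible for an antibody,
#'     suggesting experimental error) and `K > k_branching_max`
#'     (branched complexes, outside the linear-chain law).
#' }
#' Every input molecule lands exactly once in either the fit or the
#' exclusion ledger with its reason (first matching rule wins).
#'
#' @param pairs Data frame with columns `molecule_id`, `K` (mL/mg) and
#'   `measurement`; optional logical columns `non_entangled` and
#'   `suspected_ht` (default `FALSE`/taken as not flagged).
#' @param source `"acsins"` or `"dls"`.
#' @param exclusions An [exclusion_config()].
#' @return A [calibration_line()] carrying the fit diagnostics and the
#'   exclusion ledger.
#' @export
fit_calibration_line <- function(pairs, source = c("acsins", "dls"),
                                 exclusions = exclusion_config()) {
  source <- match.arg(source)
  pairs <- as.data.frame(pairs)
  need <- c("molecule_id", "K", "measurement")
  if (!all(need %in% names(pairs))) {
    stop("'pairs' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"non_entangled" %in% names(pairs)) pairs$non_entangled <- FALSE
  if (!"suspected_ht" %in% names(pairs)) pairs$suspected_ht <- FALSE

  reason <- rep(NA_character_, nrow(pairs))
  mark <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  mark(is.na(pairs$measurement), "missing_measurement")
  mark(is.na(pairs$K), "no_K_fit")
  mark(pairs$non_entangled %in% TRUE, "non_entangled")
  if (source == "acsins") {
    mark(pairs$measurement <= exclusions$dnp_min, "low_dnp_sensitivity")
    mark(pairs$suspected_ht %in% TRUE, "suspected_ht")
  } else {
    mark(abs(pairs$measurement) > exclusions$kd_abs_max, "kd_out_of_range")
    mark(pairs$K > exclusions$k_branching_max, "above_branching_cutoff")
  }
  use <- is.na(reason)
  ledger <- data.frame(molecule_id = pairs$molecule_id[!use],
                       reason = reason[!use])
  if (sum(use) < 3) {
    msg <- paste0(
      "fewer than 3 molecules survive the ", source, " exclusions (",
      sum(use), " left); exclusion ledger:\n",
      paste(sprintf("  %s: %s", ledger$molecule_id, ledger$reason),
            collapse = "\n"))
    stop(msg, call. = FALSE)
  }
  fit <- stats::lm(measurement ~ K, data = pairs[use, ])
  co <- stats::coef(fit)
  line <- calibration_line(
    source, intercept = unname(co[1]), slope = -unname(co[2]),
    n_used = sum(use), excluded = ledger,
    residual_sd = summary(fit)$sigma
  )
  line$used_ids <- pairs$molecule_id[use]
  line$slope_se <- summary(fit)$coefficients["K", "Std. Error"]
  line
}

#' Calibrate both assay lines from a training cohort
#'
#' End-to-end training: fit K per molecule from its viscosity profile
#' ([fit_training_k()]), flag suspected head-to-tail binders
#' ([detect_ht_outliers()]), then fit the AC-SINS and DLS calibration
#' lines with the exclusion rules ([fit_calibration_line()]).
#'
#' @param cohort An [ab_cohort()] whose molecules carry viscosity profiles.
#' @param params A [model_params()] object.
#' @param exclusions An [exclusion_config()]; set `ht_separator` to enable
#'   head-to-tail exclusion.
#' @param use_split If non-`NULL`, restrict to molecules whose `split`
#'   label equals this value (e.g. `"train"`).
#' @return Object of class `"ab_calibration"`: list with elements `acsins`
#'   and `dls` ([calibration_line()]s), `k_table` (the per-molecule K
#'   fits), `ht_ids` and `exclusions`.
#' @export
calibrate_cohort <- function(cohort, params = model_params(),
                             exclusions = exclusion_config(),
                             use_split = NULL) {
  stopifnot(inherits(cohort, "ab_cohort"))
  if (!is.null(use_split)) {
    keep <- cohort$molecules$split %in% use_split
    cohort <- ab_cohort(cohort$molecules[keep, , drop = FALSE],
                        cohort$viscosity[cohort$viscosity$molecule_id %in%
                                           cohort$molecules$molecule_id[keep], ,
                                         drop = FALSE])
  }
  k_table <- fit_training_k(cohort, params, exclusions)
  ht_ids <- if (is.null(exclusions$ht_separator)) {
    suppressWarnings(detect_ht_outliers(cohort, NULL))
  } else {
    detect_ht_outliers(cohort, exclusions$ht_separator)
  }
  m <- cohort$molecules
  base <- merge(k_table, m[, c("molecule_id", "dnp_um2_per_s", "kd_ml_per_g")],
                by = "molecule_id", sort = FALSE)
  base$suspected_ht <- base$molecule_id %in% ht_ids
  mk_pairs <- function(col) {
    data.frame(molecule_id = base$molecule_id, K = base$K_ml_per_mg,
               measurement = base[[col]],
               non_entangled = base$non_entangled %in% TRUE,
               suspected_ht = base$suspected_ht)
  }
  structure(list(
    acsins = fit_calibration_line(mk_pairs("dnp_um2_per_s"), "acsins",
                                  exclusions),
    dls = fit_calibration_line(mk_pairs("kd_ml_per_g"), "dls", exclusions),
    k_table = k_table, ht_ids = ht_ids, exclusions = exclusions
  ), class = "ab_calibration")
}

#' @export
print.ab_calibration <- function(x, ...) {
  cat("Antibody viscosity calibration\n")
  print(x$acsins)
  print(x$dls)
  if (length(x$ht_ids)) {
    cat("  suspected HT binders:", paste(x$ht_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Randomly split a cohort into train/validation/test sets
#'
#' Seeded permutation split; labels are written into the cohort's `split`
#' column. The seed is required so every split is reproducible.
#'
#' @param cohort An [ab_cohort()].
#' @param sizes Integer vector `c(train, validation, test)` summing to the
#'   cohort size.
#' @param seed Integer seed (required; no hidden default).
#' @return The cohort with `split` labels assigned.
#' @export
split_cohort <- function(cohort, sizes, seed) {
  stopifnot(inherits(cohort, "ab_cohort"))
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required for a reproducible split", call. = FALSE)
  }
  sizes <- as.integer(sizes)
  if (length(sizes) != 3 || any(sizes < 0)) {
    stop("'sizes' must be c(train, validation, test), all non-negative",
         call. = FALSE)
  }
  n <- nrow(cohort$molecules)
  if (sum(sizes) != n) {
    stop(sprintf("split sizes sum to %d but the cohort has %d molecules",
                 sum(sizes), n), call. = FALSE)
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  labels <- rep(c("train", "validation", "test"), times = sizes)
  cohort$molecules$split[perm] <- labels
  cohort
}
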