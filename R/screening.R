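#' Estimate the dimerization constant from one dilute measurement
#'
#' Inverts a calibration line: `K = (intercept - measurement) / slope`.
#' A measurement above the intercept gives a negative raw K, which is
#' clamped to 0 for prediction (the reptation law models associative
#' entanglement only; a non-associating molecule sits on the monomer
#' baseline) and flagged `clamped_to_zero` with the raw value retained.
#' Applicability flags: `low_sensitivity_dnp` when an AC-SINS reading lies
#' below the sensitivity floor (strictly below; the floor itself is still
#' considered usable), and `above_branching_cutoff` when the implied K
#' exceeds the branching cutoff.
#'
#' @param x The measurement: D_np in um^2/s for an AC-SINS line, kD in
#'   mL/g for a DLS line. `NA` returns an absent-result marker (a
#'   [k_estimate()] with `NA` value and flag `missing_measurement`), not
#'   an error.
#' @param line A [calibration_line()].
#' @param exclusions An [exclusion_config()] supplying the thresholds.
#' @return A [k_estimate()] with `source` taken from the line.
#' @examples
#' k_from_measurement(4.9, reference_lines()$acsins)$value   # 0
#' k_from_measurement(41.03, reference_lines()$dls)$value    # 1e-3
#' @export
k_from_measurement <- function(x, line, exclusions = exclusion_config()) {
  stopifnot(inherits(line, "calibration_line"))
  if (length(x) != 1) stop("'x' must be a scalar", call. = FALSE)
  if (is.na(x)) {
    return(k_estimate(NA_real_, source = line$source,
                      flags = "missing_measurement", raw = NA_real_))
  }
  raw <- (line$intercept - x) / line$slope
  flags <- character()
  value <- raw
  if (raw < 0) {
    value <- 0
    flags <- c(flags, "clamped_to_zero")
  }
  if (line$source == "acsins" && x < exclusions$dnp_min) {
    flags <- c(flags, "low_sensitivity_dnp")
  }
  if (value > exclusions$k_branching_max) {
    flags <- c(flags, "above_branching_cutoff")
  }
  k_estimate(value, source = line$source, flags = flags, raw = raw)
}

#' Predict a concentration-viscosity curve
#'
#' Evaluates the reptation viscosity law along a concentration grid for a
#' given dimerization constant. Points below the entanglement floor are
#' still evaluated but flagged: there the solution is too dilute for
#' entangled dynamics and the prediction is unreliable.
#'
#' @param K A [k_estimate()] (its `value` is used) or a plain number in
#'   mL/mg.
#' @param concentrations Concentration grid, mg/mL; the default 10 mg/mL
#'   steps over 70-250 mg/mL covers the usual experimental range.
#' @param params A [model_params()] object.
#' @param entanglement_floor mg/mL; below it predictions are flagged.
#' @return Data frame with columns `conc_mg_ml`, `visc_cP`,
#'   `below_entanglement_floor`.
#' @export
predict_curve <- function(K, concentrations = seq(70, 250, by = 10),
                          params = model_params(),
                          entanglement_floor = 100) {
  k <- if (inherits(K, "k_estimate")) K$value else K
  if (is.na(k)) {
    return(data.frame(conc_mg_ml = concentrations, visc_cP = NA_real_,
                      below_entanglement_floor =
                        concentrations < entanglement_floor))
  }
  if (any(concentrations <= 0)) {
    stop("'concentrations' must be positive", call. = FALSE)
  }
  data.frame(
    conc_mg_ml = concentrations,
    visc_cP = viscosity(k, concentrations, params),
    below_entanglement_floor = concentrations < entanglement_floor
  )
}

#' Binary developability call on a predicted or measured viscosity
#'
#' A molecule is `"good"` when its viscosity at 150 mg/mL is at or below
#' the cutoff (boundary inclusive: exactly 20 cP is still good) and
#' `"bad"` above it.
#'
#' @param eta150 Viscosity at 150 mg/mL, cP. Vectorized; `NA` propagates.
#' @param cutoff Developability threshold, cP.
#' @return Character vector of `"good"`/`"bad"`.
#' @export
classify_viscosity <- function(eta150, cutoff = 20) {
  if (any(eta150 < 0, na.rm = TRUE)) {
    stop("'eta150' must be non-negative", call. = FALSE)
  }
  ifelse(is.na(eta150), NA_character_,
         ifelse(eta150 <= cutoff, "good", "bad"))
}

#' Screening performance label for a molecule
#'
#' Compares the two dilute-solution predictions against the experimental
#' viscosity at the developability cutoff ("high" means strictly above the
#' cutoff):
#' \itemize{
#'   \item `"False positive"` — both predictions suggest low viscosity but
#'     the experiment shows high viscosity (a viscous molecule the screen
#'     would wave through);
#'   \item `"False negative"` — at least one prediction suggests high
#'     viscosity but the experiment shows low viscosity (a good molecule
#'     the screen would discard);
#'   \item `"TRUE"` — every other combination.
#' }
#' Note this naming is molecule-centric ("positive" = passes the screen)
#' and is the reverse of the detection convention in which flagging a
#' viscous molecule is the positive event. [standard_label()] converts to
#' the detection convention.
#'
#' A missing prediction is ignored and the label is computed from the
#' available source(s); if both are missing the label is `NA`.
#'
#' @param pred_acsins AC-SINS-predicted viscosity, cP.
#' @param pred_dls DLS-predicted viscosity, cP.
#' @param experimental Measured viscosity, cP.
#' @param cutoff Developability threshold, cP.
#' @return Character vector over the recycled inputs, values in
#'   `c("TRUE", "False positive", "False negative")`.
#' @examples
#' performance_label(12.8, 17.5, 34.2) # "False positive"
#' performance_label(20.0, 24.1, 13.4) # "False negative"
#' performance_label(10.4, 21.0, 25.9) # "TRUE"
#' @export
performance_label <- function(pred_acsins, pred_dls, experimental,
                              cutoff = 20) {
  n <- max(length(pred_acsins), length(pred_dls), length(experimental))
  pa <- rep_len(pred_acsins, n)
  pd <- rep_len(pred_dls, n)
  ex <- rep_len(experimental, n)
  vapply(seq_len(n), function(i) {
    if (is.na(ex[i]) || (is.na(pa[i]) && is.na(pd[i]))) {
      return(NA_character_)
    }
    preds <- c(pa[i], pd[i])
    preds <- preds[!is.na(preds)]
    any_pred_high <- any(preds > cutoff)
    exp_high <- ex[i] > cutoff
    if (exp_high && !any_pred_high) return("False positive")
    if (!exp_high && any_pred_high) return("False negative")
    "TRUE"
  }, character(1))
}

#' Translate performance labels into the standard detection convention
#'
#' In the detection convention the positive event is flagging a viscous
#' molecule, so a screen that misses a viscous molecule commits a false
#' negative and a screen that wrongly flags a good molecule commits a
#' false positive — the reverse of [performance_label()]'s
#' molecule-centric naming.
#'
#' @param label Character vector as returned by [performance_label()].
#' @return Character vector with values `"true"`, `"false_negative"`
#'   (missed viscous molecule), `"false_positive"` (good molecule wrongly
#'   flagged).
#' @export
standard_label <- function(label) {
  map <- c("TRUE" = "true",
           "False positive" = "false_negative",
           "False negative" = "false_positive")
  out <- unname(map[label])
  out[is.na(label)] <- NA_character_
  out
}

#' Screen a cohort: dilute measurements to viscosity calls
#'
#' For each molecule, estimates K from each available dilute measurement
#' via the calibration lines, predicts the concentration-viscosity curve,
#' evaluates the 150 mg/mL viscosity, and applies the developability
#' cutoff. The combined call is conservative: a molecule is flagged
#' (`"bad"`) when any source predicts viscosity above the cutoff.
#'
#' @param cohort An [ab_cohort()] with `dnp_um2_per_s` and/or `kd_ml_per_g`
#'   filled in.
#' @param lines Calibration lines as from [reference_lines()] or
#'   [calibrate_cohort()] (any list with `acsins` and `dls` elements).
#' @param params A [model_params()] object.
#' @param exclusions An [exclusion_config()].
#' @param concentrations Prediction grid, mg/mL.
#' @param cutoff Developability threshold, cP.
#' @return Object of class `"ab_screening"`: list with `results` (one row
#'   per molecule: K and flags per source, `eta150_*`, `class_*`) and
#'   `curves` (long format: `molecule_id`, `source`, `conc_mg_ml`,
#'   `visc_cP`, `below_entanglement_floor`).
#' @export
screen_cohort <- function(cohort, lines = reference_lines(),
                          params = model_params(),
                          exclusions = exclusion_config(),
                          concentrations = seq(70, 250, by = 10),
                          cutoff = 20) {
  stopifnot(inherits(cohort, "ab_cohort"))
  m <- cohort$molecules
  grid <- sort(unique(c(concentrations, 150)))
  rows <- list()
  curves <- list()
  for (i in seq_len(nrow(m))) {
    id <- m$molecule_id[i]
    k_a <- k_from_measurement(m$dnp_um2_per_s[i], lines$acsins, exclusions)
    k_d <- k_from_measurement(m$kd_ml_per_g[i], lines$dls, exclusions)
    eta150 <- c(acsins = NA_real_, dls = NA_real_)
    for (src in c("acsins", "dls")) {
      est <- if (src == "acsins") k_a else k_d
      cv <- predict_curve(est, grid, params, exclusions$entanglement_floor)
      eta150[src] <- cv$visc_cP[cv$conc_mg_ml == 150]
      cv$molecule_id <- id
      cv$source <- src
      curves[[paste(id, src)]] <-
        cv[, c("molecule_id", "source", "conc_mg_ml", "visc_cP",
               "below_entanglement_floor")]
    }
    cls <- classify_viscosity(eta150, cutoff)
    combined <- if (all(is.na(cls))) NA_character_
                else if (any(cls == "bad", na.rm = TRUE)) "bad" else "good"
    rows[[id]] <- data.frame(
      molecule_id = id,
      dnp_um2_per_s = m$dnp_um2_per_s[i], kd_ml_per_g = m$kd_ml_per_g[i],
      K_acsins = k_a$value, K_dls = k_d$value,
      flags_acsins = paste(k_a$flags, collapse = ";"),
      flags_dls = paste(k_d$flags, collapse = ";"),
      eta150_acsins = unname(eta150["acsins"]),
      eta150_dls = unname(eta150["dls"]),
      class_acsins = cls[["acsins"]], class_dls = cls[["dls"]],
      class_combined = combined
    )
  }
  structure(list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
                 curves = do.call(rbind, c(curves, make.row.names = FALSE)),
                 cutoff = cutoff),
            class = "ab_screening")
}

#' @export
print.ab_screening <- function(x, ...) {
  r <- x$results
  cat(sprintf("ab_screening: %d molecule(s), cutoff %g cP at 150 mg/mL\n",
              nrow(r), x$cutoff))
  cat(sprintf("  flagged (any source > %g cP): %d\n", x$cutoff,
              sum(r$class_combined == "bad", na.rm = TRUE)))
  invisible(x)
}

#' Summarize screening performance against experimental viscosity
#'
#' Tallies a prediction table against measured viscosities at the
#' developability cutoff: how many molecules the screen flagged (any
#' source predicted above the cutoff), how many were experimentally
#' viscous, and how many viscous molecules both sources missed. Per-row
#' performance labels follow [performance_label()].
#'
#' @param predictions Data frame with columns `molecule_id`,
#'   `pred_acsins`, `pred_dls` and `experimental` (all viscosities in cP
#'   at a common concentration, conventionally 150 mg/mL).
#' @param cutoff Developability threshold, cP.
#' @return Object of class `"ab_evaluation"`: list with counts
#'   (`n`, `n_flagged`, `n_experimentally_viscous`, `n_missed_viscous`,
#'   `n_false_positive`, `n_false_negative`, `n_true`), the flagged and
#'   missed id vectors, and `labels` (per-row table with both naming
#'   conventions).
#' @export
evaluate_cohort <- function(predictions, cutoff = 20) {
  predictions <- as.data.frame(predictions)
  need <- c("molecule_id", "pred_acsins", "pred_dls", "experimental")
  if (!all(need %in% names(predictions))) {
    stop("'predictions' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(predictions) == 0) {
    return(structure(list(n = 0L, n_flagged = 0L,
                          n_experimentally_viscous = 0L,
                          n_missed_viscous = 0L, n_false_positive = 0L,
                          n_false_negative = 0L, n_true = 0L,
                          flagged_ids = character(),
                          missed_ids = character(),
                          labels = data.frame(), cutoff = cutoff),
                     class = "ab_evaluation"))
  }
  p <- predictions
  high <- function(v) !is.na(v) & v > cutoff
  flagged <- high(p$pred_acsins) | high(p$pred_dls)
  viscous <- high(p$experimental)
  lab <- performance_label(p$pred_acsins, p$pred_dls, p$experimental, cutoff)
  labels <- data.frame(molecule_id = p$molecule_id,
                       pred_acsins = p$pred_acsins, pred_dls = p$pred_dls,
                       experimental = p$experimental,
                       flagged = flagged, experimentally_viscous = viscous,
                       performance = lab, standard = standard_label(lab))
  structure(list(
    n = nrow(p),
    n_flagged = sum(flagged),
    n_experimentally_viscous = sum(viscous),
    n_missed_viscous = sum(viscous & !flagged),
    n_false_positive = sum(lab == "False positive", na.rm = TRUE),
    n_false_negative = sum(lab == "False negative", na.rm = TRUE),
    n_true = sum(lab == "TRUE", na.rm = TRUE),
    flagged_ids = p$molecule_id[flagged],
    missed_ids = p$molecule_id[viscous & !flagged],
    labels = labels, cutoff = cutoff
  ), class = "ab_evaluation")
}

#' @export
print.ab_evaluation <- function(x, ...) {
  cat(sprintf("Screening evaluation (%d molecules, cutoff %g cP)\n",
              x$n, x$cutoff))
  cat(sprintf("  flagged by the screen      : %d\n", x$n_flagged))
  cat(sprintf("  experimentally viscous     : %d\n",
              x$n_experimentally_viscous))
  cat(sprintf("  viscous but missed         : %d\n", x$n_missed_viscous))
  cat(sprintf("  labels: TRUE %d | False positive %d | False negative %d\n",
              x$n_true, x$n_false_positive, x$n_false_negative))
  invisible(x)
}
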