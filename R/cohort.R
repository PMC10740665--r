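#' A cohort of antibody molecules with dilute measurements and viscosity profiles
#'
#' Container holding two linked tables:
#' \describe{
#'   \item{`molecules`}{one row per molecule: `molecule_id`,
#'     `dnp_um2_per_s` (AC-SINS nanoparticle diffusion), `kd_ml_per_g`
#'     (DLS interaction parameter), `plasmon_shift_nm` (carried but not
#'     modeled), `split` (train/validation/test label or `NA`).}
#'   \item{`viscosity`}{long format, one row per measured point:
#'     `molecule_id`, `conc_mg_ml`, `visc_cP`.}
#' }
#' Units are encoded in the column names to keep mL/g (kD) and mL/mg (K)
#' from being silently confused. Missing measurements are `NA`, never
#' zero-filled.
#'
#' @param molecules Data frame with at least a `molecule_id` column; other
#'   recognized columns are filled with `NA` if absent.
#' @param viscosity Data frame with columns `molecule_id`, `conc_mg_ml`,
#'   `visc_cP`; may be empty.
#' @return Object of class `"ab_cohort"`.
#' @export
ab_cohort <- function(molecules, viscosity = NULL) {
  molecules <- as.data.frame(molecules)
  if (!"molecule_id" %in% names(molecules)) {
    stop("'molecules' must have a 'molecule_id' column", call. = FALSE)
  }
  molecules$molecule_id <- as.character(molecules$molecule_id)
  dup <- molecules$molecule_id[duplicated(molecules$molecule_id)]
  if (length(dup)) {
    stop("duplicate molecule_id in cohort: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (col in c("dnp_um2_per_s", "kd_ml_per_g", "plasmon_shift_nm")) {
    if (!col %in% names(molecules)) {
      molecules[[col]] <- rep(NA_real_, nrow(molecules))
    }
    molecules[[col]] <- as.numeric(molecules[[col]])
  }
  if (!"split" %in% names(molecules)) {
    molecules$split <- rep(NA_character_, nrow(molecules))
  }
  molecules$split <- as.character(molecules$split)

  if (is.null(viscosity)) {
    viscosity <- data.frame(molecule_id = character(),
                            conc_mg_ml = numeric(), visc_cP = numeric())
  }
  viscosity <- as.data.frame(viscosity)
  need <- c("molecule_id", "conc_mg_ml", "visc_cP")
  if (!all(need %in% names(viscosity))) {
    stop("'viscosity' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  viscosity$molecule_id <- as.character(viscosity$molecule_id)
  viscosity$conc_mg_ml <- as.numeric(viscosity$conc_mg_ml)
  viscosity$visc_cP <- as.numeric(viscosity$visc_cP)
  orphan <- setdiff(viscosity$molecule_id, molecules$molecule_id)
  if (length(orphan)) {
    stop("viscosity table references unknown molecule_id: ",
         paste(unique(orphan), collapse = ", "), call. = FALSE)
  }
  bad_c <- viscosity$conc_mg_ml[!is.na(viscosity$conc_mg_ml) &
                                  viscosity$conc_mg_ml <= 0]
  if (length(bad_c)) {
    stop("viscosity table contains non-positive concentrations", call. = FALSE)
  }
  structure(list(molecules = molecules[need_cols_order(molecules)],
                 viscosity = viscosity[, need, drop = FALSE]),
            class = "ab_cohort")
}

need_cols_order <- function(molecules) {
  first <- c("molecule_id", "dnp_um2_per_s", "kd_ml_per_g",
             "plasmon_shift_nm", "split")
  c(first, setdiff(names(molecules), first))
}

#' @export
print.ab_cohort <- function(x, ...) {
  n <- nrow(x$molecules)
  cat(sprintf("ab_cohort: %d molecule(s), %d viscosity point(s)\n",
              n, nrow(x$viscosity)))
  if (n) {
    cat(sprintf("  D_np present: %d, k_D present: %d\n",
                sum(!is.na(x$molecules$dnp_um2_per_s)),
                sum(!is.na(x$molecules$kd_ml_per_g))))
    sp <- table(x$molecules$split, useNA = "no")
    if (length(sp)) {
      cat("  split:", paste(sprintf("%s=%d", names(sp), sp), collapse = " "),
          "\n")
    }
  }
  invisible(x)
}

#' @export
length.ab_cohort <- function(x) nrow(x$molecules)

#' Viscosity profile of one molecule
#'
#' @param cohort An [ab_cohort()].
#' @param molecule_id Molecule identifier.
#' @return Data frame with `conc_mg_ml` and `visc_cP` columns (possibly
#'   zero rows).
#' @export
molecule_profile <- function(cohort, molecule_id) {
  stopifnot(inherits(cohort, "ab_cohort"))
  v <- cohort$viscosity
  v[v$molecule_id == molecule_id, c("conc_mg_ml", "visc_cP"), drop = FALSE]
}

#' Exclusion thresholds for calibration and prediction
#'
#' The screening workflow excludes measurements outside the regime where
#' the reptation model and the dilute assays are reliable:
#' \describe{
#'   \item{`dnp_min`}{AC-SINS sensitivity floor, um^2/s. The correlation
#'     between nanoparticle diffusion and viscosity breaks down below
#'     1 um^2/s because large nanoparticle clusters grow sub-linearly in
#'     Stokes radius.}
#'   \item{`kd_abs_max`}{plausibility bound on |kD|, mL/g. Values far
#'     outside the range expected for antibodies indicate experimental
#'     error.}
#'   \item{`k_branching_max`}{mL/mg; above it, branched head-to-tail
#'     complexes are likely and the linear-chain reptation law is not
#'     trusted.}
#'   \item{`ht_separator`}{optional line in (kD, D_np) space separating
#'     suspected head-to-tail binders; see [detect_ht_outliers()]. `NULL`
#'     disables head-to-tail exclusion.}
#'   \item{`entanglement_floor`}{mg/mL; viscosity points below it are too
#'     dilute for entangled dynamics.}
#' }
#'
#' @param dnp_min AC-SINS diffusion sensitivity floor, um^2/s.
#' @param kd_abs_max Maximum plausible |kD|, mL/g.
#' @param k_branching_max Branching cutoff on K, mL/mg.
#' @param ht_separator `NULL`, or a numeric vector/list with elements
#'   `slope` and `intercept` describing the line
#'   `D_np = intercept + slope * kD`.
#' @param entanglement_floor Minimum concentration for reptation, mg/mL.
#' @return Object of class `"exclusion_config"`.
#' @export
exclusion_config <- function(dnp_min = 1.0, kd_abs_max = 60,
                             k_branching_max = 0.01, ht_separator = NULL,
                             entanglement_floor = 100) {
  vals <- c(dnp_min = dnp_min, kd_abs_max = kd_abs_max,
            k_branching_max = k_branching_max,
            entanglement_floor = entanglement_floor)
  if (!all(is.finite(vals))) {
    stop("exclusion thresholds must all be finite", call. = FALSE)
  }
  if (!is.null(ht_separator)) {
    ht_separator <- as.list(ht_separator)
    if (!all(c("slope", "intercept") %in% names(ht_separator))) {
      stop("'ht_separator' needs named elements 'slope' and 'intercept'",
           call. = FALSE)
    }
    ht_separator <- list(slope = as.numeric(ht_separator$slope),
                         intercept = as.numeric(ht_separator$intercept))
    if (!all(vapply(ht_separator, is.finite, logical(1)))) {
      stop("'ht_separator' coefficients must be finite", call. = FALSE)
    }
  }
  structure(list(dnp_min = dnp_min, kd_abs_max = kd_abs_max,
                 k_branching_max = k_branching_max,
                 ht_separator = ht_separator,
                 entanglement_floor = entanglement_floor),
            class = "exclusion_config")
}

#' @export
print.exclusion_config <- function(x, ...) {
  cat("Exclusion thresholds\n")
  cat(sprintf("  D_np sensitivity floor : %g um^2/s\n", x$dnp_min))
  cat(sprintf("  |kD| plausibility max  : %g mL/g\n", x$kd_abs_max))
  cat(sprintf("  K branching cutoff     : %g mL/mg\n", x$k_branching_max))
  cat(sprintf("  entanglement floor     : %g mg/mL\n", x$entanglement_floor))
  if (is.null(x$ht_separator)) {
    cat("  HT separator           : unset (no head-to-tail exclusions)\n")
  } else {
    cat(sprintf("  HT separator           : D_np > %g %+g * kD\n",
                x$ht_separator$intercept, x$ht_separator$slope))
  }
  invisible(x)
}
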