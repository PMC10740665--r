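#' Configuration for the synthetic cohort generator
#'
#' Describes a simulated antibody development cohort with the statistical
#' structure the screening method assumes: a true dimerization constant K
#' per molecule drawn log-uniformly, dilute readouts placed on the
#' calibration lines with Gaussian measurement noise, viscosity profiles
#' from the reptation law with multiplicative lognormal noise, plus two
#' kinds of injected outliers:
#' \describe{
#'   \item{head-to-tail binders}{the nanoparticle tether sterically hides
#'     the head-to-tail site, so D_np reports the weak head-to-head K
#'     while kD and the viscosity profile follow a `ht_K_multiplier`-fold
#'     stronger effective K;}
#'   \item{strong binders}{molecules whose association is strong enough to
#'     push D_np below the 1 um^2/s sensitivity floor of AC-SINS.}
#' }
#'
#' Defaults mirror the conditions of the cohort the calibration was built
#' for: viscosity measured near 70 and 150 mg/mL, measurement noise of
#' 0.3 um^2/s on D_np and 3 mL/g on kD, 5% lognormal noise on viscosity,
#' and K spanning 1e-5 to 1e-2 mL/mg.
#'
#' @param n_molecules Number of molecules.
#' @param seed Integer seed (required; the generator is fully deterministic
#'   given the config).
#' @param K_log10_range Range of log10(K / (mL/mg)) for the log-uniform
#'   draw.
#' @param dnp_noise_sd Gaussian noise sd on D_np, um^2/s.
#' @param kd_noise_sd Gaussian noise sd on kD, mL/g.
#' @param visc_lognoise_sd Lognormal sd on viscosity (sd of log eta),
#'   dimensionless.
#' @param concentrations Viscosity measurement concentrations, mg/mL.
#' @param ht_fraction Fraction of molecules that are head-to-tail binders.
#' @param ht_K_multiplier Factor (> 1) by which the effective K of a
#'   head-to-tail binder exceeds what AC-SINS reports.
#' @param strong_binder_fraction Fraction of molecules below the AC-SINS
#'   sensitivity floor.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_molecules, seed,
                             K_log10_range = c(-5, -2),
                             dnp_noise_sd = 0.3, kd_noise_sd = 3,
                             visc_lognoise_sd = 0.05,
                             concentrations = c(70, 150),
                             ht_fraction = 0, ht_K_multiplier = 5,
                             strong_binder_fraction = 0) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required: synthetic cohorts must be reproducible",
         call. = FALSE)
  }
  if (n_molecules < 1) stop("'n_molecules' must be >= 1", call. = FALSE)
  if (length(K_log10_range) != 2 || diff(K_log10_range) < 0) {
    stop("'K_log10_range' must be an ordered [min, max] pair", call. = FALSE)
  }
  fr <- c(ht_fraction, strong_binder_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("outlier fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  if (ht_K_multiplier <= 1) {
    stop("'ht_K_multiplier' must exceed 1", call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("'concentrations' must be positive", call. = FALSE)
  }
  if (any(c(dnp_noise_sd, kd_noise_sd, visc_lognoise_sd) < 0)) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  structure(list(
    n_molecules = as.integer(n_molecules), seed = as.integer(seed),
    K_log10_range = as.numeric(K_log10_range),
    dnp_noise_sd = dnp_noise_sd, kd_noise_sd = kd_noise_sd,
    visc_lognoise_sd = visc_lognoise_sd,
    concentrations = as.numeric(concentrations),
    ht_fraction = ht_fraction, ht_K_multiplier = ht_K_multiplier,
    strong_binder_fraction = strong_binder_fraction
  ), class = "synthetic_config")
}

#' Generate a synthetic antibody cohort with known ground truth
#'
#' Draws a cohort according to a [synthetic_config()]:
#' \enumerate{
#'   \item true K per molecule, log-uniform over `K_log10_range`;
#'   \item strong binders get K resampled so their noise-free D_np falls
#'     below the 1 um^2/s sensitivity floor;
#'   \item D_np = AC-SINS line at the head-to-head K plus Gaussian noise
#'     (floored at 0.01 um^2/s — diffusion cannot be negative);
#'   \item kD = DLS line at the effective K plus Gaussian noise;
#'   \item viscosity at each configured concentration from the reptation
#'     law at the effective K times lognormal noise.
#' }
#' For head-to-tail binders the effective K (driving kD and viscosity) is
#' `ht_K_multiplier` times the head-to-head K that D_np reports.
#'
#' The ground truth is returned as a separate table so pipeline tests
#' cannot accidentally leak it into the fitted quantities.
#'
#' @param config A [synthetic_config()].
#' @param params A [model_params()] object.
#' @param lines Calibration lines used as the generating model (defaults
#'   to the published [reference_lines()]).
#' @return List with `cohort` (an [ab_cohort()]) and `truth` (data frame:
#'   `molecule_id`, `K_true`, `K_effective`, `is_ht`, `is_strong_binder`,
#'   `dnp_true`, `kd_true`).
#' @export
generate_cohort <- function(config, params = model_params(),
                            lines = reference_lines()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_molecules
  ids <- sprintf("S%03d", seq_len(n))

  K <- 10^stats::runif(n, config$K_log10_range[1], config$K_log10_range[2])

  n_ht <- round(config$ht_fraction * n)
  n_sb <- round(config$strong_binder_fraction * n)
  special <- sample.int(n, n_ht + n_sb)
  ht_idx <- special[seq_len(n_ht)]
  sb_idx <- special[n_ht + seq_len(n_sb)]

  # strong binders: noise-free D_np uniform in (0.1, 0.9) um^2/s, below the
  # sensitivity floor; K follows from the AC-SINS line
  if (n_sb > 0) {
    dnp_target <- stats::runif(n_sb, 0.1, 0.9)
    K[sb_idx] <- (lines$acsins$intercept - dnp_target) / lines$acsins$slope
  }

  K_eff <- K
  K_eff[ht_idx] <- K[ht_idx] * config$ht_K_multiplier

  dnp_true <- lines$acsins$intercept - lines$acsins$slope * K
  kd_true <- lines$dls$intercept - lines$dls$slope * K_eff
  dnp <- dnp_true + stats::rnorm(n, 0, config$dnp_noise_sd)
  dnp <- pmax(dnp, 0.01)
  kd <- kd_true + stats::rnorm(n, 0, config$kd_noise_sd)

  concs <- config$concentrations
  visc <- do.call(rbind, lapply(seq_len(n), function(i) {
    eta <- viscosity(K_eff[i], concs, params) *
      exp(stats::rnorm(length(concs), 0, config$visc_lognoise_sd))
    data.frame(molecule_id = ids[i], conc_mg_ml = concs, visc_cP = eta)
  }))

  molecules <- data.frame(
    molecule_id = ids, dnp_um2_per_s = dnp, kd_ml_per_g = kd,
    plasmon_shift_nm = NA_real_, split = NA_character_
  )
  truth <- data.frame(
    molecule_id = ids, K_true = K, K_effective = K_eff,
    is_ht = seq_len(n) %in% ht_idx,
    is_strong_binder = seq_len(n) %in% sb_idx,
    dnp_true = dnp_true, kd_true = kd_true
  )
  list(cohort = ab_cohort(molecules, visc), truth = truth)
}
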