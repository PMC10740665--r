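#' Physical constants of the reptation viscosity law
#'
#' Bundles the two constants of the entanglement model of antibody solution
#' viscosity: the proportionality constant `A` and the Flory exponent `nu`.
#' The concentration exponent of the viscosity law,
#' \eqn{3/(3\nu - 1)}, is derived at construction time; with the default
#' \eqn{\nu = 3/5} it equals 3.75 exactly.
#'
#' `A` describes lateral ("slithering") interactions between entangled,
#' elongated antibody complexes. It is expected to be constant within an
#' antibody scaffold but can shift with hinge flexibility or solution
#' conditions; the default value 5.4e-8 applies to standard IgG scaffolds.
#'
#' @param A Viscosity prefactor, cP (mg/mL)^-3.75 at the default `nu`.
#'   Must be positive.
#' @param nu Flory exponent describing the effective volume of a flexible
#'   chain. Must satisfy 1/3 < nu <= 1 so the derived concentration exponent
#'   is finite and positive.
#' @return An object of class `"model_params"` with elements `A`, `nu` and
#'   `exponent`.
#' @examples
#' p <- model_params()
#' p$exponent # 3.75
#' @export
model_params <- function(A = 5.4e-8, nu = 3 / 5) {
  if (!is.numeric(A) || length(A) != 1 || !is.finite(A) || A <= 0) {
    stop("'A' must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(nu) || length(nu) != 1 || !is.finite(nu) ||
      nu <= 1 / 3 || nu > 1) {
    stop("'nu' must satisfy 1/3 < nu <= 1 (the concentration exponent ",
         "3/(3*nu - 1) diverges at nu = 1/3)", call. = FALSE)
  }
  # 3/(3*nu - 1) written as 1/(nu - 1/3): same quantity, and exact in
  # floating point at the default nu = 3/5 (exponent 3.75)
  structure(
    list(A = A, nu = nu, exponent = 1 / (nu - 1 / 3)),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Reptation viscosity law parameters\n")
  cat(sprintf("  A        = %g cP (mg/mL)^-%g\n", x$A, x$exponent))
  cat(sprintf("  nu       = %g (Flory exponent)\n", x$nu))
  cat(sprintf("  exponent = %g (concentration power 3/(3*nu - 1))\n",
              x$exponent))
  invisible(x)
}

check_kc_domain <- function(K, C) {
  if (any(C < 0, na.rm = TRUE)) {
    stop("concentration 'C' must be non-negative", call. = FALSE)
  }
  kc <- K * C
  if (any(kc <= -0.25, na.rm = TRUE)) {
    stop("K*C <= -1/4: mean chain length undefined (square root of a ",
         "negative number); input is non-physical", call. = FALSE)
  }
  kc
}

#' Mean chain length of an isodesmic head-to-head assembly
#'
#' Number-average size (in monomers) of the linear chains formed by
#' head-to-head (CDR-CDR) association with a single stepwise equilibrium
#' constant `K`:
#' \deqn{\langle L \rangle = \frac{2KC}{\sqrt{1+4KC} - 1}
#'       = \frac{1 + \sqrt{1+4KC}}{2},}
#' the two forms being algebraically identical. The second is used because
#' it is numerically stable as \eqn{KC \to 0}, where
#' \eqn{\langle L \rangle \to 1} (all monomer). For \eqn{KC \to \infty},
#' \eqn{\langle L \rangle \sim \sqrt{KC}}.
#'
#' Negative `K` is admitted (down to `K*C > -1/4`) for diagnostic use:
#' viscosity profiles that fall below the monomer baseline invert to a
#' formally negative `K`, signalling non-entangled dynamics.
#'
#' @param K Association equilibrium constant, mL/mg. `K = C2/C1^2` with `C1`,
#'   `C2` the monomer and dimer mass concentrations.
#' @param C Total antibody concentration, mg/mL. Non-negative.
#' @return Mean assembly size, dimensionless (>= 1 for `K >= 0`).
#'   Vectorized over `K` and `C`.
#' @seealso [chain_length_mass_balance()] for the independent mass-balance
#'   solver used to verify this closed form.
#' @examples
#' mean_chain_length(0, 150)   # 1: monomer limit
#' mean_chain_length(1, 2)     # 2
#' @export
mean_chain_length <- function(K, C) {
  kc <- check_kc_domain(K, C)
  (1 + sqrt(1 + 4 * kc)) / 2
}

#' Mean chain length via the isodesmic mass balance (verification oracle)
#'
#' Independent route to the mean assembly size: solves the isodesmic mass
#' balance \eqn{C = C_1/(1-KC_1)^2} numerically for the free monomer
#' concentration \eqn{C_1 \in (0, 1/K)} by bisection, then returns
#' \eqn{\langle L \rangle = 1/(1-KC_1)}. Exists so the closed form in
#' [mean_chain_length()] can be checked against the defining equilibrium
#' rather than against itself.
#'
#' @param K Association constant, mL/mg. Strictly positive.
#' @param C Total concentration, mg/mL. Strictly positive.
#' @param tol Absolute bisection tolerance on the scaled monomer fraction;
#'   the default drives the bracket to machine precision.
#' @return Mean assembly size, dimensionless.
#' @export
chain_length_mass_balance <- function(K, C, tol = 1e-15) {
  if (length(K) != 1 || length(C) != 1) {
    stop("'K' and 'C' must be scalars", call. = FALSE)
  }
  if (!is.finite(K) || !is.finite(C) || K <= 0 || C <= 0) {
    stop("mass-balance oracle requires K > 0 and C > 0", call. = FALSE)
  }
  # bisect on v = 1 - K*C1 in (0, 1]; mass balance reads (1 - v)/v^2 = K*C,
  # monotone decreasing in v, so f(v) = (1 - v) - K*C*v^2 brackets the root
  f <- function(v) (1 - v) - K * C * v * v
  lo <- .Machine$double.xmin
  hi <- 1
  if (f(hi) > 0) stop("mass balance has no root in (0, 1]", call. = FALSE)
  iter <- 0
  while (hi - lo > tol * max(1, lo) && iter < 2000) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    iter <- iter + 1
  }
  if (iter >= 2000) {
    stop(sprintf(
      "mass-balance bisection did not converge (K=%g, C=%g, bracket=[%g,%g])",
      K, C, lo, hi), call. = FALSE)
  }
  2 / (lo + hi)
}

#' Reptation-model solution viscosity
#'
#' Viscosity of an entangled solution of linear antibody chains:
#' \deqn{\eta = A\, C^{3/(3\nu-1)}\, \langle L \rangle^3,}
#' with \eqn{\langle L \rangle} the isodesmic mean chain length. For
#' `K = 0` this reduces to the monomer baseline \eqn{A C^{3.75}} (at the
#' default `nu`); the law is strictly increasing in both `C` and `K`.
#'
#' Valid in the entangled regime (roughly `C` >= 100 mg/mL); below that,
#' solutions are too dilute for reptation and the law over- or
#' under-represents the true viscosity.
#'
#' @inheritParams mean_chain_length
#' @param params A [model_params()] object.
#' @return Viscosity in cP, vectorized over `K` and `C`.
#' @examples
#' viscosity(0, 150)        # monomer baseline, about 7.81 cP
#' viscosity(7.34e-4, 150)  # about 10.4 cP
#' @export
viscosity <- function(K, C, params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  L <- mean_chain_length(K, C)
  params$A * C^params$exponent * L^3
}

#' A dimerization-constant estimate with provenance and applicability flags
#'
#' Light container pairing a `K` value (mL/mg) with where it came from and
#' any applicability caveats raised along the way.
#'
#' Flags used across the package:
#' \describe{
#'   \item{`non_entangled`}{fitted `K <= 0`; the viscosity lies at or below
#'     the monomer baseline, so entangled reptation dynamics do not apply.}
#'   \item{`clamped_to_zero`}{a negative raw `K` from a calibration line was
#'     clamped to 0 for prediction; the raw value is kept in `raw`.}
#'   \item{`above_branching_cutoff`}{`K` > 0.01 mL/mg, where branched
#'     (head-to-tail) complexes are likely and the linear-chain law is
#'     unreliable.}
#'   \item{`low_sensitivity_dnp`}{the AC-SINS diffusion readout was below
#'     1 um^2/s, where its correlation with viscosity breaks down.}
#'   \item{`missing_measurement`}{no measurement was available; `value` is
#'     `NA`.}
#' }
#'
#' @param value Estimated K, mL/mg (signed; may be `NA`).
#' @param source One of `"acsins"`, `"dls"`, `"profile_fit"`.
#' @param flags Character vector of applicability flags.
#' @param raw Raw (unclamped) K, mL/mg.
#' @param details Optional list of fit diagnostics.
#' @return Object of class `"k_estimate"`.
#' @export
k_estimate <- function(value, source = "profile_fit", flags = character(),
                       raw = value, details = list()) {
  source <- match.arg(source, c("acsins", "dls", "profile_fit"))
  structure(
    list(value = value, source = source, flags = unique(flags),
         raw = raw, details = details),
    class = "k_estimate"
  )
}

#' @export
print.k_estimate <- function(x, ...) {
  cat(sprintf("K estimate: %s mL/mg  [source: %s]\n",
              format(x$value, digits = 6), x$source))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  if (!identical(x$raw, x$value)) {
    cat(sprintf("  raw (unclamped): %s\n", format(x$raw, digits = 6)))
  }
  invisible(x)
}

has_flag <- function(x, flag) flag %in% x$flags

#' Invert the viscosity law for the dimerization constant
#'
#' Closed-form inversion of the reptation law at a single concentration:
#' \eqn{L = (\eta/(A C^{3.75}))^{1/3}} and, from the isodesmic chain
#' statistics, \eqn{K = (L^2 - L)/C}. A viscosity at or below the monomer
#' baseline gives `K <= 0`, which is preserved (not clamped) and flagged
#' `non_entangled`: such molecules are not experiencing entangled dynamics
#' and the reptation law does not apply to them.
#'
#' @param eta Measured (or predicted) viscosity, cP. Positive.
#' @param C Concentration at which `eta` applies, mg/mL. Positive.
#' @param params A [model_params()] object.
#' @return A [k_estimate()] with source `"profile_fit"`.
#' @examples
#' k_from_viscosity(10.4, 150)$value # about 7.34e-4 mL/mg
#' @export
k_from_viscosity <- function(eta, C, params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  if (length(eta) != 1 || length(C) != 1) {
    stop("'eta' and 'C' must be scalars; see fit_k_profile() for profiles",
         call. = FALSE)
  }
  if (!is.finite(eta) || eta <= 0) stop("'eta' must be positive", call. = FALSE)
  if (!is.finite(C) || C <= 0) stop("'C' must be positive", call. = FALSE)
  L <- (eta / (params$A * C^params$exponent))^(1 / 3)
  if (L <= 0.5) {
    stop(sprintf(
      "inversion impossible: implied chain length %.4g <= 1/2 (viscosity %g cP at %g mg/mL is below the invertible range)",
      L, eta, C), call. = FALSE)
  }
  K <- (L * L - L) / C
  flags <- if (K <= 0) "non_entangled" else character()
  k_estimate(K, source = "profile_fit", flags = flags,
             details = list(L = L, eta = eta, C = C))
}

#' Fit the dimerization constant to a concentration-viscosity profile
#'
#' Single-parameter fit of the reptation law to measured (concentration,
#' viscosity) pairs. Points below the entanglement floor (default
#' 100 mg/mL) are excluded with a warning: below it, solutions are too
#' dilute to exhibit entangled dynamics and obey a different power regime.
#' One usable point delegates to the exact inversion
#' [k_from_viscosity()]; two or more minimize the sum of squared
#' log-viscosity residuals (log residuals weight the order-of-magnitude
#' span of viscosity evenly across concentrations), solved by root-finding
#' on the analytic gradient.
#'
#' @param profile Data frame with numeric columns `conc_mg_ml` and
#'   `visc_cP`, or a two-column matrix in that order.
#' @param params A [model_params()] object.
#' @param entanglement_floor Minimum concentration (mg/mL) for a point to
#'   enter the fit.
#' @return A [k_estimate()] with source `"profile_fit"`; `details` holds the
#'   log residuals, the points used and the points excluded.
#' @export
fit_k_profile <- function(profile, params = model_params(),
                          entanglement_floor = 100) {
  stopifnot(inherits(params, "model_params"))
  profile <- as.data.frame(profile)
  if (ncol(profile) >= 2 &&
      !all(c("conc_mg_ml", "visc_cP") %in% names(profile))) {
    names(profile)[1:2] <- c("conc_mg_ml", "visc_cP")
  }
  C <- as.numeric(profile$conc_mg_ml)
  eta <- as.numeric(profile$visc_cP)
  keep <- is.finite(C) & is.finite(eta) & C > 0 & eta > 0
  C <- C[keep]; eta <- eta[keep]
  if (length(C) == 0) {
    stop("profile has no usable (C > 0, eta > 0) points", call. = FALSE)
  }
  above <- C >= entanglement_floor
  if (any(!above)) {
    warning(sprintf(
      "excluding %d profile point(s) below the %g mg/mL entanglement floor (too dilute for entangled dynamics)",
      sum(!above), entanglement_floor), call. = FALSE)
  }
  if (!any(above)) {
    stop(sprintf(
      "all profile points lie below the %g mg/mL entanglement floor; the reptation law is not applicable",
      entanglement_floor), call. = FALSE)
  }
  C <- C[above]; eta <- eta[above]
  excluded <- data.frame(conc_mg_ml = profile$conc_mg_ml[keep][!above],
                         visc_cP = profile$visc_cP[keep][!above])

  if (length(C) == 1) {
    est <- k_from_viscosity(eta, C, params)
    est$details$n_used <- 1L
    est$details$excluded_below_floor <- excluded
    return(est)
  }

  # per-point exact inversions seed the bracket for the joint fit
  k_pts <- vapply(seq_along(C), function(i) {
    k_from_viscosity(eta[i], C[i], params)$value
  }, numeric(1))

  # gradient of 0.5 * sum(log eta_model - log eta_obs)^2 wrt K;
  # monotone increasing in K, so its root is the unique minimizer
  grad <- function(K) {
    L <- mean_chain_length(K, C)
    r <- log(params$A) + params$exponent * log(C) + 3 * log(L) - log(eta)
    sum(r * 3 * C / (sqrt(1 + 4 * K * C) * L))
  }
  k_min_domain <- -0.2499 / max(C)
  lo <- max(min(k_pts) - max(1e-8, diff(range(k_pts))), k_min_domain)
  hi <- max(k_pts) + max(1e-8, diff(range(k_pts)))
  g_lo <- grad(lo); g_hi <- grad(hi)
  # widen upward if needed (gradient is increasing in K)
  tries <- 0
  while (g_hi < 0 && tries < 60) { hi <- hi * 2 + 1e-6; g_hi <- grad(hi); tries <- tries + 1 }
  while (g_lo > 0 && lo > k_min_domain + 1e-12 && tries < 120) {
    lo <- max(k_min_domain, lo - (hi - lo)); g_lo <- grad(lo); tries <- tries + 1
  }
  if (g_lo > 0 || g_hi < 0) {
    stop("profile fit did not converge: could not bracket the optimum",
         call. = FALSE)
  }
  K <- stats::uniroot(grad, c(lo, hi), f.lower = g_lo, f.upper = g_hi,
                      tol = .Machine$double.eps)$root
  resid <- log(viscosity(K, C, params)) - log(eta)
  flags <- if (K <= 0) "non_entangled" else character()
  k_estimate(K, source = "profile_fit", flags = flags,
             details = list(log_residuals = resid, n_used = length(C),
                            conc_mg_ml = C, visc_cP = eta,
                            excluded_below_floor = excluded))
}
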