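#' Dimensionless compartment parameter of the crowding model
#'
#' The reduction of the free diffusion constant by periodic barriers is
#' governed by a single dimensionless combination of the geometry,
#' \deqn{\kappa = \frac{2 \epsilon L}{S + 2 \epsilon L},}
#' built from the opening radius, the compartment length and the
#' cross-sectional area `S = pi a^2`. It equals the ratio
#' `D_eff / D`, lies strictly below 1, and is invariant under
#' rescalings `(eps, L) -> (eps/c, cL)` that preserve the product
#' `eps * L`.
#'
#' The form follows from the series-resistance picture of transport
#' through one spatial period: the diffusive conductance of a narrow
#' aperture between two compartments is `g = 2 eps D` (the one-sided
#' absorbing escape rate through a disk hole is `4 eps D / V`, the
#' inverse of [mfpt_escape_3d()], and net transport sees that access
#' resistance on both sides of the opening), and it acts in series
#' with the bulk resistance `L / (S D)` of the compartment itself.
#' Per period, `1 / D_eff = (1/g + L/(S D)) V / L^2`, i.e.
#' `D_eff = D * 2 eps L / (S + 2 eps L)`. The bulk term contributes a
#' relative `2 eps L / S` (about 5% at the 1/20 calibration) and makes
#' the calibrated geometry reproduce the measured slowdown in 3D
#' Brownian simulation (see [estimate_apparent_D()]); dropping it
#' recovers the leading-order small-hole result `2 eps L / S`.
#'
#' @param spec A [compartment_spec()].
#' @return The dimensionless compartment parameter (in (0, 1) for any
#'   geometry within the small-hole regime).
#' @examples
#' spec <- calibrate_geometry(0.05, a = 0.5)
#' compartment_parameter(spec) # 0.05
#' @export
compartment_parameter <- function(spec) {
  stopifnot(inherits(spec, "compartment_spec"))
  epsL2 <- 2 * spec$eps * spec$L
  epsL2 / (spec$S + epsL2)
}

#' Effective 1D diffusion constant of the compartmentalized dendrite
#'
#' Long-time apparent diffusion constant of the reduced 1D description:
#' `D_eff = kappa * D` with `kappa` the [compartment_parameter()]. The
#' derivation balances the net inter-compartment fluxes through the
#' series of aperture conductance `g = 2 eps D` and compartment bulk
#' conductance `S D / L`, giving a hopping rate over the lattice
#' spacing `L` and hence `D_eff = D * 2 eps L / (S + 2 eps L)`.
#'
#' @param spec A [compartment_spec()].
#' @return Effective diffusion constant in um^2/s, strictly below `spec$D`.
#' @export
effective_diffusion_constant <- function(spec) {
  stopifnot(inherits(spec, "compartment_spec"))
  compartment_parameter(spec) * spec$D
}

#' Calibrate the barrier geometry to a target diffusion reduction
#'
#' Measurements fix only the ratio `D_eff / D` (the compartment
#' parameter); the model has one spare degree of freedom that is pinned
#' by a calibration condition on the aspect ratio `eps / L`. The default
#' `calibration_ratio = 0.025` keeps the small-hole approximation
#' accurate: the calibration fixes the product `eps * L`, and the
#' first-order escape-time formula is accurate only while the opening
#' is small relative to the dendrite radius (brute-force Brownian
#' escape times put the formula's relative error at ~9% for
#' `eps/L = 0.1`, ~6% at 0.05 and ~3% at 0.025 for the 1/20 geometry;
#' the validity requirement is ~<= 5%). Given a target compartment
#' parameter `kappa` this solves `2 eps L = S kappa / (1 - kappa)` with
#' `eps / L = calibration_ratio`.
#'
#' @param target_ratio Desired `D_eff / D`, strictly in (0, 1).
#' @param a Dendrite radius, um.
#' @param calibration_ratio Aspect ratio `eps / L` (default 0.025).
#' @param D Free diffusion constant, um^2/s (default 400, fluorescein in
#'   aqueous solution).
#' @param validity_bound Passed to [compartment_spec()].
#' @return A calibrated [compartment_spec()] whose
#'   [compartment_parameter()] equals `target_ratio` to machine precision.
#' @examples
#' spec <- calibrate_geometry(0.05, a = 0.5)
#' effective_diffusion_constant(spec) / spec$D # 0.05, i.e. a 20x slowdown
#' @export
calibrate_geometry <- function(target_ratio, a, calibration_ratio = 0.025,
                               D = 400, validity_bound = 0.15) {
  if (!is.numeric(target_ratio) || target_ratio <= 0 || target_ratio >= 1)
    stop("target_ratio must lie strictly between 0 and 1", call. = FALSE)
  if (calibration_ratio <= 0 || calibration_ratio > validity_bound)
    stop("calibration_ratio must be positive and within the small-hole validity bound",
         call. = FALSE)
  S <- pi * a^2
  eps_L <- target_ratio / (1 - target_ratio) * S / 2   # product eps * L
  eps <- sqrt(eps_L * calibration_ratio)
  L <- eps / calibration_ratio
  if (eps >= a)
    stop(sprintf(
      "calibration infeasible: required opening radius %.3g um is not smaller than the dendrite radius %.3g um",
      eps, a), call. = FALSE)
  compartment_spec(L = L, eps = eps, a = a, D = D,
                   validity_bound = validity_bound)
}

#' Drift and diffusion coefficients of the inhomogeneous reduced model
#'
#' When the opening radius and compartment volume vary along the
#' dendrite, the reduced description is a Fokker-Planck equation
#' `dc/dt = d^2(b(x) c)/dx^2` whose associated stochastic equation has a
#' local diffusion coefficient
#' `b(x) = 2 D L eps(x) / (S(x) + 2 L eps(x))` (with `S(x) = V(x)/L`)
#' and drift `a(x) = b'(x)`. The drift vanishes
#' identically for spatially homogeneous opening sizes, and `b`
#' reduces to the effective diffusion constant in the homogeneous limit.
#'
#' @param profile An [inhomogeneous_profile()].
#' @param spec A [compartment_spec()] supplying `L` and `D`.
#' @param stencil_h Finite-difference step for the drift derivative, um.
#' @return A list with functions `a_of_x` (drift, um/s) and `b_of_x`
#'   (diffusion, um^2/s) defined on `[0, profile$L_dend]`.
#' @export
drift_and_diffusion_coefficients <- function(profile, spec,
                                             stencil_h = 1e-4) {
  stopifnot(inherits(profile, "inhomogeneous_profile"),
            inherits(spec, "compartment_spec"))
  b_of_x <- function(x) {
    S_of_x <- profile$V_of_x(x) / spec$L
    epsL2 <- 2 * spec$L * profile$eps_of_x(x)
    spec$D * epsL2 / (S_of_x + epsL2)
  }
  a_of_x <- function(x) {
    h <- stencil_h
    xl <- pmax(x - h, 0); xr <- pmin(x + h, profile$L_dend)
    db <- (b_of_x(xr) - b_of_x(xl)) / (xr - xl)
    if (any(!is.finite(db)))
      stop("numerical derivative of the diffusion coefficient failed; profile may not be differentiable",
           call. = FALSE)
    db
  }
  list(a_of_x = a_of_x, b_of_x = b_of_x)
}

#' Apparent diffusion constant for jittered (almost periodic) barriers
#'
#' Randomly jittered barrier positions with displacement standard
#' deviation `sigma` increase the apparent diffusion constant relative to
#' the strictly periodic arrangement. Expanding the compartment lengths
#' to second order in the jitter gives
#' \deqn{D_\sigma = D_{eff}\left(1 + \frac{\sigma^2}{L^2}\right),}
#' which recovers the periodic value at `sigma = 0` and grows
#' quadratically for small jitter.
#'
#' @param jitter A [jitter_spec()].
#' @return Apparent diffusion constant in um^2/s, `>=` the periodic
#'   effective value with equality iff `sigma == 0`.
#' @export
jittered_effective_D <- function(jitter) {
  stopifnot(inherits(jitter, "jitter_spec"))
  D_eff <- effective_diffusion_constant(jitter$base)
  D_eff * (1 + (jitter$sigma / jitter$base$L)^2)
}
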