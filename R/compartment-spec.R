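#' Geometry of the periodic barrier model of a crowded dendrite
#'
#' The crowding model divides a cylindrical dendrite of radius `a` into
#' periodic compartments of length `L`, separated by reflecting cross
#' sections pierced by a single small opening of radius `eps`. All
#' reduced-model coefficients derive from this object.
#'
#' The small-hole (narrow-escape) approximation underlying the model is
#' accurate only while the opening is small relative to the compartment;
#' the ratio `eps/L` is checked against a configurable validity bound
#' (default 0.15).
#'
#' @param L Compartment length, um (> 0).
#' @param eps Opening radius, um (> 0, < `a`).
#' @param a Dendrite radius, um (> 0).
#' @param D Free (aqueous) diffusion constant, um^2/s (> 0).
#' @param validity_bound Maximum admissible `eps/L` (default 0.15).
#' @param on_invalid What to do when `eps/L` exceeds the bound:
#'   `"error"` (default) or `"warn"`.
#' @return An object of class `compartment_spec` with fields `L`, `eps`,
#'   `a`, `D` and derived cross-section `S = pi a^2`.
#' @examples
#' spec <- compartment_spec(L = 0.313, eps = 0.0313, a = 0.5, D = 400)
#' compartment_parameter(spec)
#' @export
compartment_spec <- function(L, eps, a, D,
                             validity_bound = 0.15,
                             on_invalid = c("error", "warn")) {
  on_invalid <- match.arg(on_invalid)
  for (nm in c("L", "eps", "a", "D")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  if (eps >= a)
    stop("opening radius 'eps' must be smaller than the dendrite radius 'a'",
         call. = FALSE)
  if (eps / L > validity_bound) {
    msg <- sprintf(
      "eps/L = %.3g exceeds the small-hole validity bound %.3g",
      eps / L, validity_bound)
    if (on_invalid == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(
    list(L = L, eps = eps, a = a, D = D,
         S = pi * a^2, validity_bound = validity_bound),
    class = "compartment_spec")
}

#' @export
print.compartment_spec <- function(x, ...) {
  cat("Compartmentalized dendrite geometry\n")
  cat(sprintf("  compartment length L : %.4g um\n", x$L))
  cat(sprintf("  opening radius eps   : %.4g um (eps/L = %.3g)\n", x$eps, x$eps / x$L))
  cat(sprintf("  dendrite radius a    : %.4g um (S = %.4g um^2)\n", x$a, x$S))
  cat(sprintf("  free diffusion D     : %.4g um^2/s\n", x$D))
  cat(sprintf("  compartment parameter: %.4g  (D_eff = %.4g um^2/s)\n",
              compartment_parameter(x), effective_diffusion_constant(x)))
  invisible(x)
}

#' Jittered (almost periodic) barrier specification
#'
#' Barrier positions are perturbed around the periodic lattice by a
#' centered random displacement of standard deviation `sigma`. Small
#' jitter increases the apparent diffusion constant and turns the reduced
#' description into a fourth-order diffusion-type equation.
#'
#' @param base A [compartment_spec()].
#' @param sigma Jitter amplitude (standard deviation of barrier
#'   displacement), um, >= 0.
#' @param sigma_bound Maximum admissible `sigma/L` (default 0.3).
#' @param on_invalid `"error"` or `"warn"` when the bound is exceeded.
#' @return An object of class `jitter_spec`.
#' @export
jitter_spec <- function(base, sigma, sigma_bound = 0.3,
                        on_invalid = c("error", "warn")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(inherits(base, "compartment_spec"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  if (sigma / base$L > sigma_bound) {
    msg <- sprintf("sigma/L = %.3g exceeds the small-jitter bound %.3g",
                   sigma / base$L, sigma_bound)
    if (on_invalid == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(list(base = base, sigma = sigma, sigma_bound = sigma_bound),
            class = "jitter_spec")
}

#' Spatially inhomogeneous opening/volume profile
#'
#' Generalizes the periodic model to position-dependent opening radius
#' `eps(x)` and compartment volume `V(x)` on a dendrite `[0, L_dend]`.
#' Both callables must be strictly positive and smooth; derivatives are
#' taken by central finite differences.
#'
#' @param eps_of_x Function position (um) -> opening radius (um).
#' @param V_of_x Function position (um) -> compartment volume (um^3).
#' @param L_dend Dendrite length, um.
#' @return An object of class `inhomogeneous_profile`.
#' @export
inhomogeneous_profile <- function(eps_of_x, V_of_x, L_dend) {
  stopifnot(is.function(eps_of_x), is.function(V_of_x),
            is.numeric(L_dend), L_dend > 0)
  xs <- seq(0, L_dend, length.out = 33)
  if (any(!is.finite(eps_of_x(xs))) || any(eps_of_x(xs) <= 0))
    stop("eps_of_x must be strictly positive and finite on [0, L_dend]",
         call. = FALSE)
  if (any(!is.finite(V_of_x(xs))) || any(V_of_x(xs) <= 0))
    stop("V_of_x must be strictly positive and finite on [0, L_dend]",
         call. = FALSE)
  structure(list(eps_of_x = eps_of_x, V_of_x = V_of_x, L_dend = L_dend),
            class = "inhomogeneous_profile")
}
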