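#' Solve the compartment-chain mass-balance ODEs
#'
#' The discrete precursor of the reduced PDE: particle counts `N_j` in a
#' chain of `M` identical compartments exchange through narrow openings
#' at the hopping rate `k = D_eff / L^2` set by the series of aperture
#' and bulk conductances (see [compartment_parameter()]).
#' Conservation of mass gives
#' `dN_j/dt = k (N_{j+1} - 2 N_j + N_{j-1})` in the interior; a
#' reflecting end simply drops the missing neighbor flux, an absorbing
#' end additionally loses calcium through the terminal opening at the
#' one-sided escape rate `1 / tau = 4 eps D / V` (the opening drains
#' into a perfect sink, so only one access resistance applies).
#'
#' @param N0 Initial counts per compartment (non-negative vector,
#'   `M >= 3`).
#' @param spec A [compartment_spec()] (sets `tau` via geometry).
#' @param t_grid Output times, s.
#' @param ends Length-2 character vector, each `"reflecting"` or
#'   `"absorbing"`, for the chain ends.
#' @return A list with `time_s`, `counts` (matrix times x M) and `rate`
#'   (the hopping rate 1/s).
#' @export
solve_compartment_chain <- function(N0, spec, t_grid,
                                    ends = c("reflecting", "reflecting")) {
  stopifnot(inherits(spec, "compartment_spec"))
  M <- length(N0)
  if (M < 3) stop("at least 3 compartments required", call. = FALSE)
  if (any(N0 < 0)) stop("counts must be non-negative", call. = FALSE)
  ends <- match.arg(ends, c("reflecting", "absorbing"), several.ok = TRUE)
  if (length(ends) == 1) ends <- rep(ends, 2)
  V <- spec$S * spec$L
  k <- effective_diffusion_constant(spec) / spec$L^2   # net hop rate
  k_esc <- 1 / mfpt_escape_3d(V, spec$eps, spec$D)
  rhs <- function(t, N, p) {
    Nl <- c(N[1], N[-M]); Nr <- c(N[-1], N[M])   # reflecting ghosts
    d <- k * (Nl - 2 * N + Nr)
    if (ends[1] == "absorbing") d[1] <- d[1] - k_esc * N[1]
    if (ends[2] == "absorbing") d[M] <- d[M] - k_esc * N[M]
    list(d)
  }
  sol <- deSolve::ode(y = N0, times = t_grid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff solver failed on the compartment chain; see deSolve diagnostics",
         call. = FALSE)
  list(time_s = sol[, 1], counts = unname(sol[, -1, drop = FALSE]), rate = k)
}
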