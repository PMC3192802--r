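## 1D solvers for the reduced (homogenized) diffusion description.
## Conservative finite volumes on a cell-centered grid, Crank-Nicolson
## time stepping via a precomputed dense propagator (grids are small).

build_grid <- function(L_domain, dx) {
  n <- max(3L, round(L_domain / dx))
  dx <- L_domain / n
  list(x = (seq_len(n) - 0.5) * dx, dx = dx, n = n)
}

## second-order operator dc/dt = d/dx ( d(b c)/dx ) as a dense matrix,
## with reflecting (zero-flux), absorbing (Dirichlet 0) or mixed ends
diffusion_operator <- function(b, n, dx, bc) {
  A <- matrix(0, n, n)
  q <- b / dx^2
  for (i in seq_len(n)) {
    if (i > 1) { A[i, i - 1] <- A[i, i - 1] + q[i - 1]; A[i, i] <- A[i, i] - q[i] }
    if (i < n) { A[i, i + 1] <- A[i, i + 1] + q[i + 1]; A[i, i] <- A[i, i] - q[i] }
  }
  bcs <- expand_bc(bc)
  if (bcs[1] == "absorbing") { A[1, ] <- 0; A[1, 1] <- -2 * q[1] ; A[1, 2] <- A[1, 2] + q[2] }
  if (bcs[2] == "absorbing") { A[n, ] <- 0; A[n, n] <- -2 * q[n] ; A[n, n - 1] <- A[n, n - 1] + q[n - 1] }
  A
}

expand_bc <- function(bc) {
  bc <- match.arg(bc, c("reflecting", "absorbing", "mixed"))
  switch(bc,
         reflecting = c("reflecting", "reflecting"),
         absorbing = c("absorbing", "absorbing"),
         mixed = c("absorbing", "reflecting"))
}

cn_propagator <- function(A, dt) {
  n <- nrow(A)
  solve(diag(n) - dt / 2 * A, diag(n) + dt / 2 * A)
}

resolve_c0 <- function(c0, x) {
  v <- if (is.function(c0)) c0(x) else {
    if (length(c0) != length(x))
      stop("initial condition vector must match the solver grid (", length(x),
           " nodes); supply a function of x instead", call. = FALSE)
    c0
  }
  if (any(v < 0)) stop("initial concentration must be non-negative", call. = FALSE)
  v
}

#' Solve the reduced 1D effective diffusion equation
#'
#' Integrates `dc/dt = d^2(b(x) c)/dx^2` on `[0, L_domain]` with
#' conservative Crank-Nicolson finite volumes. For the homogeneous
#' crowding model `b(x)` is the constant effective diffusion constant;
#' supplying an [inhomogeneous_profile()] (with a [compartment_spec()])
#' uses the position-dependent coefficients of
#' [drift_and_diffusion_coefficients()].
#'
#' @param c0 Initial concentration: a function of position or a vector on
#'   the solver grid. Must be non-negative.
#' @param t_grid Output times, s (first entry may be 0).
#' @param D_eff Constant effective diffusion constant, um^2/s (ignored if
#'   `profile` given).
#' @param L_domain Domain length, um.
#' @param dx Grid spacing, um (default 0.05).
#' @param bc Boundary conditions: `"reflecting"` (both ends, mass
#'   conserving), `"absorbing"` (both ends) or `"mixed"` (absorbing at 0,
#'   reflecting at `L_domain`).
#' @param profile Optional [inhomogeneous_profile()].
#' @param spec Optional [compartment_spec()], required with `profile`.
#' @param dt_max Maximum internal time step, s (default 1e-4).
#' @return A [linescan_record()] with the solution sampled at `t_grid`.
#' @examples
#' rec <- solve_reduced_1d(function(x) exp(-(x - 10)^2 / 0.5),
#'                         t_grid = seq(0, 0.01, 1e-3),
#'                         D_eff = 20, L_domain = 20)
#' @export
solve_reduced_1d <- function(c0, t_grid, D_eff = NULL, L_domain,
                             dx = 0.05, bc = "reflecting",
                             profile = NULL, spec = NULL, dt_max = 1e-4) {
  g <- build_grid(L_domain, dx)
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "inhomogeneous_profile"))
    if (is.null(spec)) stop("a compartment_spec is required with a profile", call. = FALSE)
    cf <- drift_and_diffusion_coefficients(profile, spec)
    b <- cf$b_of_x(g$x)
  } else {
    if (is.null(D_eff) || D_eff <= 0)
      stop("D_eff must be a positive number (or supply a profile)", call. = FALSE)
    b <- rep(D_eff, g$n)
  }
  v0 <- resolve_c0(c0, g$x)
  A <- diffusion_operator(b, g$n, g$dx, bc)
  vals <- march_cn(A, v0, t_grid, dt_max, g$dx, max(b))
  linescan_record(t_grid, g$x, vals,
                  meta = list(dx = g$dx, bc = bc, solver = "reduced_1d",
                              normalization = "none"))
}

## Crank-Nicolson march sampling at t_grid; constant operator so the
## propagator for each distinct substep size is factored once.
march_cn <- function(A, v0, t_grid, dt_max, dx, bmax) {
  if (t_grid[1] != 0) t_all <- c(0, t_grid) else t_all <- t_grid
  out <- matrix(NA_real_, length(t_grid), length(v0))
  v <- v0
  props <- list()
  t_now <- 0
  k_out <- 1
  if (t_grid[1] == 0) { out[1, ] <- v; k_out <- 2 }
  for (tt in t_grid[t_grid > 0]) {
    span <- tt - t_now
    m <- max(1L, ceiling(span / dt_max))
    dt <- span / m
    key <- format(dt, digits = 12)
    if (is.null(props[[key]])) props[[key]] <- cn_propagator(A, dt)
    P <- props[[key]]
    for (j in seq_len(m)) v <- P %*% v
    v <- as.vector(v)
    out[k_out, ] <- v
    k_out <- k_out + 1
    t_now <- tt
  }
  out
}

#' Solve the fourth-order reduced equation for jittered barriers
#'
#' Almost periodic barrier placement adds an O(sigma^2) fourth-order
#' correction to the reduced description:
#' \deqn{\partial_t u = D_\sigma \partial_x^2 u - D_{eff}\sigma^2 \partial_x^4 u,}
#' with `D_sigma` from [jittered_effective_D()]. The equation is marched
#' implicitly (Crank-Nicolson; the fourth-order term is stiff) in
#' conservative flux form with mirror ghost cells, so the zeroth moment
#' is conserved and the `sigma -> 0` limit reproduces
#' [solve_reduced_1d()] exactly.
#'
#' @param c0 Initial condition (function of position or grid vector).
#' @param jitter A [jitter_spec()].
#' @param t_grid Output times, s.
#' @param L_domain Domain length, um.
#' @param dx Grid spacing, um (default 0.05).
#' @param dt_max Maximum internal time step, s.
#' @return A [linescan_record()].
#' @export
solve_fourth_order <- function(c0, jitter, t_grid, L_domain,
                               dx = 0.05, dt_max = 1e-4) {
  stopifnot(inherits(jitter, "jitter_spec"))
  g <- build_grid(L_domain, dx)
  D2 <- jittered_effective_D(jitter)
  K4 <- effective_diffusion_constant(jitter$base) * jitter$sigma^2
  v0 <- resolve_c0(c0, g$x)
  A <- fourth_order_operator(D2, K4, g$n, g$dx)
  vals <- march_cn(A, v0, t_grid, dt_max, g$dx, D2)
  linescan_record(t_grid, g$x, vals,
                  meta = list(dx = g$dx, bc = "reflecting",
                              solver = "fourth_order", sigma = jitter$sigma,
                              normalization = "none"))
}

## flux form F_{i+1/2} = D2 (u_{i+1}-u_i)/dx - K4 (u_{i+2}-3u_{i+1}+3u_i-u_{i-1})/dx^3
## with mirror ghosts (u_{-1}=u_0, u_{-2}=u_1, ...): wall fluxes vanish.
fourth_order_operator <- function(D2, K4, n, dx) {
  idx <- function(i) {            # mirror-reflected cell index
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  Fmat <- matrix(0, n + 1, n)     # face f between cells f-1 and f
  for (f in 2:n) {                # interior faces; wall faces stay zero
    iL <- f - 1; iR <- f
    add <- function(i, w) Fmat[f, idx(i)] <<- Fmat[f, idx(i)] + w
    add(iR,  D2 / dx); add(iL, -D2 / dx)
    add(iR + 1, -K4 / dx^3); add(iR, 3 * K4 / dx^3)
    add(iL, -3 * K4 / dx^3); add(iL - 1, K4 / dx^3)
  }
  (Fmat[2:(n + 1), , drop = FALSE] - Fmat[1:n, , drop = FALSE]) / dx
}
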