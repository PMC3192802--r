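#' Full reaction-diffusion system specification for dendritic calcium
#'
#' Bundles geometry, calcium transport, buffers, dye, pumps, spines and
#' synaptic inputs into one solvable system. Defaults reproduce the
#' standard parameter table (medium buffer levels, both pumps, dye on);
#' parameters whose printed values are not available and were filled
#' from the cited literature are listed in `fill_flags`.
#'
#' @param L_dend Dendritic segment length, um (default 20).
#' @param radius Dendrite radius, um (default 0.5).
#' @param dx Grid spacing, um (default 0.05).
#' @param D_ca Calcium (dye-bound) diffusion constant, um^2/s:
#'   20 for the crowded dendrite, 400 for aqueous solution.
#' @param buffers List of [buffer_spec()]s (default medium calmodulin
#'   and calcineurin).
#' @param dye A [buffer_spec()] for the indicator dye or `NULL`
#'   (default [fluo4_spec()]).
#' @param pumps List of [pump_spec()]s (default PMCA and NCX).
#' @param synapses List of [synapse_spec()]s (default none).
#' @param spines A [spine_sink_spec()] or `NULL` (default none).
#' @param compartment_length Crowding compartment length used for the
#'   spine sink rate, um (default from [calibrate_geometry()] at the
#'   1/20 reduction).
#' @param resting_ca Resting calcium concentration, uM (default 0).
#' @param initial_pulse Optional list `(amplitude_uM, center, width)`
#'   adding a Gaussian calcium pulse to the initial condition.
#' @return A list of class `reaction_system_spec` with a `fill_flags`
#'   field naming literature-filled parameters.
#' @export
reaction_system_spec <- function(L_dend = 20, radius = 0.5, dx = 0.05,
                                 D_ca = 20,
                                 buffers = list(calmodulin_spec(),
                                                calcineurin_spec()),
                                 dye = fluo4_spec(),
                                 pumps = list(pmca_spec(), ncx_spec()),
                                 synapses = list(), spines = NULL,
                                 compartment_length = NULL,
                                 resting_ca = 0, initial_pulse = NULL) {
  stopifnot(L_dend > 0, radius > 0, dx > 0, D_ca > 0, resting_ca >= 0)
  if (is.null(compartment_length))
    compartment_length <- calibrate_geometry(0.05, a = radius)$L
  fills <- c(
    "PMCA rate_per_pump (27 ions/s)", "NCX rate_per_pump (4800 ions/s)",
    "PMCA K_half (0.45 uM)", "NCX K_half (1.8 uM)",
    "NMDA ca_fraction (0.1)",
    "initial pulse amplitude (1 uM unless overridden)",
    "free-Ca diffusion constants (400 aqueous / 20 crowded um^2/s)")
  structure(list(L_dend = L_dend, radius = radius, dx = dx, D_ca = D_ca,
                 S = pi * radius^2, perimeter = 2 * pi * radius,
                 buffers = buffers, dye = dye, pumps = pumps,
                 synapses = synapses, spines = spines,
                 compartment_length = compartment_length,
                 resting_ca = resting_ca, initial_pulse = initial_pulse,
                 fill_flags = fills),
            class = "reaction_system_spec")
}

#' Reaction right-hand side of a multi-site buffer at one state
#'
#' Sequential mass-action ladder `B_{j-1} + Ca <-> B_j`. States are
#' linear densities; the unbound state is derived from conservation
#' (`b_0 = total - sum(b_j)`), so total buffer is conserved exactly by
#' construction.
#'
#' @param u_ca Calcium linear density, particles/um (vector over nodes).
#' @param u_b Bound-state densities: matrix `nodes x n_sites`
#'   (columns = 1..n_sites calcium bound), particles/um.
#' @param spec A [buffer_spec()].
#' @param cross_section Dendrite cross-section, um^2.
#' @return List with `du_ca` (particles/(um s)) and `du_b`
#'   (matrix like `u_b`); the derivatives of all occupancy states
#'   (including the implicit unbound state) sum to zero.
#' @export
buffer_rhs <- function(u_ca, u_b, spec, cross_section) {
  stopifnot(inherits(spec, "buffer_spec"))
  u_b <- as.matrix(u_b)
  ns <- spec$n_sites
  if (ncol(u_b) != ns) stop("u_b must have n_sites columns", call. = FALSE)
  conv <- dendro_constants$particles_per_um3_per_uM * cross_section
  tot <- spec$total_concentration * conv
  b0 <- tot - rowSums(u_b)
  states <- cbind(b0, u_b)              # j = 0..ns
  c_uM <- pmax(u_ca, 0) / conv
  du_b <- matrix(0, nrow(u_b), ns)
  du_ca <- numeric(length(u_ca))
  for (j in seq_len(ns)) {
    fwd <- spec$k_forward[j] * c_uM * states[, j]
    bwd <- spec$k_backward[j] * states[, j + 1]
    net <- fwd - bwd
    du_b[, j] <- du_b[, j] + net
    if (j > 1) du_b[, j - 1] <- du_b[, j - 1] - net
    du_ca <- du_ca - net
  }
  list(du_ca = du_ca, du_b = du_b)
}

## reflecting-boundary discrete Laplacian flux divergence
lap1d <- function(u, dx) {
  n <- length(u)
  (c(u[-1], u[n]) - 2 * u + c(u[1], u[-n])) / dx^2
}

#' Assemble and integrate the calcium reaction-diffusion system
#'
#' Method-of-lines discretization on a uniform grid (reflecting ends)
#' integrated with a stiff solver (`deSolve::ode.1D`, lsodes). State
#' variables are linear particle densities: free calcium, each bound
#' buffer occupancy state and dye-bound calcium; unbound buffer states
#' follow from conservation. Pumps, spine sinks and synaptic input
#' enter as local source/sink terms; their instantaneous system-wide
#' rates are returned alongside the trajectory for budget auditing.
#'
#' @param system A [reaction_system_spec()].
#' @param t_end Final time, s.
#' @param times Output times, s (default 201 points to `t_end`).
#' @param rtol,atol Solver tolerances.
#' @return An object of class `calcium_trajectory`: `times`, `x`,
#'   `u_ca` (matrix times x nodes), `buffers` (list of 3D arrays),
#'   `u_dye`, flux series `pump_rate`, `spine_rate`, `inject_rate`
#'   (particles/s, system totals) and the `system`.
#' @export
assemble_and_solve <- function(system, t_end, times = NULL,
                               rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(system, "reaction_system_spec"), t_end > 0)
  if (is.null(times)) times <- seq(0, t_end, length.out = 201)
  sy <- system
  n <- max(3L, round(sy$L_dend / sy$dx))
  dx <- sy$L_dend / n
  x <- (seq_len(n) - 0.5) * dx
  conv <- dendro_constants$particles_per_um3_per_uM * sy$S

  nb <- length(sy$buffers)
  nsites <- vapply(sy$buffers, function(b) b$n_sites, integer(1))
  has_dye <- !is.null(sy$dye)
  nspec <- 1L + sum(nsites) + as.integer(has_dye)

  ## initial condition
  u_ca0 <- rep(sy$resting_ca * conv, n)
  if (!is.null(sy$initial_pulse)) {
    p <- sy$initial_pulse
    amp <- (p$amplitude_uM %||% 1) * conv
    u_ca0 <- u_ca0 + amp * exp(-(x - p$center)^2 / (2 * (p$width %||% 0.5)^2))
  }
  y0 <- u_ca0
  for (b in sy$buffers) y0 <- c(y0, rep(0, n * b$n_sites))
  if (has_dye) y0 <- c(y0, rep(0, n))

  ## spine sink rates per node
  spine_k <- rep(0, n)
  if (!is.null(sy$spines)) {
    V_comp <- sy$S * sy$compartment_length
    k1 <- spine_sink_rate(sy$spines$neck_radius, V_comp, sy$D_ca,
                          dendrite_radius = sy$radius)
    if (!is.null(sy$spines$positions)) {
      for (xs in sy$spines$positions) {
        idx <- abs(x - xs) <= sy$compartment_length / 2
        spine_k[idx] <- spine_k[idx] + k1
      }
    } else {
      spine_k <- spine_k + k1 * sy$spines$density * sy$compartment_length
    }
  }

  ## synaptic footprint per node (particles/(um s) per unit q(t))
  syn_foot <- lapply(sy$synapses, function(syn) {
    f <- as.numeric(abs(x - syn$position) <= syn$receptor_radius)
    if (sum(f) == 0) f[which.min(abs(x - syn$position))] <- 1
    f / (sum(f) * dx)              # integrates to 1 over the grid
  })

  pump_line <- vapply(sy$pumps, function(p)
    p$rate_per_pump * p$surface_density * sy$perimeter, numeric(1))

  idx_ca <- seq_len(n)
  idx_buf <- list(); off <- n
  for (b in seq_len(nb)) {
    idx_buf[[b]] <- off + seq_len(n * nsites[b])
    off <- off + n * nsites[b]
  }
  idx_dye <- if (has_dye) off + seq_len(n) else integer(0)

  rhs <- function(t, y, parms) {
    u_ca <- y[idx_ca]
    d_ca <- sy$D_ca * lap1d(u_ca, dx)
    dy <- numeric(length(y))
    c_uM <- pmax(u_ca, 0) / conv

    for (b in seq_len(nb)) {
      bs <- sy$buffers[[b]]
      u_b <- matrix(y[idx_buf[[b]]], n, bs$n_sites)
      r <- buffer_rhs(u_ca, u_b, bs, sy$S)
      d_ca <- d_ca + r$du_ca
      du_b <- r$du_b
      if (bs$diffusion > 0)
        for (j in seq_len(bs$n_sites))
          du_b[, j] <- du_b[, j] + bs$diffusion * lap1d(u_b[, j], dx)
      dy[idx_buf[[b]]] <- du_b
    }
    if (has_dye) {
      u_d <- y[idx_dye]
      r <- buffer_rhs(u_ca, matrix(u_d, n, 1), sy$dye, sy$S)
      d_ca <- d_ca + r$du_ca
      du_d <- r$du_b[, 1]
      if (sy$dye$diffusion > 0) du_d <- du_d + sy$dye$diffusion * lap1d(u_d, dx)
      dy[idx_dye] <- du_d
    }
    pump_loss <- numeric(n)
    for (p in seq_along(sy$pumps))
      pump_loss <- pump_loss +
        pump_line[p] * hill_activation(c_uM, sy$pumps[[p]])
    spine_loss <- spine_k * pmax(u_ca, 0)
    inj <- numeric(n)
    for (s in seq_along(sy$synapses)) {
      q <- nmda_current(t, sy$synapses[[s]]) * 1e-12 *
        sy$synapses[[s]]$ca_fraction /
        (dendro_constants$ca_valence * dendro_constants$elementary_charge_C)
      inj <- inj + q * syn_foot[[s]]
    }
    d_ca <- d_ca - pump_loss - spine_loss + inj
    dy[idx_ca] <- d_ca
    list(dy, c(pump_rate = sum(pump_loss) * dx,
               spine_rate = sum(spine_loss) * dx,
               inject_rate = sum(inj) * dx))
  }

  sol <- deSolve::ode.1D(y = y0, times = times, func = rhs, parms = NULL,
                         nspec = nspec, dimens = n, method = "lsodes",
                         rtol = rtol, atol = atol,
                         lrw = 120 * length(y0) + 20000)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff solver failed; see deSolve diagnostics (diagnostics(sol))",
         call. = FALSE)
  ts <- sol[, 1]
  ycols <- 1 + seq_len(length(y0))
  u_ca <- sol[, ycols[idx_ca], drop = FALSE]
  buffers <- lapply(seq_len(nb), function(b) {
    arr <- array(sol[, ycols[idx_buf[[b]]], drop = FALSE],
                 dim = c(length(ts), n, nsites[b]))
    dimnames(arr) <- NULL
    arr
  })
  names(buffers) <- vapply(sy$buffers, function(b) b$name, character(1))
  u_dye <- if (has_dye) sol[, ycols[idx_dye], drop = FALSE] else NULL
  extra <- (max(ycols) + 1):ncol(sol)
  structure(list(times = ts, x = x, dx = dx, u_ca = unname(u_ca),
                 buffers = buffers, u_dye = if (has_dye) unname(u_dye),
                 pump_rate = unname(sol[, extra[1]]),
                 spine_rate = unname(sol[, extra[2]]),
                 inject_rate = unname(sol[, extra[3]]),
                 system = sy),
            class = "calcium_trajectory")
}

#' @export
print.calcium_trajectory <- function(x, ...) {
  cat(sprintf("Calcium trajectory: %d times x %d nodes (dx = %.3g um), D = %.4g um^2/s\n",
              length(x$times), length(x$x), x$dx, x$system$D_ca))
  cat(sprintf("  peak free [Ca]: %.4g uM\n",
              linear_density_to_concentration(max(x$u_ca), x$system$S)))
  invisible(x)
}

#' Total calcium budget of a trajectory
#'
#' At every output time: free + buffer-bound + dye-bound calcium on the
#' grid, plus cumulative pumped and spine-absorbed (trapezoid over the
#' recorded system-wide rates), minus cumulative injected (closed form
#' for the dual-exponential trains). With all sinks and inputs off this
#' reduces to exact conservation of total calcium.
#'
#' @param traj A `calcium_trajectory`.
#' @return Data frame with per-time budget components and the relative
#'   closure error `rel_error` (vs the initial total, or the peak total
#'   when starting from zero).
#' @export
calcium_budget <- function(traj) {
  stopifnot(inherits(traj, "calcium_trajectory"))
  dx <- traj$dx
  free <- rowSums(traj$u_ca) * dx
  bound <- rep(0, length(traj$times))
  for (b in seq_along(traj$buffers)) {
    arr <- traj$buffers[[b]]
    for (j in seq_len(dim(arr)[3]))
      bound <- bound +
        rowSums(matrix(arr[, , j], nrow = dim(arr)[1])) * dx * j
  }
  dyeb <- if (!is.null(traj$u_dye)) rowSums(traj$u_dye) * dx else 0
  cum_trap <- function(v) c(0, cumsum((v[-1] + v[-length(v)]) / 2 *
                                        diff(traj$times)))
  pumped <- cum_trap(traj$pump_rate)
  spined <- cum_trap(traj$spine_rate)
  injected <- vapply(traj$times, function(t) {
    tot <- 0
    for (s in traj$system$synapses) tot <- tot + nmda_cumulative_ions(t, s)
    tot
  }, numeric(1))
  total <- free + bound + dyeb + pumped + spined - injected
  ref <- max(abs(total[1]), max(free + bound + dyeb))
  data.frame(time_s = traj$times, free = free, bound = bound, dye = dyeb,
             pumped = pumped, spine_absorbed = spined, injected = injected,
             total = total,
             rel_error = abs(total - total[1]) / ref)
}

#' Spatial spread of the calcium signal (FWHM-based)
#'
#' For every output time: the full width at half maximum of the free
#' calcium profile above baseline (linear interpolation at half the
#' instantaneous peak) and the spread `0.5 * FWHM` measured from the
#' source. Multimodal profiles are flagged and measured around the
#' global peak.
#'
#' @param traj A `calcium_trajectory`.
#' @param baseline Baseline linear density subtracted first (default the
#'   resting level).
#' @return Data frame `time_s`, `peak`, `fwhm_um`, `spread_um`,
#'   `multimodal`; all-zero profiles yield `NA`.
#' @export
measure_spread <- function(traj, baseline = NULL) {
  stopifnot(inherits(traj, "calcium_trajectory"))
  conv <- dendro_constants$particles_per_um3_per_uM * traj$system$S
  if (is.null(baseline)) baseline <- traj$system$resting_ca * conv
  x <- traj$x
  out <- lapply(seq_along(traj$times), function(k) {
    prof <- pmax(traj$u_ca[k, ] - baseline, 0)
    pk <- max(prof)
    if (pk <= 0) return(data.frame(time_s = traj$times[k], peak = NA_real_,
                                   fwhm_um = NA_real_, spread_um = NA_real_,
                                   multimodal = NA))
    half <- pk / 2
    above <- prof >= half
    runs <- rle(above)
    multimodal <- sum(runs$values) > 1
    ipk <- which.max(prof)
    ## walk out from the global peak to the half crossings
    iL <- ipk; while (iL > 1 && prof[iL - 1] >= half) iL <- iL - 1
    iR <- ipk; while (iR < length(prof) && prof[iR + 1] >= half) iR <- iR + 1
    xl <- if (iL == 1) x[1] else
      stats::approx(prof[c(iL - 1, iL)], x[c(iL - 1, iL)], xout = half)$y
    xr <- if (iR == length(prof)) x[length(x)] else
      stats::approx(prof[c(iR + 1, iR)], x[c(iR + 1, iR)], xout = half)$y
    fw <- xr - xl
    data.frame(time_s = traj$times[k], peak = pk, fwhm_um = fw,
               spread_um = fw / 2, multimodal = multimodal)
  })
  do.call(rbind, out)
}

#' Run a named calcium scenario
#'
#' Shipped scenarios: `fig4a`/`fig4b` — a 1 uM calcium pulse spreading
#' by bare diffusion in aqueous solution (400 um^2/s) vs the crowded
#' dendrite (20 um^2/s); `fig4c`/`fig4d` — the same with medium buffers
#' (CaM 25 uM, CN 10 uM), both pumps and the dye; `fig4e` — a 1 s NMDA
#' pulse train at the midpoint of the crowded dendrite;
#' `frequency_sweep` — `fig4e` repeated over a frequency grid with a
#' spread-vs-frequency table.
#'
#' @param name One of `"fig4a"`, `"fig4b"`, `"fig4c"`, `"fig4d"`,
#'   `"fig4e"`, `"frequency_sweep"`.
#' @param overrides Named list overriding [reaction_system_spec()]
#'   arguments (e.g. `dx`, `L_dend`, `synapse frequency`).
#' @param frequencies Frequency grid for the sweep, Hz.
#' @param t_end Simulated time, s (default 0.01 for pulse scenarios,
#'   1 for synaptic ones).
#' @param fig4e_frequency Pulse-train frequency for `fig4e`, Hz
#'   (default 50).
#' @return For single scenarios: list with `trajectory`, `spread` and a
#'   `report` (resolved parameters incl. fill flags). The sweep returns
#'   `runs` (per-frequency), a `spread_table` and the saturation
#'   frequency (smallest tested frequency beyond which the spread
#'   changes by <= 10% between consecutive frequencies).
#' @export
run_scenario <- function(name = c("fig4a", "fig4b", "fig4c", "fig4d",
                                  "fig4e", "frequency_sweep"),
                         overrides = list(),
                         frequencies = c(1, 5, 10, 20, 50, 100),
                         t_end = NULL, fig4e_frequency = 50) {
  name <- match.arg(name)
  base <- function(D, reactions, syn_freq = NULL, t_default) {
    args <- list(
      D_ca = D,
      buffers = if (reactions) list(calmodulin_spec(), calcineurin_spec())
                else list(),
      dye = if (reactions) fluo4_spec() else NULL,
      pumps = if (reactions) list(pmca_spec(), ncx_spec()) else list())
    if (is.null(syn_freq)) {
      args$initial_pulse <- list(amplitude_uM = 1, center = 10, width = 0.5)
    } else {
      args$synapses <- list(synapse_spec(position = 10,
                                         frequency = syn_freq,
                                         train_duration = 1))
    }
    args[names(overrides)] <- overrides
    sys <- do.call(reaction_system_spec, args)
    tt <- t_end %||% t_default
    traj <- assemble_and_solve(sys, tt)
    sp <- measure_spread(traj)
    list(trajectory = traj, spread = sp,
         report = scenario_report(name, sys, sp))
  }
  switch(name,
    fig4a = base(400, FALSE, t_default = 0.01),
    fig4b = base(20, FALSE, t_default = 0.01),
    fig4c = base(400, TRUE, t_default = 0.01),
    fig4d = base(20, TRUE, t_default = 0.01),
    fig4e = base(20, TRUE, syn_freq = fig4e_frequency, t_default = 1),
    frequency_sweep = {
      runs <- lapply(frequencies, function(f)
        base(20, TRUE, syn_freq = f, t_default = 1))
      names(runs) <- paste0(frequencies, "Hz")
      tab <- data.frame(
        frequency_hz = frequencies,
        max_spread_um = vapply(runs, function(r)
          max(r$spread$spread_um, na.rm = TRUE), numeric(1)))
      sat <- saturation_frequency(tab)
      list(runs = runs, spread_table = tab, saturation_frequency = sat,
           report = runs[[length(runs)]]$report)
    })
}

## smallest tested frequency beyond which consecutive relative spread
## changes stay within 10%
saturation_frequency <- function(tab, tol = 0.1) {
  f <- tab$frequency_hz; s <- tab$max_spread_um
  relchg <- abs(diff(s)) / pmax(s[-length(s)], 1e-12)
  for (i in seq_along(relchg))
    if (all(relchg[i:length(relchg)] <= tol)) return(f[i])
  f[length(f)]
}

scenario_report <- function(name, sys, spread) {
  list(scenario = name,
       parameters = list(
         L_dend_um = sys$L_dend, radius_um = sys$radius, dx_um = sys$dx,
         D_ca_um2_s = sys$D_ca,
         buffers = lapply(sys$buffers, unclass),
         dye = if (!is.null(sys$dye)) unclass(sys$dye),
         pumps = lapply(sys$pumps, unclass),
         synapses = lapply(sys$synapses, unclass),
         spines = if (!is.null(sys$spines)) unclass(sys$spines)),
       fill_flags = sys$fill_flags,
       max_spread_um = suppressWarnings(max(spread$spread_um, na.rm = TRUE)))
}
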