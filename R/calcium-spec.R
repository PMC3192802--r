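#' Multi-site calcium buffer specification
#'
#' A buffer with `n_sites` sequential calcium binding steps
#' `B_j + Ca <-> B_{j+1}` (mass action), e.g. calmodulin (4 sites) or
#' calcineurin (1 site). Buffers are immobile by default; a nonzero
#' `diffusion` adds buffer transport terms.
#'
#' @param name Buffer name.
#' @param k_forward Forward rates per step, 1/(uM s), length `n_sites`.
#' @param k_backward Backward rates per step, 1/s, length `n_sites`.
#' @param total_concentration Total buffer concentration, uM.
#' @param diffusion Buffer diffusion constant, um^2/s (default 0,
#'   immobile).
#' @return A list of class `buffer_spec`.
#' @examples
#' calmodulin_spec(25)
#' @export
buffer_spec <- function(name, k_forward, k_backward, total_concentration,
                        diffusion = 0) {
  n_sites <- length(k_forward)
  if (n_sites < 1 || n_sites > 4)
    stop("1 to 4 binding sites supported", call. = FALSE)
  if (length(k_backward) != n_sites)
    stop("k_forward and k_backward must have equal length", call. = FALSE)
  if (any(k_forward <= 0) || any(k_backward <= 0))
    stop("rates must be positive", call. = FALSE)
  stopifnot(total_concentration >= 0, diffusion >= 0)
  structure(list(name = name, n_sites = n_sites,
                 k_forward = as.numeric(k_forward),
                 k_backward = as.numeric(k_backward),
                 total_concentration = total_concentration,
                 diffusion = diffusion),
            class = "buffer_spec")
}

#' Calmodulin buffer with four sequential binding steps
#'
#' Rate pairs 160/405 (1/(uM s), 1/s) for the first two steps and
#' 2.3/2.4 for the last two.
#'
#' @param total_concentration Total CaM, uM (default 25, the medium
#'   level; low/high are 10/100).
#' @return A `buffer_spec`.
#' @export
calmodulin_spec <- function(total_concentration = 25) {
  buffer_spec("calmodulin",
              k_forward = c(160, 160, 2.3, 2.3),
              k_backward = c(405, 405, 2.4, 2.4),
              total_concentration = total_concentration)
}

#' Calcineurin buffer with a single binding site (rates 50/25)
#'
#' @param total_concentration Total CN, uM (default 10, the medium
#'   level; low/high are 5/25).
#' @return A `buffer_spec`.
#' @export
calcineurin_spec <- function(total_concentration = 10) {
  buffer_spec("calcineurin", k_forward = 50, k_backward = 25,
              total_concentration = total_concentration)
}

#' Fluo-4 calcium indicator dye (2 uM, rates 60/170)
#'
#' @param total_concentration Total dye, uM (default 2).
#' @return A `buffer_spec` (single site).
#' @export
fluo4_spec <- function(total_concentration = 2) {
  buffer_spec("fluo4", k_forward = 60, k_backward = 170,
              total_concentration = total_concentration)
}

#' Membrane calcium pump (PMCA / NCX) with Hill activation
#'
#' Extrusion flux per unit membrane area follows
#' `rate_per_pump * surface_density * c^h / (c^h + K_half^h)`.
#'
#' @param name Pump name.
#' @param rate_per_pump Ions extruded per pump per second at saturation.
#' @param surface_density Pumps per um^2 of membrane.
#' @param K_half Half-saturation calcium concentration, uM.
#' @param hill Hill coefficient, in `[1, 4]`.
#' @return A list of class `pump_spec`.
#' @export
pump_spec <- function(name, rate_per_pump, surface_density, K_half, hill) {
  stopifnot(rate_per_pump > 0, surface_density > 0, K_half > 0)
  if (hill < 1 || hill > 4)
    stop("hill coefficient must lie in [1, 4]", call. = FALSE)
  structure(list(name = name, rate_per_pump = rate_per_pump,
                 surface_density = surface_density, K_half = K_half,
                 hill = hill),
            class = "pump_spec")
}

#' Default PMCA pump (hill 1.0, 9200 pumps/um^2)
#'
#' The per-pump turnover (27 ions/s) and half-saturation (0.45 uM) are
#' literature-sourced fills; see the resolved-parameter report.
#'
#' @return A `pump_spec`.
#' @export
pmca_spec <- function() {
  pump_spec("PMCA", rate_per_pump = 27, surface_density = 9200,
            K_half = 0.45, hill = 1.0)
}

#' Default NCX exchanger (hill 1.7, 300 exchangers/um^2)
#'
#' The per-exchanger turnover (4800 ions/s) and half-saturation
#' (1.8 uM) are literature-sourced fills.
#'
#' @return A `pump_spec`.
#' @export
ncx_spec <- function() {
  pump_spec("NCX", rate_per_pump = 4800, surface_density = 300,
            K_half = 1.8, hill = 1.7)
}

#' NMDA-receptor synaptic input specification
#'
#' The synaptic current is a train of dual-exponential pulses
#' `I(t) = A (exp(-(t-t_k)/tau_decay) - exp(-(t-t_k)/tau_rise))` with
#' the prefactor chosen so each pulse peaks at `peak_current`. Current
#' converts to a calcium particle flux through
#' `ca_fraction / (2 e)` and is spread over a rectangle of half-width
#' `receptor_radius` at `position`.
#'
#' @param position Receptor location on the dendrite, um.
#' @param frequency Pulse frequency, Hz.
#' @param n_pulses Number of pulses; default fills `train_duration`.
#' @param train_duration Train length used to default `n_pulses`, s
#'   (default 1).
#' @param peak_current Peak single-receptor current, pA (default 9).
#' @param ca_fraction Fraction of current carried by calcium
#'   (default 0.1, a literature fill).
#' @param tau_rise_ms Rise time constant, ms (default 3).
#' @param tau_decay_ms Decay time constant, ms (default 80).
#' @param receptor_radius Half-width of the input footprint, um
#'   (default 0.025).
#' @param t0 Train onset, s (default 0).
#' @return A list of class `synapse_spec`.
#' @export
synapse_spec <- function(position, frequency, n_pulses = NULL,
                         train_duration = 1, peak_current = 9,
                         ca_fraction = 0.1, tau_rise_ms = 3,
                         tau_decay_ms = 80, receptor_radius = 0.025,
                         t0 = 0) {
  if (tau_rise_ms >= tau_decay_ms)
    stop("tau_rise must be smaller than tau_decay", call. = FALSE)
  if (ca_fraction <= 0 || ca_fraction >= 1)
    stop("ca_fraction must lie in (0, 1)", call. = FALSE)
  stopifnot(frequency > 0, peak_current > 0, receptor_radius > 0, t0 >= 0)
  if (is.null(n_pulses)) n_pulses <- max(1L, floor(frequency * train_duration))
  if (n_pulses > 1 && (n_pulses - 1) / frequency > train_duration + 1e-9)
    stop("n_pulses inconsistent with frequency and train_duration",
         call. = FALSE)
  structure(list(position = position, frequency = frequency,
                 n_pulses = as.integer(n_pulses),
                 peak_current = peak_current, ca_fraction = ca_fraction,
                 tau_rise = ms_to_s(tau_rise_ms),
                 tau_decay = ms_to_s(tau_decay_ms),
                 receptor_radius = receptor_radius, t0 = t0),
            class = "synapse_spec")
}

#' Passive spine sinks (perfect absorbers at the neck entrance)
#'
#' Calcium entering a spine neck is absorbed at the rate set by the
#' inverse narrow-escape time to the neck opening; see
#' [spine_sink_rate()].
#'
#' @param neck_radius Spine neck radius, um (the anatomical band is
#'   roughly 0.05-0.16 um).
#' @param positions Spine positions, um (or `NULL` with `density`).
#' @param density Spines per um (alternative to explicit positions).
#' @return A list of class `spine_sink_spec`.
#' @export
spine_sink_spec <- function(neck_radius, positions = NULL, density = NULL) {
  stopifnot(neck_radius > 0)
  if (is.null(positions) && is.null(density))
    stop("give spine positions or a density", call. = FALSE)
  structure(list(neck_radius = neck_radius, positions = positions,
                 density = density),
            class = "spine_sink_spec")
}

#' Saturable Hill activation of a pump
#'
#' @param c_uM Calcium concentration, uM (vector ok; negative values are
#'   clamped to 0).
#' @param pump A `pump_spec`.
#' @return Activation in `[0, 1)`: `c^h / (c^h + K^h)`.
#' @export
hill_activation <- function(c_uM, pump) {
  c_uM <- pmax(c_uM, 0)
  ch <- c_uM^pump$hill
  ch / (ch + pump$K_half^pump$hill)
}

#' Calcium extrusion flux of a membrane pump, per unit dendrite length
#'
#' Surface pump densities (1/um^2) convert to a per-length sink through
#' the dendrite perimeter `2 pi a`:
#' `flux = rate_per_pump * surface_density * perimeter * hill(c)`,
#' in particles/(um s). Pumps only remove calcium.
#'
#' @param u_ca Calcium linear density, particles/um (vector ok).
#' @param pump A `pump_spec`.
#' @param perimeter Dendrite perimeter, um.
#' @param cross_section Dendrite cross-section, um^2 (converts `u_ca`
#'   to concentration for the Hill term).
#' @return Extrusion flux, particles/(um s), same length as `u_ca`.
#' @export
pump_flux <- function(u_ca, pump, perimeter, cross_section) {
  stopifnot(inherits(pump, "pump_spec"), perimeter > 0)
  c_uM <- linear_density_to_concentration(pmax(u_ca, 0), cross_section)
  pump$rate_per_pump * pump$surface_density * perimeter *
    hill_activation(c_uM, pump)
}

#' Absorption rate of a passive dendritic spine
#'
#' The rate for a calcium ion in the compartment containing the spine to
#' find the neck opening is the inverse narrow-escape time,
#' `k = 1 / mfpt_escape_3d(V, neck_radius, D) = 4 neck_radius D / V`.
#'
#' @param neck_radius Spine neck radius, um.
#' @param compartment_volume Compartment volume, um^3.
#' @param D Calcium diffusion constant, um^2/s.
#' @param dendrite_radius Optional dendrite radius for the domain check.
#' @return Absorption rate, 1/s.
#' @export
spine_sink_rate <- function(neck_radius, compartment_volume, D,
                            dendrite_radius = NULL) {
  if (!is.null(dendrite_radius) && neck_radius >= dendrite_radius)
    stop("spine neck radius must be below the dendrite radius", call. = FALSE)
  1 / mfpt_escape_3d(compartment_volume, neck_radius, D)
}

#' Single-receptor NMDA current
#'
#' Dual-exponential pulse train; each pulse is normalized to peak at
#' `peak_current`.
#'
#' @param t Times, s (vector ok).
#' @param syn A `synapse_spec`.
#' @return Current in pA, zero before `t0`.
#' @export
nmda_current <- function(t, syn) {
  stopifnot(inherits(syn, "synapse_spec"))
  tr <- syn$tau_rise; td <- syn$tau_decay
  t_peak <- tr * td / (td - tr) * log(td / tr)
  norm <- exp(-t_peak / td) - exp(-t_peak / tr)
  amp <- syn$peak_current / norm
  out <- numeric(length(t))
  for (k in seq_len(syn$n_pulses)) {
    s <- t - syn$t0 - (k - 1) / syn$frequency
    on <- s > 0
    out[on] <- out[on] + amp * (exp(-s[on] / td) - exp(-s[on] / tr))
  }
  out
}

#' Calcium particle flux injected by the NMDA receptor, per unit length
#'
#' Converts the electrical current to an ion flux,
#' `q(t) = I(t) * ca_fraction / (2 e)`, and spreads it uniformly over
#' the receptor footprint `[position - r, position + r]`.
#'
#' @param t Time, s (scalar or vector).
#' @param syn A `synapse_spec`.
#' @param x Positions at which to evaluate the flux profile, um.
#' @return If `t` is scalar: flux profile over `x`, particles/(um s).
#'   Otherwise a matrix `length(t) x length(x)`.
#' @export
nmda_particle_flux <- function(t, syn, x) {
  q <- nmda_current(t, syn) * 1e-12 * syn$ca_fraction /
    (dendro_constants$ca_valence * dendro_constants$elementary_charge_C)
  foot <- as.numeric(abs(x - syn$position) <= syn$receptor_radius)
  width <- 2 * syn$receptor_radius
  if (length(t) == 1) q * foot / width else outer(q, foot / width)
}

## exact cumulative ion count injected by a pulse train up to time t
nmda_cumulative_ions <- function(t, syn) {
  tr <- syn$tau_rise; td <- syn$tau_decay
  t_peak <- tr * td / (td - tr) * log(td / tr)
  amp <- syn$peak_current / (exp(-t_peak / td) - exp(-t_peak / tr))
  scale <- amp * 1e-12 * syn$ca_fraction /
    (dendro_constants$ca_valence * dendro_constants$elementary_charge_C)
  total <- 0
  for (k in seq_len(syn$n_pulses)) {
    s <- t - syn$t0 - (k - 1) / syn$frequency
    if (s > 0)
      total <- total + scale *
        (td * (1 - exp(-s / td)) - tr * (1 - exp(-s / tr)))
  }
  total
}
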