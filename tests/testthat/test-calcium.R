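test_that("concentration <-> linear density conversion", {
  # 600 particles/um^3 volumetric density over S = 0.785 um^2
  dens_per_um3 <- 600
  c_uM <- dens_per_um3 / dendro_constants$particles_per_um3_per_uM
  expect_equal(concentration_to_linear_density(c_uM, 0.785),
               600 * 0.785, tolerance = 1e-12)   # ~470 particles per um
  expect_equal(600 * 0.785, 471, tolerance = 0.01)
  expect_equal(concentration_to_linear_density(0, 0.785), 0)
  # exact round trip
  u <- concentration_to_linear_density(1.37, pi * 0.5^2)
  expect_identical(linear_density_to_concentration(u, pi * 0.5^2), 1.37)
  expect_error(concentration_to_linear_density(-1, 0.785), "non-negative")
  # Table cross-section: pi (0.5)^2 = 0.785
  expect_equal(dendrite_cross_section(0.5), 0.785, tolerance = 1e-3)
})

test_that("buffer kinetics: conservation, equilibria, detailed balance", {
  S <- pi * 0.25
  conv <- dendro_constants$particles_per_um3_per_uM * S
  cn <- calcineurin_spec(10)
  # derivatives of all occupancy states sum to zero (conservation)
  u_ca <- c(100, 300)
  u_b <- matrix(c(200, 500), 2, 1)
  r <- buffer_rhs(u_ca, u_b, cn, S)
  expect_equal(r$du_ca + rowSums(r$du_b), c(0, 0))
  # zero calcium drives occupancy down
  r0 <- buffer_rhs(c(0, 0), u_b, cn, S)
  expect_true(all(r0$du_b < 0))
  # calcineurin equilibrium: bound/free = (kf/kb) [Ca] = 2 [Ca] per uM
  ca_uM <- 0.8
  u_ca_eq <- ca_uM * conv
  eqfun <- function(b) buffer_rhs(u_ca_eq, matrix(b, 1, 1), cn, S)$du_b[1, 1]
  b_eq <- uniroot(eqfun, c(0, 10 * conv))$root
  free_b <- 10 * conv - b_eq
  expect_equal(b_eq / free_b, (50 / 25) * ca_uM, tolerance = 1e-6)
})

test_that("equal-rate four-site ladder reaches its detailed-balance equilibrium", {
  S <- pi * 0.25
  conv <- dendro_constants$particles_per_um3_per_uM * S
  eq_buf <- buffer_spec("equal4", k_forward = rep(100, 4),
                        k_backward = rep(50, 4), total_concentration = 20)
  ca_uM <- 0.6
  # closed form: occupancy j proportional to r^j with r = (kf/kb) [Ca]
  r_ratio <- (100 / 50) * ca_uM
  w <- r_ratio^(0:4); w <- w / sum(w)
  # long-time ODE integration at clamped calcium
  rhs <- function(t, y, p) {
    d <- buffer_rhs(ca_uM * conv, matrix(y, 1, 4), eq_buf, S)
    list(as.vector(d$du_b))
  }
  out <- deSolve::ode(rep(0, 4), c(0, 50), rhs, NULL, rtol = 1e-10,
                      atol = 1e-10)
  states <- out[2, -1]
  tot <- 20 * conv
  got <- unname(c(tot - sum(states), states) / tot)
  expect_equal(got, w, tolerance = 1e-6)
})

test_that("pump flux: Hill midpoint, saturation, NCX exponent", {
  S <- pi * 0.25; per <- 2 * pi * 0.5
  conv <- dendro_constants$particles_per_um3_per_uM * S
  pm <- pmca_spec()
  sat <- pm$rate_per_pump * pm$surface_density * per
  # [Ca] = K_half, hill 1 -> exactly half the saturated flux
  expect_equal(pump_flux(pm$K_half * conv, pm, per, S), sat / 2)
  expect_equal(pump_flux(0, pm, per, S), 0)
  # saturation at high calcium
  expect_equal(pump_flux(1e6 * conv, pm, per, S), sat, tolerance = 1e-3)
  # NCX hill 1.7: flux ratio at 2 K vs K
  nc <- ncx_spec()
  expect_equal(nc$hill, 1.7)
  ratio <- pump_flux(2 * nc$K_half * conv, nc, per, S) /
    pump_flux(nc$K_half * conv, nc, per, S)
  expect_equal(ratio, (2^1.7 / (1 + 2^1.7)) / (1 / 2), tolerance = 1e-9)
})

test_that("spine sink rate is the inverse narrow-escape time", {
  V <- 0.348; D <- 20
  expect_equal(spine_sink_rate(0.1, V, D), 1 / mfpt_escape_3d(V, 0.1, D))
  expect_equal(spine_sink_rate(0.2, V, D), 2 * spine_sink_rate(0.1, V, D))
  expect_error(spine_sink_rate(0.6, V, D, dendrite_radius = 0.5), "below")
})

test_that("NMDA input: gating, peak timing, charge-to-ion bookkeeping", {
  syn <- synapse_spec(position = 10, frequency = 10, n_pulses = 3, t0 = 0.05)
  expect_equal(nmda_current(c(0, 0.01, 0.049), syn), c(0, 0, 0))
  # single pulse time-to-peak: tr td/(td-tr) ln(td/tr) ~ 10.2 ms
  syn1 <- synapse_spec(position = 10, frequency = 1, n_pulses = 1)
  tt <- seq(0, 0.08, 1e-5)
  tpk <- tt[which.max(nmda_current(tt, syn1))]
  t_theory <- 0.003 * 0.08 / (0.08 - 0.003) * log(0.08 / 0.003)
  expect_equal(t_theory, 0.0102, tolerance = 0.01)
  expect_equal(tpk, t_theory, tolerance = 1e-3)
  # peak normalized to 9 pA (max over a 1e-5 s grid)
  expect_equal(max(nmda_current(tt, syn1)), 9, tolerance = 1e-6)
  # integrated ions over one pulse = f * int I dt / (2 e)
  q_num <- sum(nmda_current(tt, syn1)) * 1e-5 * 1e-12 * syn1$ca_fraction /
    (2 * dendro_constants$elementary_charge_C)
  ions <- dendrocrowd:::nmda_cumulative_ions(0.08, syn1)
  expect_equal(ions, q_num, tolerance = 1e-3)
  # footprint: rectangle of half-width receptor_radius
  x <- seq(9.9, 10.1, by = 0.005)
  prof <- nmda_particle_flux(t_theory, syn1, x)
  expect_true(all(prof[abs(x - 10) > 0.025] == 0))
  expect_true(all(prof[abs(x - 10) < 0.02] > 0))
  expect_error(synapse_spec(10, 10, n_pulses = 100, train_duration = 1),
               "inconsistent")
  expect_error(synapse_spec(10, 10, tau_rise_ms = 90), "smaller")
})

test_that("pure-diffusion system matches the reduced solver", {
  sys <- quick_system(D_ca = 20, buffers = list(), dye = NULL,
                      pumps = list(),
                      initial_pulse = list(amplitude_uM = 1, center = 5,
                                           width = 0.5))
  traj <- assemble_and_solve(sys, 0.005, times = seq(0, 0.005, 5e-4))
  ref <- solve_reduced_1d(
    function(x) concentration_to_linear_density(1, sys$S) *
      exp(-(x - 5)^2 / (2 * 0.5^2)),
    seq(0, 0.005, 5e-4), D_eff = 20, L_domain = 10, dx = 0.1)
  expect_equal(traj$u_ca[11, ], ref$values[11, ], tolerance = 0.001)
  # conservation in the closed system
  b <- calcium_budget(traj)
  expect_lt(max(b$rel_error), 1e-6)
})

test_that("buffered equilibria match closed-form mass action", {
  sys <- quick_system(D_ca = 20, pumps = list(),
                      buffers = list(calcineurin_spec(10)),
                      dye = NULL, resting_ca = 0.5)
  traj <- assemble_and_solve(sys, 2, times = c(0, 1, 2))
  conv <- dendro_constants$particles_per_um3_per_uM * sys$S
  # uniform start: solve scalar equilibrium  b/(B-b) = 2 c_free
  tot_ca <- 0.5; tot_b <- 10
  eq <- uniroot(function(cf) (tot_ca - cf) / 1 -
                  tot_b * 2 * cf / (1 + 2 * cf) / 1,
                c(1e-9, tot_ca))$root
  cf_num <- linear_density_to_concentration(traj$u_ca[3, 50], sys$S)
  expect_equal(cf_num, eq, tolerance = 1e-4)
  # buffer occupancy sums constant at every node and time
  arr <- traj$buffers[[1]]
  expect_lt(max(abs(arr[3, , 1] - (tot_ca - eq) * conv)) /
              max(arr[3, , 1]), 1e-3)
})

test_that("calcium budget closes with pumps, spines and synaptic input on", {
  sys <- quick_system(
    D_ca = 20,
    buffers = list(calmodulin_spec(), calcineurin_spec()),
    spines = spine_sink_spec(neck_radius = 0.1, density = 1),
    synapses = list(synapse_spec(position = 5, frequency = 20,
                                 train_duration = 0.2)))
  traj <- assemble_and_solve(sys, 0.2, times = seq(0, 0.2, 1e-4))
  b <- calcium_budget(traj)
  expect_lt(max(b$rel_error), 1e-4)
  # positivity preserved
  expect_gte(min(traj$u_ca), -1e-6 * max(traj$u_ca))
  # absorbed and pumped masses are increasing
  expect_true(all(diff(b$pumped) >= 0))
  expect_true(all(diff(b$spine_absorbed) >= 0))
})

test_that("spread measurement: Gaussian FWHM, amplitude invariance", {
  sys <- quick_system(D_ca = 20, buffers = list(), dye = NULL,
                      pumps = list(),
                      initial_pulse = list(amplitude_uM = 1, center = 5,
                                           width = 0.6))
  traj <- assemble_and_solve(sys, 0.001, times = c(0, 1e-3))
  sp <- measure_spread(traj)
  expect_equal(sp$fwhm_um[1], 2.3548 * 0.6, tolerance = 0.02)
  expect_false(any(sp$multimodal))
  # amplitude scaling leaves the width untouched
  sys2 <- quick_system(D_ca = 20, buffers = list(), dye = NULL,
                       pumps = list(),
                       initial_pulse = list(amplitude_uM = 7, center = 5,
                                            width = 0.6))
  sp2 <- measure_spread(assemble_and_solve(sys2, 0.001, times = c(0, 1e-3)))
  expect_equal(sp2$fwhm_um[1], sp$fwhm_um[1], tolerance = 1e-6)
})

test_that("crowding localizes and prolongs the buffered transient", {
  mk <- function(D) quick_system(
    D_ca = D, initial_pulse = list(amplitude_uM = 1, center = 5, width = 0.5))
  times <- seq(0, 0.01, 5e-4)
  aq <- assemble_and_solve(mk(400), 0.01, times = times)
  cr <- assemble_and_solve(mk(20), 0.01, times = times)
  sp_aq <- measure_spread(aq); sp_cr <- measure_spread(cr)
  k <- length(times)
  # crowded transient is more localized at matched times...
  expect_lt(sp_cr$fwhm_um[k], sp_aq$fwhm_um[k])
  # ...and longer-lasting at the origin
  mid <- which.min(abs(aq$x - 5))
  expect_gt(cr$u_ca[k, mid], aq$u_ca[k, mid])
  # crowded peak at origin never below aqueous peak (slower dilution)
  expect_true(all(cr$u_ca[, mid] >= aq$u_ca[, mid] - 1e-9))
})

test_that("buffers accelerate the decay of the free-calcium transient", {
  times <- seq(0, 0.01, 5e-4)
  bare <- assemble_and_solve(
    quick_system(D_ca = 20, buffers = list(), dye = NULL, pumps = list(),
                 initial_pulse = list(amplitude_uM = 1, center = 5,
                                      width = 0.5)),
    0.01, times = times)
  buff <- assemble_and_solve(
    quick_system(D_ca = 20,
                 initial_pulse = list(amplitude_uM = 1, center = 5,
                                      width = 0.5)),
    0.01, times = times)
  mid <- which.min(abs(bare$x - 5))
  t10 <- function(traj) {
    v <- traj$u_ca[, mid]
    k <- which(v <= 0.1 * v[1])
    if (length(k) == 0) Inf else times[k[1]]
  }
  expect_lt(t10(buff), t10(bare))
})

test_that("grid refinement leaves the measured spread nearly unchanged", {
  mk <- function(dx) reaction_system_spec(
    L_dend = 10, dx = dx, D_ca = 20,
    spines = spine_sink_spec(neck_radius = 0.1, density = 1),
    synapses = list(synapse_spec(position = 5, frequency = 50,
                                 train_duration = 0.15)))
  times <- seq(0, 0.15, 5e-3)
  s1 <- measure_spread(assemble_and_solve(mk(0.1), 0.15, times = times))
  s2 <- measure_spread(assemble_and_solve(mk(0.05), 0.15, times = times))
  expect_equal(max(s1$spread_um, na.rm = TRUE),
               max(s2$spread_um, na.rm = TRUE), tolerance = 0.02)
})
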