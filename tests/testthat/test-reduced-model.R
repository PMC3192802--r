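test_that("3D small-hole MFPT has the exact scalings and magnitude", {
  # linear in volume, inverse in eps and D
  tau <- mfpt_escape_3d(0.246, 0.0313, 400)
  expect_equal(mfpt_escape_3d(0.246, 0.0313, 800), tau / 2)
  expect_equal(mfpt_escape_3d(0.246, 2 * 0.0313, 400), tau / 2)
  expect_equal(mfpt_escape_3d(2 * 0.246, 0.0313, 400), 2 * tau)
  # magnitude for the compartment of the worked example
  expect_equal(tau, 4.9e-3, tolerance = 0.01)
  expect_error(mfpt_escape_3d(-1, 0.03, 400), "positive")
  expect_error(mfpt_escape_3d(0.2, 0.03, 0), "positive")
})

test_that("3D small-hole MFPT agrees with a brute-force Brownian estimate", {
  spec <- calib_spec()
  scene <- build_scene(radius = spec$a, length = spec$L,
                       caps = c("reflecting", "absorbing_hole"),
                       cap_holes = c(0, spec$eps))
  m <- estimate_mfpt(scene, 4000, spec$D, sim_config(rng_seed = 101))
  pred <- mfpt_escape_3d(spec$S * spec$L, spec$eps, spec$D)
  expect_equal(m$censored_fraction, 0)
  expect_lt(abs(pred - m$mean) / m$mean, 0.06)
})

test_that("2D small-hole MFPT: monotonicity, diffusive scaling, MC oracle", {
  expect_gt(mfpt_escape_2d(1, 0.01, 1), mfpt_escape_2d(1, 0.05, 1))
  expect_equal(mfpt_escape_2d(1, 0.05, 0.5), 2 * mfpt_escape_2d(1, 0.05, 1))
  expect_error(mfpt_escape_2d(1, 1.2, 1), "strictly between")
  expect_error(mfpt_escape_2d(1, 0, 1), "strictly between")
  # frozen value from an independent walk-on-disk Monte-Carlo
  # (unit disk, absorbing arc fraction 0.05, D = 1, uniform start,
  # 4000 walkers, Euler dt = 5e-6, sem ~ 0.045)
  mc_mean <- 2.745
  expect_lt(abs(mfpt_escape_2d(pi, 0.05, 1) - mc_mean) / mc_mean, 0.10)
})

test_that("compartment parameter: identity, rescaling invariance, limits", {
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, 0.2, 1)
    L <- runif(1, 0.2, 1)
    eps <- runif(1, 0.2, 1) * 0.15 * L
    eps <- min(eps, 0.9 * a)
    D <- runif(1, 10, 500)
    spec <- compartment_spec(L, eps, a, D)
    # D_eff = kappa * D exactly
    expect_identical(effective_diffusion_constant(spec),
                     compartment_parameter(spec) * D)
    expect_lt(effective_diffusion_constant(spec), D)
    # invariance under (eps, L) -> (eps/c, cL)
    c_ <- runif(1, 1, 1.4)
    spec2 <- compartment_spec(L * c_, eps / c_, a, D)
    expect_equal(compartment_parameter(spec2), compartment_parameter(spec))
  }
  # monotone increasing in eps and L at fixed a
  s0 <- compartment_spec(0.4, 0.03, 0.5, 400)
  expect_gt(compartment_parameter(compartment_spec(0.4, 0.04, 0.5, 400)),
            compartment_parameter(s0))
  expect_gt(compartment_parameter(compartment_spec(0.5, 0.03, 0.5, 400)),
            compartment_parameter(s0))
  # sealed limit
  expect_lt(compartment_parameter(compartment_spec(0.4, 1e-9, 0.5, 400)),
            1e-6)
})

test_that("geometry calibration round-trips and rejects infeasible targets", {
  spec <- calibrate_geometry(0.05, a = 0.5)
  expect_equal(compartment_parameter(spec), 0.05)
  expect_equal(effective_diffusion_constant(spec) / spec$D, 0.05)
  expect_equal(spec$eps / spec$L, 0.025)
  expect_lt(spec$eps, spec$a)
  expect_error(calibrate_geometry(1, a = 0.5), "strictly between")
  expect_error(calibrate_geometry(0.9999, a = 0.05), "infeasible")
  # other targets round-trip too
  for (tr in c(0.02, 0.1, 0.2)) {
    s <- calibrate_geometry(tr, a = 0.5)
    expect_equal(compartment_parameter(s), tr)
  }
})

test_that("spec invariants are enforced", {
  expect_error(compartment_spec(0.3, 0.6, 0.5, 400), "smaller than")
  expect_error(compartment_spec(0.3, 0.06, 0.5, 400), "validity")
  expect_warning(compartment_spec(0.3, 0.06, 0.5, 400, on_invalid = "warn"),
                 "validity")
  expect_error(compartment_spec(-1, 0.03, 0.5, 400), "positive")
})

test_that("drift/diffusion coefficients: homogeneous and graded profiles", {
  spec <- calib_spec()
  # constant eps: drift identically zero, b = D_eff
  prof <- inhomogeneous_profile(
    eps_of_x = function(x) rep(spec$eps, length(x)),
    V_of_x = function(x) rep(spec$S * spec$L, length(x)),
    L_dend = 10)
  cf <- drift_and_diffusion_coefficients(prof, spec)
  xs <- seq(0.5, 9.5, length.out = 21)
  expect_equal(max(abs(cf$a_of_x(xs))), 0, tolerance = 1e-8)
  expect_equal(cf$b_of_x(xs), rep(effective_diffusion_constant(spec), 21))
  # linearly increasing eps: drift positive; decreasing: negative
  prof_up <- inhomogeneous_profile(
    eps_of_x = function(x) spec$eps * (1 + 0.05 * x),
    V_of_x = function(x) rep(spec$S * spec$L, length(x)),
    L_dend = 10)
  cf_up <- drift_and_diffusion_coefficients(prof_up, spec)
  expect_true(all(cf_up$a_of_x(xs) > 0))
  prof_dn <- inhomogeneous_profile(
    eps_of_x = function(x) spec$eps * (1.6 - 0.05 * x),
    V_of_x = function(x) rep(spec$S * spec$L, length(x)),
    L_dend = 10)
  expect_true(all(drift_and_diffusion_coefficients(prof_dn, spec)$a_of_x(xs) < 0))
})

test_that("graded opening profile biases transport toward larger openings", {
  # 1D SDE ensemble under (a, b) from a linear eps(x) drifts the same
  # way as the sign of eps'
  spec <- calib_spec()
  prof <- inhomogeneous_profile(
    eps_of_x = function(x) spec$eps * (1 + 0.08 * x),
    V_of_x = function(x) rep(spec$S * spec$L, length(x)),
    L_dend = 20)
  cf <- drift_and_diffusion_coefficients(prof, spec)
  set.seed(5)
  n <- 4000
  x <- rep(10, n)
  dt <- 1e-4
  for (s in 1:1000) {
    x <- x + cf$a_of_x(x) * dt + sqrt(2 * cf$b_of_x(x) * dt) * rnorm(n)
    x <- pmin(pmax(x, 0), 20)
  }
  # expected mean displacement <b'> t ~ +0.15 um over 0.1 s
  expect_gt(mean(x), 10.06)  # drifts toward larger openings
})

test_that("travel times to and from the soma", {
  expect_equal(mfpt_to_soma(0, 100, 20), 0)
  expect_equal(mfpt_to_soma(100, 100, 20), 250)   # ~4.2 min from the tip
  # monotone increasing in x, quadratic form
  xs <- seq(0, 100, by = 10)
  expect_true(all(diff(mfpt_to_soma(xs, 100, 20)) > 0))
  # mirror symmetry with the outward problem
  for (x in c(0, 17, 42, 100))
    expect_equal(mfpt_to_soma(x, 100, 20), mfpt_from_soma(100 - x, 100, 20))
  expect_error(mfpt_to_soma(120, 100, 20), "inside")
  # constant-V quadrature agrees with the closed form
  for (x in c(12, 57, 100))
    expect_equal(mfpt_to_soma_quadrature(x, 100, 20), mfpt_to_soma(x, 100, 20),
                 tolerance = 1e-9)
})
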