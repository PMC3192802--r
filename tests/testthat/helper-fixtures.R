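## Shared helpers: small calibrated geometries and quick solver settings
## used across the unit tests.

calib_spec <- function(D = 400) calibrate_geometry(0.05, a = 0.5, D = D)

gaussian_ic <- function(center, sd) {
  force(center); force(sd)
  function(x) exp(-(x - center)^2 / (2 * sd^2))
}

## moments of a profile on a grid
profile_moments <- function(x, v) {
  m0 <- sum(v)
  mu <- sum(x * v) / m0
  list(m0 = m0, mean = mu, var = sum((x - mu)^2 * v) / m0)
}

quick_system <- function(...) {
  reaction_system_spec(L_dend = 10, dx = 0.1, ...)
}
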