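#' Simulation configuration for the Brownian ray tracer
#'
#' @param base_step Maximum Euler step, s (default 5e-6).
#' @param adaptive_min_fraction Fraction of the smallest resolvable
#'   length scale used as the minimum step length (default 0.4, within
#'   the 0.3-0.5 band appropriate for narrow openings).
#' @param sampling_period Sampling tick, s (default 7e-4, the 0.7 ms
#'   line-scan period).
#' @param rng_seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param min_scale_fraction Fraction of the smallest geometric feature
#'   used as the floor of the adaptive step length near absorbing
#'   elements and opening edges (default 0.1; smaller is more accurate
#'   and slower).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(base_step = 5e-6, adaptive_min_fraction = 0.4,
                       sampling_period = 7e-4, rng_seed = NULL,
                       min_scale_fraction = 0.1) {
  if (adaptive_min_fraction < 0.3 || adaptive_min_fraction > 0.5)
    stop("adaptive_min_fraction must lie in [0.3, 0.5]", call. = FALSE)
  stopifnot(base_step > 0, sampling_period > 0)
  stopifnot(min_scale_fraction > 0, min_scale_fraction <= 0.5)
  structure(list(base_step = base_step,
                 adaptive_min_fraction = adaptive_min_fraction,
                 sampling_period = sampling_period, rng_seed = rng_seed,
                 min_scale_fraction = min_scale_fraction),
            class = "sim_config")
}

#' Initial particle positions, uniform in the cylinder
#'
#' @param n Number of particles.
#' @param scene A `bd_scene`.
#' @param x_range Optional axial sub-range `c(xmin, xmax)`.
#' @return An `n x 3` matrix of positions (um).
#' @export
init_uniform_cylinder <- function(n, scene, x_range = NULL) {
  stopifnot(inherits(scene, "bd_scene"))
  if (is.null(x_range)) x_range <- c(0, scene$length)
  x <- stats::runif(n, x_range[1], x_range[2])
  r <- scene$radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = x, y = r * cos(th), z = r * sin(th))
}

#' Initial positions emulating an uncaging spot
#'
#' Gaussian axial profile (the laser spot), radially homogeneous.
#'
#' @param n Number of particles.
#' @param scene A `bd_scene`.
#' @param center Axial spot center, um.
#' @param width Gaussian standard deviation, um (default 0.5, a ~1 um
#'   spot).
#' @return An `n x 3` position matrix.
#' @export
init_uncaging_spot <- function(n, scene, center, width = 0.5) {
  stopifnot(inherits(scene, "bd_scene"))
  x <- stats::rnorm(n, center, width)
  x <- pmin(pmax(x, 1e-6), scene$length - 1e-6)
  r <- scene$radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = x, y = r * cos(th), z = r * sin(th))
}

#' Run the 3D Brownian simulation
#'
#' Advances an ensemble of independent Brownian particles through the
#' scene with specular ray-traced reflections and adaptive Euler steps;
#' per-particle physical clocks are reconciled at every sampling tick,
#' where concentrations in the sampling volumes (and axial moments) are
#' recorded.
#'
#' @param scene A `bd_scene` from [build_scene()].
#' @param positions Initial `n x 3` position matrix (um); see
#'   [init_uniform_cylinder()] / [init_uncaging_spot()].
#' @param D Diffusion constant, um^2/s (`0` freezes all particles).
#' @param duration Simulated time, s.
#' @param config A [sim_config()].
#' @param volumes Sampling volume matrix from [sampling_volumes()] (may
#'   be empty).
#' @param record_x Keep per-particle axial positions at every tick
#'   (needed for MSD bootstrap; memory `n_ticks x n`).
#' @return An object of class `bd_result` with fields `times`, `counts`,
#'   `volumes`, `sum_x`, `sum_x2`, `n_active`, `n_inspine`, `status`,
#'   `absorption_times`, `final_positions`, `xs` (if recorded),
#'   `leak_reverts` and the inputs `scene`, `config`, `D`, `n`.
#' @export
simulate_ensemble <- function(scene, positions, D, duration,
                              config = sim_config(), volumes = NULL,
                              record_x = TRUE) {
  stopifnot(inherits(scene, "bd_scene"), inherits(config, "sim_config"))
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be n x 3", call. = FALSE)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  times <- seq(0, duration, by = config$sampling_period)
  if (is.null(volumes)) volumes <- matrix(numeric(0), 0, 2)
  res <- bd_run(positions, unclass(scene), D, config$base_step,
                config$adaptive_min_fraction, times, as.matrix(volumes),
                TRUE, record_x, config$min_scale_fraction %||% 0.1)
  structure(c(res, list(times = times, volumes = volumes, scene = scene,
                        config = config, D = D, n = nrow(positions))),
            class = "bd_result")
}

#' @export
print.bd_result <- function(x, ...) {
  cat(sprintf("Brownian run: %d particles, %d ticks (%.4g s), D = %.4g um^2/s\n",
              x$n, length(x$times), max(x$times), x$D))
  cat(sprintf("  absorbed: %d; leak-guard reverts: %d\n",
              sum(x$status == 1), x$leak_reverts))
  invisible(x)
}

#' Convert sampling-volume counts to a line-scan record
#'
#' Counts per volume per tick, normalized per the line-scan convention:
#' for each location the earliest frame with a nonzero count is scaled
#' to 1 (locations whose first frame is empty are flagged and normalized
#' to their first nonzero frame). Raw counts are always retained in the
#' metadata.
#'
#' @param result A `bd_result` with at least one sampling volume.
#' @param normalize Apply the per-location convention (default `TRUE`).
#' @return A [linescan_record()].
#' @export
record_linescan <- function(result, normalize = TRUE) {
  stopifnot(inherits(result, "bd_result"))
  counts <- result$counts
  if (is.null(dim(counts)) || ncol(counts) == 0)
    stop("the run had no sampling volumes", call. = FALSE)
  centers <- attr(result$volumes, "centers")
  if (is.null(centers)) centers <- rowMeans(result$volumes)
  vals <- counts * 1.0
  deferred <- logical(ncol(vals))
  if (normalize) {
    for (j in seq_len(ncol(vals))) {
      nz <- which(counts[, j] > 0)
      if (length(nz) == 0) next
      if (nz[1] != 1) deferred[j] <- TRUE
      vals[, j] <- vals[, j] / counts[nz[1], j]
    }
  }
  linescan_record(result$times, centers, vals,
                  meta = list(dt = result$config$sampling_period,
                              normalization = if (normalize)
                                "per-location first nonzero frame = 1" else "none",
                              deferred_normalization = any(deferred),
                              raw_counts = counts,
                              n_particles = result$n, D_input = result$D))
}

#' First-passage times of walkers from given start positions
#'
#' Lower-level companion of [estimate_mfpt()]: runs each walker from its
#' supplied start position until it hits any absorbing element of the
#' scene (or the censoring cap).
#'
#' @param scene A `bd_scene` with at least one absorbing element.
#' @param positions Initial `n x 3` positions, um.
#' @param D Diffusion constant, um^2/s.
#' @param config A [sim_config()].
#' @param t_cap Censoring cap, s.
#' @return List with `times` (s, `NA` when censored) and `censored`.
#' @export
bd_mfpt_times <- function(scene, positions, D, config = sim_config(),
                          t_cap) {
  stopifnot(inherits(scene, "bd_scene"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  res <- bd_mfpt(as.matrix(positions), unclass(scene), D, config$base_step,
                 config$adaptive_min_fraction, t_cap,
                 config$min_scale_fraction %||% 0.1)
  list(times = res$times, censored = res$censored,
       leak_reverts = res$leak_reverts)
}

#' Estimate the mean first passage time of escape by simulation
#'
#' Releases walkers uniformly in the scene and times their first arrival
#' at the absorbing element (e.g. a cap with an absorbing axial hole).
#' Walkers still active at the censoring cap are reported separately.
#'
#' @param scene A `bd_scene` with exactly one absorbing element.
#' @param n_walkers Number of walkers (>= 1000 recommended).
#' @param D Diffusion constant, um^2/s.
#' @param config A [sim_config()].
#' @param t_cap Censoring cap, s; default 50x the small-hole prediction
#'   when available, else `50 * L^2 / D`.
#' @return List with `mean` (s), `sem` (s), `n_escaped`,
#'   `censored_fraction`, `times`.
#' @export
estimate_mfpt <- function(scene, n_walkers, D, config = sim_config(),
                          t_cap = NULL) {
  stopifnot(inherits(scene, "bd_scene"))
  n_abs <- sum(scene$caps != "reflecting") +
    sum(if (!is.null(scene$spine)) isTRUE(scene$spine$head_absorbing) else 0)
  if (n_abs != 1)
    stop("the scene must have exactly one absorbing element", call. = FALSE)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  if (is.null(t_cap)) {
    hole <- scene$cap_holes[scene$caps == "absorbing_hole"]
    t_cap <- if (length(hole) == 1 && hole > 0) {
      V <- pi * scene$radius^2 * scene$length
      50 * mfpt_escape_3d(V, hole, D)
    } else 50 * scene$length^2 / D
  }
  pos <- init_uniform_cylinder(n_walkers, scene)
  res <- bd_mfpt(pos, unclass(scene), D, config$base_step,
                 config$adaptive_min_fraction, t_cap,
                 config$min_scale_fraction %||% 0.1)
  esc <- res$times[!res$censored]
  out <- list(mean = mean(esc), sem = stats::sd(esc) / sqrt(length(esc)),
              n_escaped = length(esc),
              censored_fraction = mean(res$censored), times = res$times,
              t_cap = t_cap)
  if (out$censored_fraction > 0) out$mean_flag <- "censored"
  out
}

#' Estimate the apparent diffusion constant from a Brownian run
#'
#' Two estimators of the long-time apparent 1D diffusion constant:
#' `"msd"` regresses the growth of the axial position variance
#' (`var(x) = 2 D t + const`) over the later part of the run, with a
#' particle-resampling bootstrap CI; `"fit1d"` least-squares matches the
#' recorded line scan to the reduced 1D diffusion equation with `D` as
#' the only free parameter (see [fit_diffusion_constant()]).
#'
#' @param result A `bd_result` (with `record_x = TRUE` for `"msd"`).
#' @param model `"msd"` or `"fit1d"`.
#' @param fit_window Fraction of the run (from the end) used for the MSD
#'   regression, default 0.6.
#' @param n_boot Bootstrap replicates (default 200 for msd, 50 for
#'   fit1d).
#' @param ... For `"fit1d"`: further arguments to
#'   [fit_diffusion_constant()].
#' @return List with `D_app` (um^2/s), `ci` (95% interval), `model`.
#' @export
estimate_apparent_D <- function(result, model = c("msd", "fit1d"),
                                fit_window = 0.6, n_boot = NULL, ...) {
  stopifnot(inherits(result, "bd_result"))
  model <- match.arg(model)
  if (model == "msd") {
    xs <- result$xs
    if (is.null(xs) || length(xs) == 0)
      stop("msd estimator needs record_x = TRUE", call. = FALSE)
    if (is.null(n_boot)) n_boot <- 200
    t <- result$times
    keep <- t >= (1 - fit_window) * max(t)
    slope_of <- function(idx) {
      v <- apply(xs[keep, idx, drop = FALSE], 1, stats::var, na.rm = TRUE)
      unname(stats::coef(stats::lm(v ~ t[keep]))[2])
    }
    n <- ncol(xs)
    D_app <- slope_of(seq_len(n)) / 2
    boots <- vapply(seq_len(n_boot), function(b)
      slope_of(sample.int(n, n, replace = TRUE)) / 2, numeric(1))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    list(D_app = D_app, ci = ci, model = "msd", boot = boots)
  } else {
    if (is.null(n_boot)) n_boot <- 50
    rec <- record_linescan(result, normalize = FALSE)
    fit <- fit_diffusion_constant(rec, n_boot = 0,
                                  L_domain = result$scene$length,
                                  x_origin = 0, ...)
    ci <- c(NA_real_, NA_real_)
    boots <- numeric(0)
    if (n_boot > 0 && !is.null(result$xs) && length(result$xs) > 0) {
      ## particle-level bootstrap: captures the full Monte-Carlo
      ## variability (particles are correlated across frames)
      vols <- result$volumes
      nv <- nrow(vols); nt <- nrow(result$xs); n <- ncol(result$xs)
      edges <- cummax(as.vector(t(vols)))      # xmin1 xmax1 xmin2 ...
                                               # (cummax absorbs fp jitter
                                               # between contiguous volumes)
      vi <- matrix(findInterval(result$xs, edges), nt, n)
      vi[is.na(result$xs)] <- 0L
      vi_vol <- matrix(0L, nt, n)
      odd <- vi %% 2L == 1L                    # odd interval = inside a volume
      vi_vol[odd] <- (vi[odd] + 1L) %/% 2L
      boots <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        cb <- t(vapply(seq_len(nt), function(k)
          tabulate(vi_vol[k, idx], nbins = nv), integer(nv)))
        rec_b <- linescan_record(result$times, rec$position_um, cb * 1.0,
                                 meta = list(dt = rec$meta$dt,
                                             raw_counts = cb))
        fit_diffusion_constant(rec_b, n_boot = 0,
                               D_range = fit$D_hat * c(1 / 3, 3),
                               L_domain = result$scene$length,
                               x_origin = 0, ...)$D_hat
      }, numeric(1))
      q <- unname(stats::quantile(boots, c(0.975, 0.025)))
      ci <- sort(2 * fit$D_hat - q)
    }
    list(D_app = fit$D_hat, ci = ci, model = "fit1d", fit = fit,
         boot = boots)
  }
}

#' Exact survival and concentration series for the absorbing cylinder
#'
#' Eigenfunction-series solution of 1D diffusion on `[0, L]` with both
#' ends absorbing and a uniform initial condition: survival fraction
#' `S(t) = sum_{m odd} (8 / m^2 pi^2) exp(-m^2 pi^2 D t / L^2)` and
#' local concentration
#' `c(x, t) = sum_{m odd} (4 / m pi) sin(m pi x / L) exp(-...)`.
#'
#' @param t Times, s.
#' @param L Cylinder length, um.
#' @param D Diffusion constant, um^2/s.
#' @param x Optional position for the local concentration (um).
#' @param n_terms Number of series terms (default 101, i.e. >= 50 odd
#'   modes).
#' @return Vector of survival fractions, or local concentrations if `x`
#'   is given.
#' @export
absorbing_cylinder_series <- function(t, L, D, x = NULL, n_terms = 101) {
  m <- seq(1, n_terms, by = 2)
  lam <- outer(t, m^2 * pi^2 * D / L^2)   # nt x nm
  if (is.null(x)) {
    as.vector(exp(-lam) %*% (8 / (m^2 * pi^2)))
  } else {
    as.vector(exp(-lam) %*% ((4 / (m * pi)) * sin(m * pi * x / L)))
  }
}

#' Validation report: Brownian simulator vs exact absorbing-cylinder series
#'
#' Runs a bare cylinder with both caps absorbing, a uniform initial
#' condition, and compares (i) the simulated global survival fraction
#' and (ii) the normalized concentration in a central sampling volume
#' against the exact eigenfunction series. Always returns a report;
#' `pass` reflects the configured tolerances.
#'
#' @param n_particles Number of particles (default 10000).
#' @param radius,length Cylinder geometry, um.
#' @param D Diffusion constant, um^2/s.
#' @param duration Simulated time, s; default spans ~2 decay times.
#' @param config A [sim_config()].
#' @param tol_survival Sup-norm tolerance on the survival curve
#'   (default 0.02).
#' @param tol_local Sup-norm tolerance on the normalized local
#'   concentration (default 0.15; the local curve is normalized to a
#'   few hundred counts in one sampling volume, so its late-time noise
#'   is an order of magnitude larger than the survival curve's).
#' @return List with curves, sup-norm errors and `pass`.
#' @export
validate_absorbing_cylinder <- function(n_particles = 10000, radius = 0.5,
                                        length = 5, D = 400,
                                        duration = NULL,
                                        config = sim_config(),
                                        tol_survival = 0.02,
                                        tol_local = 0.15) {
  if (is.null(duration)) duration <- 2 * length^2 / (pi^2 * D)
  scene <- build_scene(radius = radius, length = length,
                       caps = c("absorbing", "absorbing"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  pos <- init_uniform_cylinder(n_particles, scene)
  vols <- sampling_volumes(length / 2, height = length / 10, scene = scene)
  res <- simulate_ensemble(scene, pos, D, duration, config, vols,
                           record_x = FALSE)
  t <- res$times
  surv_sim <- res$n_active / n_particles
  surv_exact <- absorbing_cylinder_series(t, length, D)
  err_surv <- max(abs(surv_sim - surv_exact))
  local_sim <- res$counts[, 1] / res$counts[1, 1]
  local_exact <- absorbing_cylinder_series(t, length, D, x = length / 2) /
    absorbing_cylinder_series(0, length, D, x = length / 2)
  err_local <- max(abs(local_sim - local_exact))
  list(times = t, survival_sim = surv_sim, survival_exact = surv_exact,
       local_sim = local_sim, local_exact = local_exact,
       sup_error_survival = err_surv, sup_error_local = err_local,
       pass = err_surv <= tol_survival && err_local <= tol_local,
       tolerances = c(survival = tol_survival, local = tol_local))
}
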