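#' Build a 3D simulation scene: cylinder, barrier disks, optional spine
#'
#' The simulation domain is a cylinder of radius `radius` along
#' `x in [0, length]`, with reflecting or absorbing end caps, transverse
#' barrier disks pierced by a single circular opening, and an optional
#' dendritic spine (neck cylinder plus tangent head sphere) attached to
#' the lateral wall. All surfaces are analytic; ray intersections are
#' exact.
#'
#' @param radius Cylinder radius, um.
#' @param length Cylinder length, um.
#' @param barrier_x Axial positions of barrier disks, um (strictly inside
#'   `(0, length)`).
#' @param hole_r Opening radius per barrier (recycled), um, `< radius`.
#' @param hole_center `"axis"` (default) or `"random"`: openings centered
#'   on the axis or placed uniformly at random within the cross-section
#'   (requires the current RNG state; seed for reproducibility).
#' @param caps Length-2 character vector for the `x = 0` and `x = length`
#'   caps: `"reflecting"`, `"absorbing"`, or `"absorbing_hole"` (cap
#'   reflects except an absorbing axial disk of radius `cap_holes`).
#' @param cap_holes Length-2 numeric, absorbing hole radius per cap (only
#'   used with `"absorbing_hole"`).
#' @param spine Optional list with `attach_position` (um), `neck_radius`,
#'   `neck_length`, `head_radius` (um) and optionally `head_absorbing`
#'   (default `FALSE`).
#' @return An object of class `bd_scene`.
#' @examples
#' sc <- build_scene(radius = 0.5, length = 10,
#'                   barrier_x = seq(0.5, 9.5, by = 0.5), hole_r = 0.03)
#' @export
build_scene <- function(radius, length, barrier_x = numeric(0),
                        hole_r = numeric(0), hole_center = c("axis", "random"),
                        caps = c("reflecting", "reflecting"),
                        cap_holes = c(0, 0), spine = NULL) {
  hole_center <- match.arg(hole_center)
  stopifnot(radius > 0, length > 0)
  nb <- base::length(barrier_x)
  if (nb > 0) {
    if (any(barrier_x <= 0) || any(barrier_x >= length))
      stop("barriers must lie strictly inside the cylinder", call. = FALSE)
    hole_r <- rep_len(hole_r, nb)
    if (any(hole_r <= 0) || any(hole_r >= radius))
      stop("hole radii must be positive and smaller than the cylinder radius",
           call. = FALSE)
    ord <- order(barrier_x)
    barrier_x <- barrier_x[ord]; hole_r <- hole_r[ord]
    if (any(diff(barrier_x) <= 0))
      stop("barrier positions must be distinct", call. = FALSE)
  }
  if (hole_center == "axis" || nb == 0) {
    cy <- cz <- rep(0, nb)
  } else {
    rr <- (radius - hole_r) * sqrt(stats::runif(nb))
    th <- stats::runif(nb, 0, 2 * pi)
    cy <- rr * cos(th); cz <- rr * sin(th)
  }
  caps <- vapply(caps, function(s)
    match.arg(s, c("reflecting", "absorbing", "absorbing_hole")), character(1))
  if (!is.null(spine)) {
    need <- c("attach_position", "neck_radius", "neck_length", "head_radius")
    if (!all(need %in% names(spine)))
      stop("spine needs fields: ", paste(need, collapse = ", "), call. = FALSE)
    spine$head_absorbing <- isTRUE(spine$head_absorbing)
    if (spine$neck_radius >= radius || spine$neck_radius > spine$head_radius)
      stop("spine neck radius must be below the dendrite radius and the head radius",
           call. = FALSE)
    if (spine$attach_position <= 0 || spine$attach_position >= length)
      stop("spine attach position must lie inside the cylinder", call. = FALSE)
  }
  structure(list(radius = radius, length = length,
                 barrier_x = as.numeric(barrier_x), hole_r = as.numeric(hole_r),
                 hole_cy = as.numeric(cy), hole_cz = as.numeric(cz),
                 caps = unname(caps), cap_holes = as.numeric(cap_holes),
                 spine = spine),
            class = "bd_scene")
}

#' @export
print.bd_scene <- function(x, ...) {
  cat(sprintf("Brownian scene: cylinder r = %.3g um, L = %.4g um\n",
              x$radius, x$length))
  cat(sprintf("  caps: %s | %s\n", x$caps[1], x$caps[2]))
  cat(sprintf("  barriers: %d", length(x$barrier_x)))
  if (length(x$barrier_x) > 0)
    cat(sprintf(" (hole radius %.3g um)", x$hole_r[1]))
  cat("\n")
  if (!is.null(x$spine))
    cat(sprintf("  spine at x = %.3g um (neck r %.3g, len %.3g; head r %.3g)\n",
                x$spine$attach_position, x$spine$neck_radius,
                x$spine$neck_length, x$spine$head_radius))
  invisible(x)
}

#' Build a calibrated barrier scene from a compartment specification
#'
#' Places `floor(length / L) - 1` barrier disks with opening radius
#' `spec$eps` at the compartment boundaries of a cylinder of radius
#' `spec$a`, reproducing the periodic crowding geometry.
#'
#' @param spec A [compartment_spec()].
#' @param length Total cylinder length, um.
#' @param ... Passed to [build_scene()] (caps, spine, ...).
#' @return A `bd_scene`.
#' @export
calibrated_scene <- function(spec, length, ...) {
  stopifnot(inherits(spec, "compartment_spec"))
  nb <- floor(length / spec$L) - 1
  bx <- spec$L * seq_len(max(nb, 0))
  build_scene(radius = spec$a, length = length,
              barrier_x = bx, hole_r = spec$eps, ...)
}

#' Export a scene as a plain JSON geometry listing
#'
#' @param scene A `bd_scene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "bd_scene"))
  jsonlite::write_json(unclass(scene), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Full-cross-section sampling volumes (cylindrical disks)
#'
#' Emulates line-scan sampling: each volume is the slab
#' `[center - height/2, center + height/2]` across the full
#' cross-section. Volumes must be pairwise disjoint and inside the
#' cylinder.
#'
#' @param centers Axial centers, um.
#' @param height Slab height, um (default 0.2).
#' @param scene Optional `bd_scene` to validate containment against.
#' @return A matrix with columns `xmin`, `xmax` and attribute `centers`.
#' @export
sampling_volumes <- function(centers, height = 0.2, scene = NULL) {
  stopifnot(height > 0)
  centers <- sort(centers)
  xmin <- centers - height / 2
  xmax <- centers + height / 2
  if (any(xmax[-length(xmax)] > xmin[-1] + 1e-12))
    stop("sampling volumes must be pairwise disjoint", call. = FALSE)
  if (!is.null(scene) && (min(xmin) < 0 || max(xmax) > scene$length))
    stop("sampling volumes must be contained in the cylinder", call. = FALSE)
  m <- cbind(xmin = xmin, xmax = xmax)
  attr(m, "centers") <- centers
  m
}
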