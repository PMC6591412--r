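#' Spiral coefficients of the nerve-fiber-bundle trajectory model
#'
#' Retinal ganglion axon bundles are modeled as spirals in a polar frame
#' centered on the optic disc: \eqn{\phi(r) = \phi_0 + b (r - r_0)^c}, where
#' \eqn{\phi_0} is the angular position of the bundle at a starting circle of
#' radius \eqn{r_0} around the disc. `spiral_b()` is the (signed) curvature
#' coefficient and `spiral_c()` the positive exponent locating the point of
#' maximal curvature. Both are piecewise in the sign of `phi0`: positive
#' `phi0` selects the superior-retina branch, negative the inferior branch.
#'
#' @param phi0 Angular position(s) at the starting circle, degrees in
#'   \eqn{(-180, 180]}, nonzero. Positive = superior retina.
#' @return Numeric vector: `spiral_b()` is dimensionless and positive on the
#'   superior branch, negative on the inferior branch; `spiral_c()` is
#'   dimensionless and strictly positive.
#' @examples
#' spiral_b(121)   # exp(-1.9)
#' spiral_c(-90)   # 1.0
#' @export
spiral_b <- function(phi0) {
  stopifnot(all(phi0 > -180 & phi0 <= 180), all(phi0 != 0))
  ifelse(phi0 > 0,
          exp(-1.9 + 3.9 * tanh(-(phi0 - 121) / 14)),
         -exp( 0.7 + 1.5 * tanh(-(-phi0 - 90) / 25)))
}

#' @rdname spiral_b
#' @export
spiral_c <- function(phi0) {
  stopifnot(all(phi0 > -180 & phi0 <= 180), all(phi0 != 0))
  ifelse(phi0 > 0,
         1.9 + 1.4 * tanh((phi0 - 121) / 14),
         1.0 + 0.5 * tanh((-phi0 - 90) / 25))
}

#' Single nerve-fiber-bundle trajectory
#'
#' Evaluates the spiral \eqn{\phi(r) = \phi_0 + b (r - r_0)^c} in a polar
#' frame centered on the optic disc and converts it to fovea-centered retinal
#' microns. The polar angle is measured from the nasal direction at the disc
#' (pointing away from the fovea), counterclockwise-positive toward the
#' superior retina, so that `phi0 = 180` is the straight papillomacular
#' direction and small positive `phi0` the strongly curved superior arcuate
#' entry. Trajectories are truncated where they would cross the horizontal
#' raphe temporal to the disc, and where the angular sweep exceeds 180
#' degrees (beyond the trajectory model's fitted range).
#'
#' @param phi0 Starting angle, degrees in \eqn{(-180, 180]}, nonzero.
#' @param geometry A [subject_geometry()] giving the optic-disc position.
#' @param r_max Outer radius of the trajectory, degrees (> `r0`).
#' @param step Radial sampling step, degrees.
#' @param r0 Radius of the starting circle around the disc, degrees.
#' @param deg_per_mm Retina-to-degree conversion factor.
#' @return An object of class `bundle_trajectory`: a list with `phi0`,
#'   `xy` (an n x 2 matrix of retinal microns ordered periphery -> disc) and
#'   `arclen` (cumulative microns from each vertex to the disc-ward end;
#'   nonincreasing along the polyline).
#' @examples
#' b <- bundle_trajectory(121, subject_geometry())
#' head(b$xy)
#' @export
bundle_trajectory <- function(phi0, geometry, r_max = 45, step = 0.25,
                              r0 = 4, deg_per_mm = 3.6) {
  stopifnot(length(phi0) == 1L, inherits(geometry, "subject_geometry"),
            step > 0)
  if (r_max <= r0) stop("r_max must exceed r0")
  r <- seq(r0, r_max, by = step)
  phi <- phi0 + spiral_b(phi0) * (r - r0)^spiral_c(phi0)
  # cap the angular sweep: the spiral fit is an extrapolation beyond this
  keep <- abs(phi - phi0) <= 180
  r <- r[keep]; phi <- phi[keep]
  um_per_deg <- 1000 / deg_per_mm
  od <- geometry$optic_disc * um_per_deg   # disc, retinal-sense (x, y) deg
  x <- od[1] + r * um_per_deg * cospi(phi / 180)
  y <- od[2] + r * um_per_deg * sinpi(phi / 180)
  # truncate at the first raphe crossing temporal to the disc
  cross <- x < od[1] & (sign(y) != sign(phi0)) & y != 0
  k <- which(cross)
  if (length(k) > 0L && k[1] > 1L) {
    x <- x[seq_len(k[1] - 1L)]
    y <- y[seq_len(k[1] - 1L)]
  } else if (length(k) > 0L) {
    x <- x[1]; y <- y[1]
  }
  if (geometry$eye == "left") x <- -x
  xy <- cbind(x = rev(x), y = rev(y))      # periphery -> disc
  arclen <- if (nrow(xy) < 2L) rep(0, nrow(xy)) else {
    seg <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                           xy[-nrow(xy), , drop = FALSE])^2))
    rev(cumsum(c(0, rev(seg))))            # microns to disc-ward end
  }
  structure(list(phi0 = phi0, xy = xy, arclen = arclen),
            class = "bundle_trajectory")
}

#' Build a subject-specific axon map
#'
#' Generates a family of nerve-fiber-bundle trajectories for starting angles
#' `phi0` sampled uniformly over \eqn{(-180, 180]} degrees (excluding 0,
#' which lies on the raphe and belongs to neither branch), anchored at the
#' subject's optic-disc position. The map also carries a flattened vertex
#' index (coordinates, per-vertex tangent angles and arclengths) used by the
#' renderer and by nearest-bundle queries.
#'
#' @param geometry A [subject_geometry()].
#' @param phi0_samples Number of bundles (>= 2).
#' @param ... Passed to [bundle_trajectory()] (`r_max`, `step`, `r0`,
#'   `deg_per_mm`).
#' @return An object of class `axon_map`.
#' @examples
#' m <- build_axon_map(subject_geometry(), phi0_samples = 100)
#' m
#' @export
build_axon_map <- function(geometry, phi0_samples = 500, ...) {
  stopifnot(inherits(geometry, "subject_geometry"), phi0_samples >= 2)
  phi0 <- seq_len(phi0_samples) / phi0_samples * 360 - 180
  phi0[phi0 == 0] <- 180 / phi0_samples     # nudge off the raphe
  bundles <- lapply(phi0, bundle_trajectory, geometry = geometry, ...)
  n <- vapply(bundles, function(b) nrow(b$xy), 0L)
  ok <- n >= 2L
  bundles <- bundles[ok]
  n <- n[ok]
  vx <- unlist(lapply(bundles, function(b) b$xy[, 1]), use.names = FALSE)
  vy <- unlist(lapply(bundles, function(b) b$xy[, 2]), use.names = FALSE)
  arclen <- unlist(lapply(bundles, function(b) b$arclen), use.names = FALSE)
  tangent <- unlist(lapply(bundles, function(b) polyline_tangents(b$xy)),
                    use.names = FALSE)
  structure(
    list(bundles = bundles, geometry = geometry,
         phi0_samples = phi0_samples,
         vx = vx, vy = vy, arclen = arclen, tangent = tangent,
         bundle_id = rep(seq_along(bundles), times = n),
         vstart = c(0L, cumsum(n))),   # 0-based offsets, length nbundle+1
    class = "axon_map")
}

#' @export
print.axon_map <- function(x, ...) {
  cat(sprintf("axon_map: %d bundles, %d vertices (%s, %s eye)\n",
              length(x$bundles), length(x$vx),
              x$geometry$implant, x$geometry$eye))
  invisible(x)
}

# axial tangent angle (deg) at each vertex of an n x 2 polyline
polyline_tangents <- function(xy) {
  n <- nrow(xy)
  if (n < 2L) return(rep(NA_real_, n))
  i0 <- pmax(seq_len(n) - 1L, 1L)
  i1 <- pmin(seq_len(n) + 1L, n)
  wrap_axial(atan2(xy[i1, 2] - xy[i0, 2], xy[i1, 1] - xy[i0, 1]) * 180 / pi)
}

# index of the nearest map vertex for each query point (n x 2 microns)
nearest_map_vertex <- function(p, map) {
  m <- as_xy(p)
  cpp_nearest_vertex(m[, 1], m[, 2], map$vx, map$vy)
}

#' Tangent of the nearest nerve-fiber bundle
#'
#' Finds the map vertex closest to each query point and returns the axial
#' tangent angle of the bundle polyline there. This is the model's predicted
#' phosphene orientation axis at an electrode, in retinal coordinates; use
#' [tangent_to_visual()] to express it in visual-field (drawing) coordinates.
#'
#' @param p Length-2 vector or n x 2 matrix of retinal microns.
#' @param map An [build_axon_map()] result.
#' @return Numeric vector of axial angles in degrees, in \eqn{[-90, 90)}.
#' @examples
#' m <- build_axon_map(subject_geometry(), phi0_samples = 100)
#' nearest_bundle_tangent(c(-2000, 500), m)
#' @export
nearest_bundle_tangent <- function(p, map) {
  stopifnot(inherits(map, "axon_map"))
  if (length(map$vx) == 0L) stop("axon map has no bundle vertices")
  map$tangent[nearest_map_vertex(p, map)]
}

#' Convert a retinal axial angle to visual-field orientation
#'
#' The vertical axis flips between retinal and visual-field coordinates, so
#' an axis at angle theta on the retina appears at -theta in a drawing.
#'
#' @param theta Axial angle(s) in degrees, retinal coordinates.
#' @return Axial angle(s) in degrees in \eqn{[-90, 90)}, visual-field sense.
#' @export
tangent_to_visual <- function(theta) {
  wrap_axial(-theta)
}

#' Export an axon map as a multi-polyline CSV
#'
#' Writes one row per bundle vertex: bundle id, vertex index
#' (periphery -> disc), x and y in retinal microns, and the arclength to the
#' disc-ward end, suitable for plotting.
#'
#' @param map An `axon_map`.
#' @param path Output CSV path.
#' @export
export_axon_map <- function(map, path) {
  stopifnot(inherits(map, "axon_map"))
  n <- diff(map$vstart)
  df <- data.frame(bundle = map$bundle_id,
                   vertex = unlist(lapply(n, seq_len), use.names = FALSE),
                   x_um = map$vx, y_um = map$vy, arclen_um = map$arclen)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
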