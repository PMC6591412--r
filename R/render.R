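#' Raster grid over the visual field
#'
#' Percepts are rendered on a uniform raster in visual-field degrees. Images
#' are stored as matrices with rows indexing elevation (ascending, so row 1
#' is the lowest elevation) and columns indexing azimuth; exporters flip
#' rows so that the upper image half corresponds to the upper visual field.
#'
#' @param xlim,ylim Azimuth and elevation extents, degrees.
#' @param pix Pixel size, degrees per pixel.
#' @param deg_per_mm Retina-to-degree conversion used when mapping pixels to
#'   retinal microns.
#' @return An object of class `percept_grid`.
#' @examples
#' percept_grid(c(-10, 10), c(-8, 8), 0.5)
#' @export
percept_grid <- function(xlim = c(-32, 32), ylim = c(-24, 24), pix = 0.2,
                         deg_per_mm = 3.6) {
  stopifnot(pix > 0, xlim[2] > xlim[1], ylim[2] > ylim[1])
  az <- seq(xlim[1] + pix / 2, xlim[2] - pix / 2, by = pix)
  el <- seq(ylim[1] + pix / 2, ylim[2] - pix / 2, by = pix)
  structure(list(xlim = xlim, ylim = ylim, pix = pix,
                 az = az, el = el, nx = length(az), ny = length(el),
                 deg_per_mm = deg_per_mm),
            class = "percept_grid")
}

#' @export
print.percept_grid <- function(x, ...) {
  cat(sprintf("percept_grid: %d x %d px, %.2f deg/px, az [%g, %g], el [%g, %g]\n",
              x$ny, x$nx, x$pix, x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2]))
  invisible(x)
}

# flat (column-major) retinal coordinates of all pixel centers, microns
grid_retinal_coords <- function(grid, eye = "right") {
  k <- 1000 / grid$deg_per_mm
  s <- if (eye == "left") -1 else 1
  list(x = rep(s * grid$az * k, each = grid$ny),
       y = rep(-grid$el * k, times = grid$nx))
}

new_intensity_image <- function(values, grid, model, electrode, params) {
  structure(list(values = values, grid = grid, model = model,
                 electrode = electrode, params = params),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("intensity_image (%s): %d x %d px, max %.3f\n",
              x$model, nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

#' Model parameters for percept rendering
#'
#' @param rho Spatial decay constant orthogonal to the axon (scoreboard:
#'   isotropic Gaussian spread), microns, > 0.
#' @param lam Decay constant along the axon, microns, > 0; leave `NULL` for
#'   the scoreboard model.
#' @param threshold Binarisation threshold as a fraction of the peak
#'   intensity, in (0, 1). The default `1/sqrt(e)` makes the scoreboard
#'   percept a disc of radius `rho`.
#' @return A list of class `model_params`.
#' @export
model_params <- function(rho, lam = NULL, threshold = exp(-0.5)) {
  stopifnot(rho > 0, is.null(lam) || lam > 0, threshold > 0, threshold < 1)
  structure(list(rho = rho, lam = lam, threshold = threshold),
            class = "model_params")
}

#' Render a scoreboard-model percept
#'
#' The scoreboard model predicts an isolated focal spot: intensity decays as
#' an isotropic Gaussian of the retinal distance to the stimulating
#' electrode, \eqn{I = \exp(-d^2 / (2\rho^2))}, with peak 1 at the electrode.
#'
#' @param electrode Length-2 numeric, electrode center in retinal microns.
#' @param params A [model_params()] (only `rho` is used).
#' @param grid A [percept_grid()].
#' @param eye `"right"` or `"left"`.
#' @return An `intensity_image`.
#' @examples
#' img <- render_scoreboard(c(-1300, -500), model_params(rho = 300),
#'                          percept_grid(c(-12, 4), c(-8, 8), 0.25))
#' @export
render_scoreboard <- function(electrode, params, grid, eye = "right") {
  stopifnot(inherits(grid, "percept_grid"), length(electrode) == 2L)
  rc <- grid_retinal_coords(grid, eye)
  d2 <- (rc$x - electrode[1])^2 + (rc$y - electrode[2])^2
  vals <- matrix(exp(-d2 / (2 * params$rho^2)), nrow = grid$ny)
  if (max(vals) < params$threshold)
    warning("electrode lies outside the rendering grid: empty percept")
  new_intensity_image(vals, grid, "scoreboard", electrode, params)
}

#' Precomputed axon-path engine for a map/grid pair
#'
#' Rendering the axon-map model requires, for every pixel (treated as a
#' ganglion soma location), the disc-ward path of the nearest fiber bundle
#' and the soma distance to each path sample. That structure depends only on
#' the map and the grid, not on the electrode or on (rho, lambda), so it is
#' precomputed once and reused across renders -- essential during model
#' fitting.
#'
#' @param map An [build_axon_map()] result.
#' @param grid A [percept_grid()].
#' @param eye `"right"` or `"left"`.
#' @param stride Keep every `stride`-th vertex along the disc-ward path
#'   (path sampling; 1 = every vertex).
#' @param assign_stride Vertex subsampling used only for the
#'   nearest-bundle assignment of pixels.
#' @param soma_distance `"arclength"` measures the soma-to-sample distance
#'   along the fiber (default; axonal conduction follows the fiber);
#'   `"euclidean"` uses the straight-line distance, matching the activation
#'   formula verbatim. The two agree for straight bundles.
#' @return An object of class `axon_engine`.
#' @export
axon_engine <- function(map, grid, eye = "right", stride = 2L,
                        assign_stride = 2L,
                        soma_distance = c("arclength", "euclidean")) {
  stopifnot(inherits(map, "axon_map"), inherits(grid, "percept_grid"))
  soma_distance <- match.arg(soma_distance)
  rc <- grid_retinal_coords(grid, eye)
  sub <- seq(1L, length(map$vx), by = as.integer(assign_stride))
  k <- sub[cpp_nearest_vertex(rc$x, rc$y, map$vx[sub], map$vy[sub])]
  b <- map$bundle_id[k]
  j <- k - map$vstart[b]                     # soma vertex index in bundle
  nb <- diff(map$vstart)[b]                  # bundle lengths
  cnt <- (nb - j) %/% as.integer(stride) + 1L
  pix <- rep.int(seq_along(k), cnt)
  flat <- map$vstart[b[pix]] + j[pix] + (sequence(cnt) - 1L) * as.integer(stride)
  ds2 <- if (soma_distance == "arclength") {
    (map$arclen[k][pix] - map$arclen[flat])^2
  } else {
    (map$vx[flat] - rc$x[pix])^2 + (map$vy[flat] - rc$y[pix])^2
  }
  structure(list(ptr = c(0L, cumsum(cnt)),
                 ax = map$vx[flat], ay = map$vy[flat], ds2 = ds2,
                 grid = grid, eye = eye, soma_distance = soma_distance,
                 npix = length(k)),
            class = "axon_engine")
}

# raw log-intensity matrix (npix x n_electrodes) for the axon model
axon_log_intensity <- function(engine, ex, ey, rho, lam,
                               agg = c("max", "sum")) {
  agg <- match.arg(agg)
  cpp_axon_exponent(engine$ptr, engine$ax, engine$ay, engine$ds2,
                    as.numeric(ex), as.numeric(ey), rho, lam,
                    if (agg == "max") 0L else 1L)
}

#' Render an axon-map-model percept
#'
#' Each pixel is treated as a ganglion soma assigned to its nearest fiber
#' bundle. Activation combines two Gaussian decays: one with constant `rho`
#' in the distance from the stimulating electrode to the fiber, and one with
#' constant `lam` in the distance from the soma along the fiber; the pixel
#' intensity aggregates this product over the soma's disc-ward path (maximum
#' by default) and the image is normalised to peak 1.
#'
#' @inheritParams render_scoreboard
#' @param map An [build_axon_map()] result.
#' @param engine Optional precomputed [axon_engine()] (built on the fly if
#'   missing; pass one when rendering repeatedly).
#' @param agg Aggregation over path samples, `"max"` (default) or `"sum"`.
#' @param ... Passed to [axon_engine()] when `engine` is `NULL`.
#' @return An `intensity_image`.
#' @examples
#' geo <- subject_geometry()
#' m <- build_axon_map(geo, phi0_samples = 150)
#' g <- percept_grid(c(-14, 2), c(-8, 8), 0.4)
#' img <- render_axon(c(-1500, 500), model_params(300, 1000), m, g)
#' @export
render_axon <- function(electrode, params, map, grid, eye = "right",
                        engine = NULL, agg = c("max", "sum"), ...) {
  agg <- match.arg(agg)
  if (is.null(params$lam)) stop("axon model requires lam")
  if (is.null(engine)) engine <- axon_engine(map, grid, eye, ...)
  L <- axon_log_intensity(engine, electrode[1], electrode[2],
                          params$rho, params$lam, agg)
  mx <- max(L)
  vals <- if (is.finite(mx)) exp(L - mx) else matrix(0, engine$npix, 1)
  new_intensity_image(matrix(vals, nrow = grid$ny), grid, "axon_map",
                      electrode, params)
}

#' Threshold an intensity image into a binary percept
#'
#' @param img An `intensity_image`.
#' @param threshold Fraction in (0, 1); defaults to the threshold stored in
#'   the image's parameters (`1/sqrt(e)` by default).
#' @return An object of class `percept_image`: a list with the binary
#'   `mask` matrix (0/1), the grid, and provenance (model, electrode,
#'   parameters). An all-zero mask is allowed (empty percept).
#' @export
threshold_percept <- function(img, threshold = NULL) {
  stopifnot(inherits(img, "intensity_image"))
  if (is.null(threshold)) threshold <- img$params$threshold
  stopifnot(threshold > 0, threshold < 1)
  structure(list(mask = (img$values >= threshold) + 0L, grid = img$grid,
                 model = img$model, electrode = img$electrode,
                 params = img$params),
            class = "percept_image")
}

#' @export
print.percept_image <- function(x, ...) {
  cat(sprintf("percept_image (%s): %d x %d px, %d on\n",
              x$model, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Simulate percepts across electrode-retina distances
#'
#' Lift-off of an electrode from the retinal surface is modeled as an
#' increase of the current-spread constant `rho` at a fixed axonal decay
#' `lam`: electrodes close to the surface (`rho < lam`) produce elongated
#' percepts dominated by axonal stimulation, and larger distances produce
#' progressively more compact, rounder percepts.
#'
#' @param electrode Electrode center, retinal microns (choose a location
#'   near the horizontal meridian for the classic demonstration).
#' @param rho_list Numeric vector of `rho` values, microns.
#' @param lam Axonal decay constant, microns.
#' @inheritParams render_axon
#' @return A list with `percepts` (list of `percept_image`) and
#'   `descriptors` (data frame of rho, area, orientation, elongation).
#' @export
simulate_distance_series <- function(electrode, rho_list, lam, map, grid,
                                     eye = "right", engine = NULL, ...) {
  if (is.null(engine)) engine <- axon_engine(map, grid, eye, ...)
  percepts <- lapply(rho_list, function(r) {
    threshold_percept(render_axon(electrode, model_params(r, lam), map,
                                  grid, eye, engine = engine))
  })
  d <- do.call(rbind, lapply(percepts, function(p) {
    s <- describe_shape(p)
    data.frame(area = s$area, orientation = s$orientation,
               elongation = s$elongation)
  }))
  list(percepts = percepts,
       descriptors = cbind(data.frame(rho = rho_list, lam = lam), d))
}
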