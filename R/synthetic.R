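#' Configuration for the synthetic-data generator
#'
#' Describes a simulated subject: implant type, the ranges the subject
#' geometry is sampled from (spanning the implanted-subject landmark
#' estimates), the ground-truth percept-model parameters, and the
#' trial-to-trial noise applied to drawings. Defaults emulate the study
#' conditions: 5 trials per electrode; optic-disc position normal around
#' (15.5, 1.5) deg with SDs (1.1, 0.9), truncated at 2 SD; centroid jitter
#' 200 um, orientation jitter 10 deg, area-scale jitter 0.15, 1-pixel
#' boundary roughening.
#'
#' @param implant `"argus_ii"` or `"argus_i"`.
#' @param n_electrodes Electrodes with drawings (sampled from the array).
#' @param rho,lam True axon-map parameters, microns.
#' @param trials Trials per electrode.
#' @param center_x,center_y,rotation Uniform sampling ranges for the array
#'   placement (microns / degrees).
#' @param disc_az,disc_el `c(mean, sd)` of the optic-disc position, degrees
#'   (retinal sense), truncated at 2 SD.
#' @param centroid_sd Trial centroid jitter SD, microns.
#' @param orientation_sd Trial rotation jitter SD, degrees.
#' @param area_scale_sd Trial area-scale jitter SD (fraction).
#' @param roughness Boundary roughening amplitude in pixels (0 disables).
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(implant = "argus_ii", n_electrodes = 20,
                         rho = 437, lam = 1420, trials = 5,
                         center_x = c(-2142, -651),
                         center_y = c(-850, 401),
                         rotation = c(-53.9, -22.1),
                         disc_az = c(15.5, 1.1), disc_el = c(1.5, 0.9),
                         centroid_sd = 200, orientation_sd = 10,
                         area_scale_sd = 0.15, roughness = 1,
                         seed = 1) {
  stopifnot(rho > 0, lam > 0, trials >= 1, n_electrodes >= 1,
            centroid_sd >= 0, orientation_sd >= 0, area_scale_sd >= 0,
            roughness >= 0)
  structure(as.list(environment()), class = "synth_config")
}

# normal draw truncated at k standard deviations
rnorm_trunc <- function(n, mean, sd, k = 2) {
  pmin(pmax(rnorm(n, mean, sd), mean - k * sd), mean + k * sd)
}

#' Generate a synthetic subject (geometry and axon map)
#'
#' Samples an implant placement uniformly from the configured ranges and an
#' optic-disc position from a truncated normal, then builds the subject's
#' axon map.
#'
#' @param cfg A [synth_config()].
#' @param phi0_samples,... Passed to [build_axon_map()].
#' @return A list with `geometry` and `map`.
#' @export
generate_subject <- function(cfg, phi0_samples = 500, ...) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  geo <- subject_geometry(
    implant = cfg$implant,
    array_center = c(runif(1, cfg$center_x[1], cfg$center_x[2]),
                     runif(1, cfg$center_y[1], cfg$center_y[2])),
    array_rotation = runif(1, cfg$rotation[1], cfg$rotation[2]),
    optic_disc = c(rnorm_trunc(1, cfg$disc_az[1], cfg$disc_az[2]),
                   rnorm_trunc(1, cfg$disc_el[1], cfg$disc_el[2])))
  list(geometry = geo, map = build_axon_map(geo, phi0_samples, ...))
}

# 4-neighbourhood dilation / erosion of a 0/1 matrix
dilate4 <- function(m) {
  pmin(m + shift_mask(m, 1, 0) + shift_mask(m, -1, 0) +
         shift_mask(m, 0, 1) + shift_mask(m, 0, -1), 1)
}
erode4 <- function(m) {
  1 - dilate4(1 - m)
}

# toggle a fraction of boundary pixels in and out (1-pixel amplitude)
roughen_mask <- function(m, prob = 0.3) {
  add <- dilate4(m) - m
  rem <- m - erode4(m)
  m + add * (matrix(runif(length(m)), nrow(m)) < prob) -
      rem * (matrix(runif(length(m)), nrow(m)) < prob)
}

#' Generate trial drawings from a known axon map
#'
#' Renders the noiseless axon-map percept of every selected electrode at
#' the configured ground-truth (rho, lam), then derives each trial by
#' applying centroid jitter, a small rotation, an area rescaling and
#' optional boundary roughening. Electrodes whose percept is empty on the
#' grid are skipped and recorded.
#'
#' @param geometry,map A subject, e.g. from [generate_subject()].
#' @param cfg The [synth_config()].
#' @param grid Rendering [percept_grid()].
#' @param engine Optional prebuilt [axon_engine()].
#' @return A list with `ds` (a [drawing_set()]) and `truth` (list with the
#'   true `rho`, `lam`, electrodes used, skipped electrodes and the seed).
#' @export
generate_drawings <- function(geometry, map, cfg, grid, engine = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(grid, "percept_grid"))
  if (is.null(engine)) engine <- axon_engine(map, grid, geometry$eye)
  arr <- build_array(geometry)
  set.seed(cfg$seed + 1L)
  idx <- if (cfg$n_electrodes >= nrow(arr)) seq_len(nrow(arr)) else
    sort(sample.int(nrow(arr), cfg$n_electrodes))
  params <- model_params(cfg$rho, cfg$lam)
  um_per_px <- grid$pix * 1000 / grid$deg_per_mm
  drawings <- list()
  used <- skipped <- character(0)
  for (i in idx) {
    base <- threshold_percept(render_axon(c(arr$x[i], arr$y[i]), params,
                                          map, grid, geometry$eye,
                                          engine = engine))$mask
    if (sum(base) == 0) {
      skipped <- c(skipped, arr$name[i])
      next
    }
    trials <- lapply(seq_len(cfg$trials), function(t) {
      m <- transform_mask(
        base,
        dx = round(rnorm(1, 0, cfg$centroid_sd) / um_per_px),
        dy = round(rnorm(1, 0, cfg$centroid_sd) / um_per_px),
        angle = rnorm(1, 0, cfg$orientation_sd),
        scale = sqrt(pmax(1 + rnorm(1, 0, cfg$area_scale_sd), 0.25)))
      if (cfg$roughness > 0) m <- roughen_mask(m)
      m
    })
    drawings[[arr$name[i]]] <- trials
    used <- c(used, arr$name[i])
  }
  if (length(used) == 0L) stop("all percepts empty; enlarge the grid")
  ds <- drawing_set(geometry, grid,
                    arr[arr$name %in% used, c("name", "x", "y")],
                    drawings)
  list(ds = ds,
       truth = list(rho = cfg$rho, lam = cfg$lam, electrodes = used,
                    skipped = skipped, seed = cfg$seed))
}
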