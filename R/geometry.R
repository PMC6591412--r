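#' Retina / visual-field coordinate conversion
#'
#' The package works in two planar coordinate systems:
#' \describe{
#'   \item{retinal}{microns on the retinal surface, fovea at the origin,
#'     x positive toward the optic disc (nasal retina), y positive superior.}
#'   \item{visual field}{degrees of visual angle: azimuth and elevation.
#'     The vertical axis flips between the two systems (the upper visual
#'     field projects onto the inferior retina).}
#' }
#' The default conversion is linear at 3.6 degrees of visual angle per
#' millimetre of retina, applied radially from the fovea. A custom radial
#' conversion can be supplied as `fun`, a function mapping retinal
#' eccentricity in microns to eccentricity in degrees (and its inverse for
#' `visual_to_retinal()`); angles about the fovea are preserved.
#'
#' For a right eye, nasal retina maps to positive azimuth; a left eye is the
#' mirror image, so azimuth is negated (applied once, here).
#'
#' @param xy Numeric length-2 vector or 2-column matrix of retinal
#'   coordinates in microns (columns x, y).
#' @param ae Numeric length-2 vector or 2-column matrix of visual-field
#'   coordinates in degrees (columns azimuth, elevation).
#' @param eye `"right"` or `"left"`.
#' @param deg_per_mm Linear conversion factor (default 3.6).
#' @param fun Optional radial conversion hook: for `retinal_to_visual()` a
#'   function microns -> degrees; for `visual_to_retinal()` degrees ->
#'   microns. Overrides `deg_per_mm`.
#' @return A matrix (or length-2 vector, matching the input shape) of
#'   converted coordinates.
#' @examples
#' retinal_to_visual(c(1000, 0))   # 1 mm -> 3.6 deg azimuth
#' visual_to_retinal(c(3.6, 0))
#' @export
retinal_to_visual <- function(xy, eye = c("right", "left"), deg_per_mm = 3.6,
                              fun = NULL) {
  eye <- match.arg(eye)
  m <- as_xy(xy)
  stopifnot(all(is.finite(m)))
  if (is.null(fun)) {
    out <- m * (deg_per_mm / 1000)
  } else {
    r <- sqrt(rowSums(m^2))
    s <- ifelse(r > 0, vapply(r, fun, 0) / r, 0)
    out <- m * s
  }
  out[, 2] <- -out[, 2]                      # superior retina -> lower field
  if (eye == "left") out[, 1] <- -out[, 1]   # mirror azimuth once
  colnames(out) <- c("azimuth", "elevation")
  restore_shape(out, xy)
}

#' @rdname retinal_to_visual
#' @export
visual_to_retinal <- function(ae, eye = c("right", "left"), deg_per_mm = 3.6,
                              fun = NULL) {
  eye <- match.arg(eye)
  m <- as_xy(ae)
  stopifnot(all(is.finite(m)))
  if (eye == "left") m[, 1] <- -m[, 1]
  m[, 2] <- -m[, 2]
  if (is.null(fun)) {
    out <- m * (1000 / deg_per_mm)
  } else {
    r <- sqrt(rowSums(m^2))
    s <- ifelse(r > 0, vapply(r, fun, 0) / r, 0)
    out <- m * s
  }
  colnames(out) <- c("x", "y")
  restore_shape(out, ae)
}

as_xy <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2L)
    unname(p)
  } else {
    stopifnot(length(p) == 2L)
    matrix(as.numeric(p), ncol = 2L)
  }
}

restore_shape <- function(out, input) {
  if (is.matrix(input)) out else {
    v <- drop(out)
    names(v) <- colnames(out)
    v
  }
}

#' Subject implant geometry
#'
#' Bundles the per-subject landmarks that place a simulated electrode array on
#' a simulated axon map: implant type, array center (retinal microns,
#' fovea-centered), array rotation with respect to the horizontal raphe
#' (degrees, counterclockwise in retinal coordinates), and the optic-disc
#' center in visual-field degrees. These landmarks are normally estimated from
#' fundus photography and are taken here as given inputs.
#'
#' @param implant `"argus_i"` (4x4 checkerboard, 800 um pitch, 260/520 um
#'   electrodes) or `"argus_ii"` (6x10 grid, 525 um pitch, 200 um electrodes).
#' @param array_center Length-2 numeric, retinal microns.
#' @param array_rotation Rotation in degrees, in \eqn{[-180, 180)}.
#' @param optic_disc Length-2 numeric, visual-field degrees (azimuth,
#'   elevation); azimuth must be positive under the nasal-positive convention.
#' @param eye `"right"` or `"left"`.
#' @return An object of class `subject_geometry`.
#' @examples
#' geo <- subject_geometry("argus_ii", c(-1331, -850), -28.4, c(16.2, 1.38))
#' geo
#' @export
subject_geometry <- function(implant = c("argus_ii", "argus_i"),
                             array_center = c(0, 0),
                             array_rotation = 0,
                             optic_disc = c(15.5, 1.5),
                             eye = c("right", "left")) {
  implant <- match.arg(implant)
  eye <- match.arg(eye)
  stopifnot(length(array_center) == 2L, is.finite(array_center),
            length(optic_disc) == 2L, is.finite(optic_disc),
            is.finite(array_rotation))
  if (optic_disc[1] <= 0)
    stop("optic disc azimuth must be positive (nasal-positive convention)")
  if (array_rotation < -180 || array_rotation >= 180)
    stop("array_rotation must lie in [-180, 180)")
  structure(
    list(implant = implant,
         array_center = as.numeric(array_center),
         array_rotation = as.numeric(array_rotation),
         optic_disc = as.numeric(optic_disc),
         eye = eye),
    class = "subject_geometry")
}

#' @export
print.subject_geometry <- function(x, ...) {
  cat(sprintf("subject_geometry: %s, %s eye\n", x$implant, x$eye))
  cat(sprintf("  array center : (%.0f, %.0f) um\n",
              x$array_center[1], x$array_center[2]))
  cat(sprintf("  array rotation: %.1f deg\n", x$array_rotation))
  cat(sprintf("  optic disc   : (%.2f, %.2f) deg\n",
              x$optic_disc[1], x$optic_disc[2]))
  invisible(x)
}

# implant grid parameters
implant_spec <- function(implant) {
  switch(implant,
    argus_i  = list(nrow = 4L, ncol = 4L, pitch = 800),
    argus_ii = list(nrow = 6L, ncol = 10L, pitch = 525),
    stop("unknown implant type: ", implant))
}

#' Build the electrode array for a subject
#'
#' Lays out the implant's electrode grid (row letter + column number names,
#' row A most superior before rotation), rotates it counterclockwise by the
#' array rotation about the array center, and translates it to the array
#' center. Argus I electrode diameters alternate 260/520 um in a checkerboard;
#' Argus II electrodes are all 200 um.
#'
#' @param geometry A [subject_geometry()].
#' @return A data frame with columns `name`, `row`, `col`, `x`, `y`
#'   (retinal microns) and `diameter` (microns), of class `electrode_array`.
#' @examples
#' arr <- build_array(subject_geometry("argus_ii"))
#' head(arr)
#' @export
build_array <- function(geometry) {
  stopifnot(inherits(geometry, "subject_geometry"))
  sp <- implant_spec(geometry$implant)
  i <- rep(seq_len(sp$nrow), each = sp$ncol)   # row index, A = 1
  j <- rep(seq_len(sp$ncol), times = sp$nrow)
  gx <- (j - (sp$ncol + 1) / 2) * sp$pitch
  gy <- ((sp$nrow + 1) / 2 - i) * sp$pitch     # row A above row B etc.
  th <- geometry$array_rotation * pi / 180
  x <- geometry$array_center[1] + cos(th) * gx - sin(th) * gy
  y <- geometry$array_center[2] + sin(th) * gx + cos(th) * gy
  if (geometry$eye == "left") x <- -x
  diameter <- if (geometry$implant == "argus_i") {
    ifelse((i + j) %% 2 == 0, 260, 520)
  } else rep(200, length(i))
  out <- data.frame(
    name = paste0(LETTERS[i], j),
    row = i, col = j, x = x, y = y, diameter = diameter,
    stringsAsFactors = FALSE)
  class(out) <- c("electrode_array", "data.frame")
  out
}

#' Read and write subject geometry configuration files
#'
#' Subject geometries are stored in a YAML file, one named record per
#' subject with fields `implant`, `array_center_um`, `array_rotation_deg`,
#' `optic_disc_deg` and `eye`. A fixture with the four Argus study subjects
#' ships with the package:
#' `system.file("extdata", "argus_subjects.yaml", package = "phosphenes")`.
#'
#' @param path File path.
#' @param geometries Named list of [subject_geometry()] objects.
#' @return `read_subject_config()` returns a named list of
#'   `subject_geometry` objects.
#' @export
read_subject_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    subject_geometry(implant = r$implant,
                     array_center = as.numeric(r$array_center_um),
                     array_rotation = r$array_rotation_deg,
                     optic_disc = as.numeric(r$optic_disc_deg),
                     eye = if (is.null(r$eye)) "right" else r$eye)
  })
}

#' @rdname read_subject_config
#' @export
write_subject_config <- function(geometries, path) {
  stopifnot(is.list(geometries), !is.null(names(geometries)))
  out <- lapply(geometries, function(g) {
    list(implant = g$implant,
         array_center_um = g$array_center,
         array_rotation_deg = g$array_rotation,
         optic_disc_deg = g$optic_disc,
         eye = g$eye)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
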