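#' Per-subject set of phosphene drawings
#'
#' Container for one subject's binary phosphene drawings: a named list of
#' trial masks per electrode (all on a common raster grid), the electrode
#' positions in retinal microns, and the subject geometry. Drawing masks are
#' matrices in the same row/column convention as rendered percepts.
#'
#' @param geometry A [subject_geometry()].
#' @param grid The [percept_grid()] the drawings live on.
#' @param electrodes Data frame with columns `name`, `x`, `y` (retinal
#'   microns) for every electrode with drawings.
#' @param drawings Named list (names = electrode names), each element a list
#'   of binary matrices (trials).
#' @return An object of class `drawing_set`.
#' @export
drawing_set <- function(geometry, grid, electrodes, drawings) {
  stopifnot(inherits(geometry, "subject_geometry"),
            inherits(grid, "percept_grid"),
            all(c("name", "x", "y") %in% names(electrodes)),
            is.list(drawings),
            setequal(names(drawings), electrodes$name))
  for (nm in names(drawings)) {
    for (m in drawings[[nm]]) {
      stopifnot(is.matrix(m), nrow(m) == grid$ny, ncol(m) == grid$nx)
    }
  }
  structure(list(geometry = geometry, grid = grid,
                 electrodes = as.data.frame(electrodes),
                 drawings = drawings),
            class = "drawing_set")
}

#' @export
print.drawing_set <- function(x, ...) {
  nt <- vapply(x$drawings, length, 0L)
  cat(sprintf("drawing_set: %d electrodes, %d drawings (%s)\n",
              length(x$drawings), sum(nt), x$geometry$implant))
  invisible(x)
}

#' Shape-descriptor table of a drawing set
#'
#' Runs [describe_shape()] on every drawing and returns one row per trial.
#'
#' @param ds A [drawing_set()].
#' @return Data frame with columns `electrode`, `trial`, `area` (pixels),
#'   `orientation` (deg), `elongation`, `cx`, `cy` (centroid, pixels).
#' @export
describe_drawings <- function(ds) {
  stopifnot(inherits(ds, "drawing_set"))
  rows <- lapply(names(ds$drawings), function(nm) {
    trials <- ds$drawings[[nm]]
    do.call(rbind, lapply(seq_along(trials), function(t) {
      s <- describe_shape(trials[[t]])
      data.frame(electrode = nm, trial = t, area = s$area,
                 orientation = s$orientation, elongation = s$elongation,
                 cx = s$centroid[1], cy = s$centroid[2],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
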