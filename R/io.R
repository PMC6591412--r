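# write a binary mask as an 8-bit single-channel PNG; rows are flipped so
# the top of the image is the upper visual field
write_mask_png <- function(mask, path) {
  png::writePNG(apply(mask, 2, rev) * 1.0, path)
  invisible(path)
}

read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  m <- apply(v, 2, rev)
  if (!all(m %in% c(0, 1))) stop("non-binary mask image: ", path)
  storage.mode(m) <- "integer"
  m
}

#' Write and read a drawing set on disk
#'
#' The on-disk layout is plain text plus PNG masks: `geometry.yaml` (the
#' subject geometry), `grid.json` (raster bounds, pixel size and the
#' deg/mm conversion), `manifest.csv` (one row per trial: electrode, trial
#' index, mask file, electrode position in microns) and `masks/*.png`
#' (8-bit 0/255, top row = upper visual field). The round trip preserves
#' every pixel.
#'
#' @param ds A [drawing_set()].
#' @param dir Dataset directory (created if needed).
#' @param truth Optional ground-truth record (written as `truth.json`).
#' @return `read_drawing_set()` returns a [drawing_set()];
#'   `write_drawing_set()` returns `dir` invisibly.
#' @export
write_drawing_set <- function(ds, dir, truth = NULL) {
  stopifnot(inherits(ds, "drawing_set"))
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  write_subject_config(list(subject = ds$geometry),
                       file.path(dir, "geometry.yaml"))
  g <- ds$grid
  jsonlite::write_json(list(xlim = g$xlim, ylim = g$ylim, pix = g$pix,
                            deg_per_mm = g$deg_per_mm),
                       file.path(dir, "grid.json"), auto_unbox = TRUE,
                       digits = NA)
  rows <- list()
  for (nm in names(ds$drawings)) {
    e <- ds$electrodes[ds$electrodes$name == nm, ]
    for (t in seq_along(ds$drawings[[nm]])) {
      f <- file.path("masks", sprintf("%s_%02d.png", nm, t))
      write_mask_png(ds$drawings[[nm]][[t]], file.path(dir, f))
      rows[[length(rows) + 1L]] <-
        data.frame(electrode = nm, trial = t, file = f,
                   x_um = e$x, y_um = e$y, stringsAsFactors = FALSE)
    }
  }
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_drawing_set
#' @export
read_drawing_set <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  need <- c("electrode", "trial", "file", "x_um", "y_um")
  if (!all(need %in% names(man)))
    stop("manifest.csv must have columns: ", paste(need, collapse = ", "))
  gj <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  grid <- percept_grid(gj$xlim, gj$ylim, gj$pix, gj$deg_per_mm)
  geometry <- read_subject_config(file.path(dir, "geometry.yaml"))[[1]]
  arr <- build_array(geometry)
  bad <- setdiff(unique(man$electrode), arr$name)
  if (length(bad) > 0)
    stop("electrode name(s) not valid for ", geometry$implant, ": ",
         paste(bad, collapse = ", "))
  drawings <- list()
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f)) stop("missing mask file: ", f)
    m <- read_mask_png(f)
    if (nrow(m) != grid$ny || ncol(m) != grid$nx)
      stop("mask dimensions do not match the grid: ", f)
    drawings[[man$electrode[i]]] <-
      c(drawings[[man$electrode[i]]], list(m))
  }
  el <- unique(man[, c("electrode", "x_um", "y_um")])
  drawing_set(geometry, grid,
              data.frame(name = el$electrode, x = el$x_um, y = el$y_um,
                         stringsAsFactors = FALSE),
              drawings)
}

#' Read a directory tree of per-electrode drawing images
#'
#' Accepts the deposited-data style layout, one subdirectory per electrode
#' containing one PNG per trial (`<dir>/<electrode>/*.png`). Electrode
#' positions are derived from the subject geometry by electrode name.
#'
#' @param dir Root directory.
#' @param geometry The subject's [subject_geometry()].
#' @param grid The [percept_grid()] the masks are sampled on.
#' @return A [drawing_set()].
#' @export
read_drawings_tree <- function(dir, geometry, grid) {
  subs <- list.dirs(dir, recursive = FALSE)
  if (length(subs) == 0L) stop("no electrode subdirectories in ", dir)
  arr <- build_array(geometry)
  enames <- basename(subs)
  bad <- setdiff(enames, arr$name)
  if (length(bad) > 0)
    stop("electrode name(s) not valid for ", geometry$implant, ": ",
         paste(bad, collapse = ", "))
  drawings <- lapply(subs, function(s) {
    files <- sort(list.files(s, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG masks in ", s)
    lapply(files, read_mask_png)
  })
  names(drawings) <- enames
  pos <- arr[match(enames, arr$name), ]
  drawing_set(geometry, grid,
              data.frame(name = enames, x = pos$x, y = pos$y,
                         stringsAsFactors = FALSE),
              drawings)
}

#' Convert a touchscreen trace to a binary drawing mask
#'
#' Rasterises an ordered 2-D point sequence onto the grid, closes the shape
#' by connecting the first and last points, and flood-fills the enclosed
#' interior (every region not reachable from the image border). Screen
#' coordinates are converted to degrees of visual angle with `scale`
#' (degrees per input unit, derived from the recorded viewing distance) and
#' `origin` (the screen point mapping to (0, 0) degrees).
#'
#' @param trace Two-column matrix or data frame of at least 3 points
#'   (x, y), in screen units or degrees.
#' @param grid Target [percept_grid()].
#' @param scale Degrees per input unit (1 if the trace is already in
#'   degrees).
#' @param origin Length-2 input-unit offset subtracted before scaling.
#' @return A `percept_image` whose mask contains the stroke and its filled
#'   interior.
#' @export
trace_to_mask <- function(trace, grid, scale = 1, origin = c(0, 0)) {
  stopifnot(inherits(grid, "percept_grid"))
  pts <- as.matrix(trace)[, 1:2, drop = FALSE]
  stopifnot(nrow(pts) >= 3L, all(is.finite(pts)))
  deg <- sweep(pts, 2, origin) * scale
  cx <- (deg[, 1] - grid$xlim[1]) / grid$pix + 0.5
  cy <- (deg[, 2] - grid$ylim[1]) / grid$pix + 0.5
  cx <- c(cx, cx[1])   # close the shape
  cy <- c(cy, cy[1])
  stroke <- matrix(0L, grid$ny, grid$nx)
  for (i in seq_len(length(cx) - 1L)) {
    n <- max(2L, ceiling(max(abs(cx[i + 1] - cx[i]),
                             abs(cy[i + 1] - cy[i])) * 2) + 1L)
    xs <- round(seq(cx[i], cx[i + 1], length.out = n))
    ys <- round(seq(cy[i], cy[i + 1], length.out = n))
    ok <- xs >= 1 & xs <= grid$nx & ys >= 1 & ys <= grid$ny
    stroke[cbind(ys[ok], xs[ok])] <- 1L
  }
  exterior <- cpp_flood_exterior(stroke)
  mask <- (!exterior) + 0L
  structure(list(mask = mask, grid = grid, model = "drawing",
                 electrode = NULL, params = NULL),
            class = "percept_image")
}

#' Export a percept as a PNG image with a JSON sidecar
#'
#' Writes the binary mask as an 8-bit PNG (top row = upper visual field)
#' and a `.json` sidecar recording the grid bounds, pixel size, model,
#' electrode and parameters.
#'
#' @param p A `percept_image`.
#' @param path Output PNG path (the sidecar replaces the extension with
#'   `.json`).
#' @export
write_percept_png <- function(p, path) {
  stopifnot(inherits(p, "percept_image"))
  write_mask_png(p$mask, path)
  g <- p$grid
  jsonlite::write_json(
    list(xlim = g$xlim, ylim = g$ylim, pix = g$pix,
         deg_per_mm = g$deg_per_mm, model = p$model,
         electrode_um = p$electrode,
         rho = p$params$rho, lam = p$params$lam,
         threshold = p$params$threshold),
    sub("\\.png$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
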