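# coerce percept/intensity objects or matrices to a plain image matrix
as_image_matrix <- function(img) {
  if (inherits(img, "percept_image")) return(img$mask)
  if (inherits(img, "intensity_image")) return(img$values)
  if (is.matrix(img)) return(img)
  stop("expected a matrix, percept_image or intensity_image")
}

#' Raw image moment
#'
#' The raw moment \eqn{M_{ij} = \sum_x \sum_y x^i y^j I(x, y)} of a
#' grayscale or binary image, with 0-based pixel coordinates, x = column and
#' y = row. Area is \eqn{M_{00}} and the center of mass
#' \eqn{(M_{10}/M_{00}, M_{01}/M_{00})}.
#'
#' @param img Matrix (rows = y, columns = x), `percept_image` or
#'   `intensity_image`.
#' @param i,j Nonnegative integer orders (i for x, j for y).
#' @return The moment, a single number.
#' @examples
#' raw_moment(matrix(1, 10, 10), 0, 0)  # 100
#' @export
raw_moment <- function(img, i, j) {
  stopifnot(i >= 0, j >= 0)
  m <- as_image_matrix(img)
  x <- col(m) - 1
  y <- row(m) - 1
  sum(x^i * y^j * m)
}

#' Moment-based shape descriptors of a phosphene image
#'
#' Computes the three descriptors used to quantify phosphene drawings:
#' \describe{
#'   \item{area}{\eqn{M_{00}}, in pixels for binary images (optionally
#'     scaled to deg^2 via `pix`).}
#'   \item{orientation}{half the two-argument arctangent of the central
#'     second moments, \eqn{\theta = \frac{1}{2}\mathrm{atan2}(2\mu'_{11},
#'     \mu'_{20}-\mu'_{02})}, the axis of the principal eigenvector of the
#'     image covariance matrix, degrees in \eqn{[-90, 90)}. When
#'     \eqn{\mu'_{20} = \mu'_{02}} and \eqn{\mu'_{11} = 0} (e.g. a disc)
#'     the orientation is defined as 0.}
#'   \item{elongation}{\eqn{E = \sqrt{1 - \lambda_2/\lambda_1}} with
#'     \eqn{\lambda_1 \ge \lambda_2} the covariance eigenvalues: 0 for a
#'     circle, approaching 1 for an infinitesimally thin line.}
#' }
#' An empty image yields area 0 and NA orientation/elongation; a single
#' pixel has elongation 0.
#'
#' @inheritParams raw_moment
#' @param pix Optional pixel size in degrees; if given, `area_deg2` is
#'   added.
#' @return A list of class `shape_descriptors` with elements `area`,
#'   `centroid` (x, y in 0-based pixels), `orientation`, `elongation` (and
#'   `area_deg2` if `pix` was supplied).
#' @examples
#' m <- matrix(0L, 21, 21); m[11, ] <- 1L   # horizontal line
#' describe_shape(m)
#' @export
describe_shape <- function(img, pix = NULL) {
  m <- as_image_matrix(img)
  m00 <- sum(m)
  out <- list(area = m00, centroid = c(NA_real_, NA_real_),
              orientation = NA_real_, elongation = NA_real_)
  if (!is.null(pix)) out$area_deg2 <- m00 * pix^2
  if (m00 <= 0) return(structure(out, class = "shape_descriptors"))
  x <- col(m) - 1
  y <- row(m) - 1
  xb <- sum(x * m) / m00
  yb <- sum(y * m) / m00
  mu20 <- sum(x * x * m) / m00 - xb^2
  mu02 <- sum(y * y * m) / m00 - yb^2
  mu11 <- sum(x * y * m) / m00 - xb * yb
  out$centroid <- c(x = xb, y = yb)
  out$orientation <- if (mu20 == mu02 && mu11 == 0) 0 else
    wrap_axial(0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi)
  disc <- sqrt(4 * mu11^2 + (mu20 - mu02)^2) / 2
  l1 <- (mu20 + mu02) / 2 + disc
  l2 <- (mu20 + mu02) / 2 - disc
  out$elongation <- if (l1 <= 0) 0 else
    sqrt(min(max(1 - l2 / l1, 0), 1))
  structure(out, class = "shape_descriptors")
}

#' @export
print.shape_descriptors <- function(x, ...) {
  cat(sprintf("area %.1f px, orientation %s, elongation %s\n", x$area,
              if (is.na(x$orientation)) "NA" else sprintf("%.1f deg", x$orientation),
              if (is.na(x$elongation)) "NA" else sprintf("%.3f", x$elongation)))
  invisible(x)
}

#' Average drawings aligned at their centers of mass
#'
#' Translates every image by an integer pixel shift so that the centers of
#' mass coincide (at the centroid of the first nonempty drawing, so that
#' translated copies align exactly), then takes the pixel-wise mean.
#' This is the "mean image" used to summarise the five trials of an
#' electrode. Pixels shifted beyond the image edge are cropped.
#'
#' @param imgs List of equally sized matrices or `percept_image`s, at least
#'   one of which is nonempty.
#' @return A matrix of mean intensities in \eqn{[0, 1]}.
#' @export
average_drawings <- function(imgs) {
  stopifnot(length(imgs) >= 1L)
  ms <- lapply(imgs, as_image_matrix)
  cents <- lapply(ms, function(m) describe_shape(m)$centroid)
  ok <- !vapply(cents, anyNA, TRUE)
  if (!any(ok)) stop("all drawings are empty")
  target <- cents[[which(ok)[1]]]   # align on the first nonempty drawing
  acc <- 0
  for (i in seq_along(ms)) {
    if (ok[i]) {
      sh <- round(target - cents[[i]])
      acc <- acc + shift_mask(ms[[i]], sh[1], sh[2])
    } else acc <- acc + ms[[i]]
  }
  acc / length(ms)
}

# integer-shift an image by (dx, dy) pixels (x = columns, y = rows), no wrap
shift_mask <- function(m, dx, dy) {
  out <- matrix(0, nrow(m), ncol(m))
  sr <- seq_len(nrow(m)); sc <- seq_len(ncol(m))
  tr <- sr + dy; tc <- sc + dx
  keep_r <- tr >= 1 & tr <= nrow(m)
  keep_c <- tc >= 1 & tc <= ncol(m)
  out[tr[keep_r], tc[keep_c]] <- m[sr[keep_r], sc[keep_c]]
  out
}

# similarity transform of a binary mask about its centroid (rotation in
# degrees, isotropic scale, then translation in pixels); nearest-neighbour
# inverse mapping, used by the synthetic-data generator
transform_mask <- function(m, dx = 0, dy = 0, angle = 0, scale = 1) {
  if (sum(m) == 0) return(m)
  if (dx == 0 && dy == 0 && angle == 0 && scale == 1) return(m)
  cen <- describe_shape(m)$centroid
  nr <- nrow(m); nc <- ncol(m)
  x <- as.vector(col(m)) - 1
  y <- as.vector(row(m)) - 1
  # inverse map: undo translation, then rotate by -angle and unscale
  xr <- x - dx - cen[1]
  yr <- y - dy - cen[2]
  ca <- cospi(angle / 180); sa <- sinpi(angle / 180)
  xs <- ( ca * xr + sa * yr) / scale + cen[1]
  ys <- (-sa * xr + ca * yr) / scale + cen[2]
  ri <- round(ys) + 1
  ci <- round(xs) + 1
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  out <- matrix(0L, nr, nc)
  out[cbind(row(m)[ok], col(m)[ok])] <- m[cbind(ri[ok], ci[ok])]
  out
}
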