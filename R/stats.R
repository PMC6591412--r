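new_resampling_result <- function(observed, null, iters, seed, statistic) {
  structure(list(observed = observed, null = null,
                 p = (1 + sum(null <= observed)) / (1 + iters),
                 iters = iters, seed = seed, statistic = statistic),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("%s: observed %.4g, null mean %.4g, p = %.4g (%d iterations)\n",
              x$statistic, x$observed, mean(x$null), x$p, x$iters))
  invisible(x)
}

# per-electrode SEM of one descriptor; area SEM is normalised by the
# electrode's mean area
electrode_sem <- function(values, electrodes, descriptor) {
  vapply(split(values, electrodes), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    switch(descriptor,
           orientation = axial_sem(v),
           area = if (mean(v) > 0) sd(v) / sqrt(length(v)) / mean(v)
                  else NA_real_,
           sd(v) / sqrt(length(v)))
  }, 0)
}

#' Within-electrode drawing consistency (SEM resampling test)
#'
#' Tests whether drawings are more similar within an electrode than across
#' electrodes. The observed statistic is the mean over electrodes of the
#' per-electrode standard error of the mean of a shape descriptor (area SEMs
#' are normalised by that electrode's mean area; orientation SEMs use axial
#' residuals about the doubled-angle circular mean). The null distribution
#' resamples electrode-sized groups of drawings, with replacement, from the
#' subject's pooled drawings; the one-tailed p-value is the fraction of null
#' statistics at or below the observed one (with a +1 correction so p is
#' never exactly 0).
#'
#' @param ds A [drawing_set()] (every electrode needs >= 2 trials).
#' @param descriptor `"area"`, `"orientation"` or `"elongation"`.
#' @param iters Number of resampling iterations.
#' @param seed Integer seed; results are reproducible given (seed, iters).
#' @return A `resampling_result` with elements `observed`, `null`, `p`.
#' @export
sem_consistency_test <- function(ds, descriptor = c("area", "orientation",
                                                    "elongation"),
                                 iters = 1000, seed = 1) {
  descriptor <- match.arg(descriptor)
  stopifnot(inherits(ds, "drawing_set"), length(ds$drawings) >= 2L)
  d <- describe_drawings(ds)
  vals <- d[[descriptor]]
  if (anyNA(vals)) {
    warning("descriptor undefined on some drawings; excluded")
  }
  sems <- electrode_sem(vals, d$electrode, descriptor)
  observed <- mean(sems, na.rm = TRUE)
  sizes <- as.vector(table(d$electrode)[unique(d$electrode)])
  groups <- rep(seq_along(sizes), times = sizes)
  pool <- vals
  set.seed(seed)
  null <- vapply(seq_len(iters), function(i) {
    res <- pool[sample.int(length(pool), length(groups), replace = TRUE)]
    mean(electrode_sem(res, groups, descriptor), na.rm = TRUE)
  }, 0)
  new_resampling_result(observed, null, iters, seed,
                        paste0("sem_consistency[", descriptor, "]"))
}

# tangent (visual-field sense) under the subject's map at given retinal
# positions; NA where the nearest bundle vertex is farther than max_dist
map_tangents_at <- function(xy, map, max_dist = 1000) {
  k <- nearest_map_vertex(xy, map)
  d <- sqrt((map$vx[k] - xy[, 1])^2 + (map$vy[k] - xy[, 2])^2)
  out <- tangent_to_visual(map$tangent[k])
  out[d > max_dist] <- NA_real_
  out
}

#' Orientation alignment with the axon map (null-model resampling)
#'
#' The observed statistic is the mean over electrodes of the mean absolute
#' angular error between each trial's drawn orientation and the tangent of
#' the nerve-fiber bundle nearest to the electrode. Two null models are
#' available:
#' \describe{
#'   \item{NM1}{drawn orientations are independent of the map: orientations
#'     are resampled uniformly from \eqn{[-90, 90]} degrees. The null mean
#'     is ~45 degrees.}
#'   \item{NM2}{the array placement is random: the array center is drawn
#'     uniformly from x in \eqn{[-6000, 4000]} um, y in \eqn{[-4000, 4000]}
#'     um and the rotation from \eqn{[-90, 90]} degrees; bundle tangents are
#'     recomputed at each placement while the drawn orientations stay
#'     fixed.}
#' }
#' The one-tailed p-value is the fraction of null statistics at or below the
#' observed one (+1 corrected).
#'
#' @inheritParams sem_consistency_test
#' @param map The subject's [build_axon_map()].
#' @param null_model `"NM1"` or `"NM2"`.
#' @param max_dist Electrodes whose nearest bundle vertex is farther than
#'   this (microns) are treated as outside the map and skipped with a
#'   warning.
#' @return A `resampling_result`.
#' @export
orientation_alignment_test <- function(ds, map, null_model = c("NM1", "NM2"),
                                       iters = 1000, seed = 1,
                                       max_dist = 1000) {
  null_model <- match.arg(null_model)
  stopifnot(inherits(ds, "drawing_set"), inherits(map, "axon_map"))
  d <- describe_drawings(ds)
  d <- d[!is.na(d$orientation), ]
  epos <- ds$electrodes
  tan_vf <- map_tangents_at(cbind(epos$x, epos$y), map, max_dist)
  names(tan_vf) <- epos$name
  if (anyNA(tan_vf)) {
    warning("electrode(s) outside the axon map skipped: ",
            paste(epos$name[is.na(tan_vf)], collapse = ", "))
  }
  keep <- d$electrode %in% epos$name[!is.na(tan_vf)]
  d <- d[keep, ]
  err <- angular_error(d$orientation, tan_vf[d$electrode])
  observed <- mean(tapply(err, d$electrode, mean))
  set.seed(seed)
  if (null_model == "NM1") {
    null <- vapply(seq_len(iters), function(i) {
      th <- runif(nrow(d), -90, 90)
      e <- angular_error(th, tan_vf[d$electrode])
      mean(tapply(e, d$electrode, mean))
    }, 0)
  } else {
    arr <- build_array(ds$geometry)
    arr <- arr[match(unique(d$electrode), arr$name), , drop = FALSE]
    # grid offsets of the used electrodes, before placement
    g0 <- ds$geometry
    base <- cbind(arr$x - g0$array_center[1], arr$y - g0$array_center[2])
    th0 <- g0$array_rotation * pi / 180
    un <- cbind( cos(th0) * base[, 1] + sin(th0) * base[, 2],
                -sin(th0) * base[, 1] + cos(th0) * base[, 2])
    cx <- runif(iters, -6000, 4000)
    cy <- runif(iters, -4000, 4000)
    rot <- runif(iters, -90, 90) * pi / 180
    ne <- nrow(un)
    px <- rep(cx, each = ne) +
      cos(rep(rot, each = ne)) * un[, 1] - sin(rep(rot, each = ne)) * un[, 2]
    py <- rep(cy, each = ne) +
      sin(rep(rot, each = ne)) * un[, 1] + cos(rep(rot, each = ne)) * un[, 2]
    tans <- map_tangents_at(cbind(px, py), map, max_dist = Inf)
    tanm <- matrix(tans, nrow = ne)           # electrodes x iterations
    rownames(tanm) <- arr$name
    null <- vapply(seq_len(iters), function(i) {
      e <- angular_error(d$orientation, tanm[d$electrode, i])
      mean(tapply(e, d$electrode, mean))
    }, 0)
  }
  new_resampling_result(observed, null, iters, seed,
                        paste0("orientation_alignment[", null_model, "]"))
}

#' Fraction of phosphene-orientation variance explained by the axon map
#'
#' Computes \eqn{R^2 = 1 - SS_{res}/SS_{tot}} where the residuals are the
#' axially wrapped differences between drawn orientations and the bundle
#' tangent at the corresponding electrode, and the total sum of squares is
#' about the circular (doubled-angle) mean orientation. Can be negative when
#' the map predicts worse than the mean orientation; reported as-is.
#'
#' @inheritParams orientation_alignment_test
#' @param per_trial If `TRUE` (default) every trial contributes one
#'   observation; otherwise electrode-mean orientations are used.
#' @return A single number (possibly negative).
#' @export
orientation_variance_explained <- function(ds, map, per_trial = TRUE,
                                           max_dist = 1000) {
  stopifnot(inherits(ds, "drawing_set"), inherits(map, "axon_map"),
            length(ds$drawings) >= 2L)
  d <- describe_drawings(ds)
  d <- d[!is.na(d$orientation), ]
  epos <- ds$electrodes
  tan_vf <- map_tangents_at(cbind(epos$x, epos$y), map, max_dist)
  names(tan_vf) <- epos$name
  d <- d[d$electrode %in% epos$name[!is.na(tan_vf)], ]
  if (!per_trial) {
    s <- vapply(split(d$orientation, d$electrode), axial_mean, 0)
    shat <- tan_vf[names(s)]
  } else {
    s <- d$orientation
    shat <- tan_vf[d$electrode]
  }
  ss_res <- sum(wrap_axial(s - shat)^2)
  ss_tot <- sum(wrap_axial(s - axial_mean(s))^2)
  if (ss_tot == 0) {
    warning("zero orientation variance; R^2 undefined")
    return(NA_real_)
  }
  1 - ss_res / ss_tot
}

#' Correlation between phosphene elongation and area
#'
#' Pearson correlation across drawings (pooled over electrodes) between the
#' elongation and area descriptors.
#'
#' @param ds A [drawing_set()], or a data frame with columns `area` and
#'   `elongation` (e.g. from [describe_drawings()]).
#' @return A list with `r`, `p` and `n`. `r` is `NA` (with a warning) if
#'   either descriptor has zero variance.
#' @export
elongation_area_correlation <- function(ds) {
  d <- if (inherits(ds, "drawing_set")) describe_drawings(ds) else ds
  d <- d[!is.na(d$area) & !is.na(d$elongation), ]
  if (nrow(d) < 3L) stop("need at least 3 drawings")
  if (sd(d$area) == 0 || sd(d$elongation) == 0) {
    warning("zero variance in area or elongation; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = nrow(d)))
  }
  ct <- cor.test(d$area, d$elongation, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}
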