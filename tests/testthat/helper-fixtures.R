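# Shared fixtures (built once per test run) and independent oracles.

fix_geo <- subject_geometry("argus_ii", c(-1331, -850), -28.4, c(16.2, 1.38))
fix_map <- build_axon_map(fix_geo, phi0_samples = 150, step = 0.5)
fix_grid <- percept_grid(c(-16, 2), c(-10, 8), 0.35)

fix_cfg <- synth_config(n_electrodes = 6, rho = 300, lam = 900, seed = 42)
fix_sub <- generate_subject(fix_cfg, phi0_samples = 150, step = 0.5)
fix_gen <- generate_drawings(fix_sub$geometry, fix_sub$map, fix_cfg, fix_grid)
fix_ds <- fix_gen$ds

# brute-force per-pixel moment oracle, independent of describe_shape()
brute_describe <- function(m) {
  M <- matrix(0, 3, 3)
  for (r in seq_len(nrow(m))) {
    for (cc in seq_len(ncol(m))) {
      v <- m[r, cc]
      if (v == 0) next
      x <- cc - 1
      y <- r - 1
      for (i in 0:2) for (j in 0:2) M[i + 1, j + 1] <-
          M[i + 1, j + 1] + x^i * y^j * v
    }
  }
  m00 <- M[1, 1]
  if (m00 == 0) return(list(area = 0, orientation = NA, elongation = NA))
  xb <- M[2, 1] / m00
  yb <- M[1, 2] / m00
  mu20 <- M[3, 1] / m00 - xb^2
  mu02 <- M[1, 3] / m00 - yb^2
  mu11 <- M[2, 2] / m00 - xb * yb
  theta <- if (mu20 == mu02 && mu11 == 0) 0 else {
    t <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    ((t + 90) %% 180) - 90
  }
  l1 <- (mu20 + mu02) / 2 + sqrt(4 * mu11^2 + (mu20 - mu02)^2) / 2
  l2 <- (mu20 + mu02) / 2 - sqrt(4 * mu11^2 + (mu20 - mu02)^2) / 2
  list(area = m00, centroid = c(xb, yb), orientation = theta,
       elongation = if (l1 <= 0) 0 else sqrt(max(0, min(1, 1 - l2 / l1))))
}

# filled ellipse mask: semi-axes (a, b) pixels, rotated by ang degrees
ellipse_mask <- function(n, a, b, ang = 0, cx = (n - 1) / 2,
                         cy = (n - 1) / 2) {
  x <- matrix(rep(0:(n - 1), each = n), n) - cx   # x[r, c] = c - 1 - cx
  y <- matrix(rep(0:(n - 1), times = n), n) - cy  # y[r, c] = r - 1 - cy
  xr <- x * cospi(ang / 180) + y * sinpi(ang / 180)
  yr <- -x * sinpi(ang / 180) + y * cospi(ang / 180)
  ((xr / a)^2 + (yr / b)^2 <= 1) + 0L
}

# hand-built axon map of straight horizontal bundles (for closed-form
# checks); bundles run periphery (temporal) -> disc (nasal, +x)
straight_map <- function(ys = seq(-3000, 3000, by = 100),
                         xmin = -8000, xmax = 4000, step = 50) {
  xs <- seq(xmin, xmax, by = step)
  bundles <- lapply(ys, function(y0) {
    xy <- cbind(x = xs, y = rep(y0, length(xs)))
    structure(list(phi0 = if (y0 >= 0) 90 else -90, xy = xy,
                   arclen = xmax - xs),
              class = "bundle_trajectory")
  })
  n <- rep(length(xs), length(ys))
  structure(
    list(bundles = bundles, geometry = fix_geo, phi0_samples = length(ys),
         vx = rep(xs, times = length(ys)),
         vy = rep(ys, each = length(xs)),
         arclen = rep(xmax - xs, times = length(ys)),
         tangent = rep(0, length(xs) * length(ys)),
         bundle_id = rep(seq_along(ys), times = n),
         vstart = c(0L, cumsum(n))),
    class = "axon_map")
}
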