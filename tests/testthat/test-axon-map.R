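test_that("spiral coefficients match their closed forms at the anchors", {
  expect_equal(spiral_b(121), exp(-1.9))
  expect_equal(spiral_c(121), 1.9)
  expect_equal(spiral_b(-90), -exp(0.7))
  expect_equal(spiral_c(-90), 1.0)
  # independent re-evaluation at an arbitrary angle
  phi0 <- 60
  expect_equal(spiral_b(phi0),
               exp(-1.9 + 3.9 * tanh(-(phi0 - 121) / 14)), tolerance = 1e-12)
  expect_equal(spiral_c(phi0),
               1.9 + 1.4 * tanh((phi0 - 121) / 14), tolerance = 1e-12)
  phi0 <- -35
  expect_equal(spiral_b(phi0),
               -exp(0.7 + 1.5 * tanh(-(-phi0 - 90) / 25)), tolerance = 1e-12)
  expect_equal(spiral_c(phi0),
               1.0 + 0.5 * tanh((-phi0 - 90) / 25), tolerance = 1e-12)
})

test_that("spiral exponent is positive and branches have fixed sign", {
  grid <- setdiff(seq(-179, 180, by = 1), 0)
  expect_true(all(spiral_c(grid) > 0))
  expect_true(all(spiral_b(grid[grid > 0]) > 0))
  expect_true(all(spiral_b(grid[grid < 0]) < 0))
  expect_error(spiral_b(0))
  expect_error(spiral_c(200))
})

test_that("trajectories start at phi0 on the r0 circle and sweep monotonely", {
  um <- 1000 / 3.6
  od <- fix_geo$optic_disc * um
  for (phi0 in c(-150, -90, -20, 15, 90, 121, 179)) {
    b <- bundle_trajectory(phi0, fix_geo, r_max = 30)
    # disc-ward end sits at radius r0 = 4 deg, angle phi0
    start <- od + 4 * um * c(cospi(phi0 / 180), sinpi(phi0 / 180))
    expect_equal(unname(b$xy[nrow(b$xy), ]), unname(start), tolerance = 1e-9)
    # |phi(r) - phi0| nondecreasing in r
    d <- sqrt((b$xy[, 1] - od[1])^2 + (b$xy[, 2] - od[2])^2)
    ph <- atan2(b$xy[, 2] - od[2], b$xy[, 1] - od[1]) * 180 / pi
    sweep <- abs(phi0 - rev(ph))   # ordered disc -> periphery after rev
    expect_true(all(diff(pmin(sweep, 360 - sweep)) > -1e-9))
    # arclengths: nonnegative, zero at the disc end, nonincreasing
    expect_true(all(b$arclen >= 0))
    expect_equal(b$arclen[nrow(b$xy)], 0)
    expect_true(all(diff(b$arclen) <= 0))
  }
  expect_error(bundle_trajectory(90, fix_geo, r_max = 3), "r_max")
})

test_that("superior bundles stay superior and none cross the temporal raphe", {
  b90 <- bundle_trajectory(90, fix_geo)
  expect_true(all(b90$xy[, 2] >= 0))
  od_x <- fix_geo$optic_disc[1] * 1000 / 3.6
  for (bb in fix_map$bundles) {
    temporal <- bb$xy[, 1] < od_x
    if (bb$phi0 > 0) expect_true(all(bb$xy[temporal, 2] >= 0))
    else expect_true(all(bb$xy[temporal, 2] <= 0))
  }
})

test_that("axon maps have the requested bundle count and mirror symmetry", {
  m <- build_axon_map(fix_geo, phi0_samples = 60)
  expect_lte(length(m$bundles), 60L)
  expect_gte(length(m$bundles), 55L)  # few bundles may truncate to nothing
  geo_l <- subject_geometry(fix_geo$implant, fix_geo$array_center,
                           fix_geo$array_rotation, fix_geo$optic_disc,
                           eye = "left")
  ml <- build_axon_map(geo_l, phi0_samples = 60)
  expect_equal(ml$vx, -m$vx)
  expect_equal(ml$vy, m$vy)
})

test_that("nearest-bundle tangent agrees with a brute-force search", {
  set.seed(7)
  pts <- cbind(runif(25, -4000, 1000), runif(25, -3000, 3000))
  got <- nearest_bundle_tangent(pts, fix_map)
  for (i in seq_len(nrow(pts))) {
    d2 <- (fix_map$vx - pts[i, 1])^2 + (fix_map$vy - pts[i, 2])^2
    expect_equal(got[i], fix_map$tangent[which.min(d2)])
  }
  expect_true(all(got >= -90 & got < 90))
})

test_that("tangents are axial: reversing a polyline leaves them unchanged", {
  b <- bundle_trajectory(70, fix_geo)
  t1 <- phosphenes:::polyline_tangents(b$xy)
  t2 <- phosphenes:::polyline_tangents(b$xy[rev(seq_len(nrow(b$xy))), ])
  expect_equal(angular_error(t1, rev(t2)), rep(0, length(t1)),
               tolerance = 1e-9)
})

test_that("meridian points between fovea and disc see ~horizontal fibers", {
  # the smooth horizontal-tangent segment of the map lies on the nasal
  # meridian; query a point on it (see the methods vignette for why the
  # far-temporal raphe is excluded)
  expect_lt(abs(nearest_bundle_tangent(c(2222, 0), fix_map)), 15)
})

test_that("a point exactly on a vertex returns that vertex's tangent", {
  k <- 1234
  p <- c(fix_map$vx[k], fix_map$vy[k])
  expect_equal(nearest_bundle_tangent(p, fix_map), fix_map$tangent[k])
})

test_that("axon map exports as a tidy multi-polyline CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_axon_map(fix_map, tmp)
  df <- read.csv(tmp)
  expect_named(df, c("bundle", "vertex", "x_um", "y_um", "arclen_um"))
  expect_equal(nrow(df), length(fix_map$vx))
  expect_equal(df$x_um, fix_map$vx)
})
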