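test_that("scoreboard percept is an isotropic Gaussian with peak 1", {
  g <- percept_grid(c(-8, 8), c(-6, 6), 0.2)
  rho <- 400
  # put the electrode exactly on a pixel center
  rc <- phosphenes:::grid_retinal_coords(g)
  e <- c(rc$x[1000], rc$y[1000])
  img <- render_scoreboard(e, model_params(rho), g)
  expect_equal(max(img$values), 1)   # peak at the electrode pixel
  d2 <- (rc$x - e[1])^2 + (rc$y - e[2])^2
  expect_equal(as.vector(img$values), exp(-d2 / (2 * rho^2)))
  # value at retinal distance rho is exp(-1/2)
  at_rho <- which(abs(d2 - rho^2) < 1e-6)
  if (length(at_rho) > 0)
    expect_equal(as.vector(img$values)[at_rho],
                 rep(exp(-0.5), length(at_rho)))
  # radial symmetry: intensity depends only on distance
  o <- order(d2)
  expect_true(all(diff(as.vector(img$values)[o]) <= 1e-12))
})

test_that("thresholding at 1/sqrt(e) carves a disc of radius rho", {
  g <- percept_grid(c(-8, 8), c(-6, 6), 0.2)
  rho <- 500
  p <- threshold_percept(render_scoreboard(c(0, 0), model_params(rho), g))
  um_per_px <- g$pix * 1000 / g$deg_per_mm
  rc <- phosphenes:::grid_retinal_coords(g)
  r <- sqrt(rc$x^2 + rc$y^2)
  on <- as.vector(p$mask) == 1
  expect_lte(max(r[on]), rho + um_per_px)          # radius within 1 px
  expect_gte(min(r[!on]), rho - um_per_px)
  expect_lt(abs(sum(p$mask) * um_per_px^2 - pi * rho^2) / (pi * rho^2), 0.03)
})

test_that("threshold is monotone: higher threshold gives a subset", {
  g <- percept_grid(c(-14, 2), c(-8, 8), 0.4)
  img <- render_axon(c(-1331, -850), model_params(300, 900), fix_map, g)
  lo <- threshold_percept(img, 0.4)$mask
  hi <- threshold_percept(img, 0.8)$mask
  expect_true(all(hi <= lo))
  expect_error(threshold_percept(img, 1.5))
})

test_that("axon render on straight parallel bundles matches closed forms", {
  g <- percept_grid(c(-18, 6), c(-6, 6), 0.2)
  rho <- 350; lam <- 800
  rc <- phosphenes:::grid_retinal_coords(g)
  sm <- straight_map(ys = sort(unique(rc$y)))   # bundles on pixel rows
  eng <- axon_engine(sm, g, stride = 1, assign_stride = 1)
  e <- c(rc$x[which.min(abs(rc$x) + abs(rc$y))],
         rc$y[which.min(abs(rc$x) + abs(rc$y))])  # pixel nearest the origin
  img <- render_axon(e, model_params(rho, lam), sm, g, engine = eng)
  expect_equal(max(img$values), 1)
  vals <- as.vector(img$values)
  # soma peripheral on the stimulated bundle at distance d: the best path
  # sample sits between soma and electrode, giving the product-of-decays
  # profile exp(-d^2 / (2 (rho^2 + lambda^2))); disc-ward somas decay with
  # rho only (their axon path runs away from the electrode)
  on_bundle <- abs(rc$y - e[2]) < 1e-9
  d <- rc$x[on_bundle] - e[1]
  expected <- ifelse(d < 0, exp(-d^2 / (2 * (rho^2 + lam^2))),
                     exp(-d^2 / (2 * rho^2)))
  expect_equal(vals[on_bundle], expected, tolerance = 0.02)
  # orthogonal cross-section through the electrode decays with rho
  at_e <- abs(rc$x - e[1]) < 1e-9
  dy <- rc$y[at_e] - e[2]
  # each pixel's soma is its own bundle; best sample near the electrode's
  # x-position, soma distance |x_e - x_soma| = 0 there
  expect_equal(vals[at_e], exp(-dy^2 / (2 * rho^2)), tolerance = 0.02)
})

test_that("the infinite-lambda limit reduces to max-over-path scoreboard", {
  g <- percept_grid(c(-18, 6), c(-6, 6), 0.2)
  rc0 <- phosphenes:::grid_retinal_coords(g)
  sm <- straight_map(ys = sort(unique(rc0$y)))
  eng <- axon_engine(sm, g, stride = 1, assign_stride = 1)
  rho <- 350
  img <- render_axon(c(0, 0), model_params(rho, 1e9), sm, g, engine = eng)
  rc <- phosphenes:::grid_retinal_coords(g)
  # every soma peripheral to the electrode on its bundle sees the
  # electrode's full orthogonal response
  peripheral <- rc$x <= 0
  expect_equal(as.vector(img$values)[peripheral],
               exp(-(rc$y[peripheral]^2) / (2 * rho^2)), tolerance = 0.02)
})

test_that("euclidean and arclength soma distances agree on straight bundles", {
  sm <- straight_map()
  g <- percept_grid(c(-12, 4), c(-4, 4), 0.25)
  e1 <- axon_engine(sm, g, soma_distance = "arclength")
  e2 <- axon_engine(sm, g, soma_distance = "euclidean")
  i1 <- render_axon(c(-500, 100), model_params(300, 700), sm, g, engine = e1)
  i2 <- render_axon(c(-500, 100), model_params(300, 700), sm, g, engine = e2)
  expect_equal(i1$values, i2$values, tolerance = 0.05)
})

test_that("percepts near the nasal meridian are close to horizontal", {
  g <- percept_grid(c(-2, 16), c(-7, 7), 0.25)
  img <- render_axon(c(2500, 300), model_params(300, 1000), fix_map, g)
  s <- describe_shape(threshold_percept(img))
  expect_lt(abs(s$orientation), 10)
  expect_gt(s$elongation, 0.5)
})

test_that("distance series elongation shrinks as rho outgrows lambda", {
  g <- percept_grid(c(-2, 16), c(-7, 7), 0.25)
  r <- simulate_distance_series(c(2500, 300), c(300, 800, 1600), 500,
                                fix_map, g)
  expect_length(r$percepts, 3L)
  e <- r$descriptors$elongation
  expect_true(all(diff(e) <= 0))
  # identical rho twice gives identical percepts
  r2 <- simulate_distance_series(c(2500, 300), c(800, 800), 500, fix_map, g)
  expect_identical(r2$percepts[[1]]$mask, r2$percepts[[2]]$mask)
})
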