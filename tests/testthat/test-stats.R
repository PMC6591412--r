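# small hand-made drawing set: 4 electrodes x 3 trials of oriented ellipses
make_toy_ds <- function(orients, jitter = 0, seed = 1, n = 81,
                        trials = 3) {
  set.seed(seed)
  geo <- subject_geometry("argus_ii", c(-1331, -850), -28.4, c(16.2, 1.38))
  arr <- build_array(geo)
  k <- seq_len(length(orients))
  grid <- percept_grid(c(-8, 8), c(-8, 8), 16 / n)
  drawings <- lapply(k, function(i) {
    lapply(seq_len(trials), function(t) {
      ang <- orients[i] + if (jitter > 0) rnorm(1, 0, jitter) else 0
      ellipse_mask(n, 25, 6, ang = ang)
    })
  })
  names(drawings) <- arr$name[k]
  drawing_set(geo, grid, arr[k, c("name", "x", "y")], drawings)
}

test_that("identical drawings per electrode give zero observed SEM", {
  ds <- make_toy_ds(c(0, 30, 60, -60))
  for (d in c("area", "orientation", "elongation")) {
    r <- sem_consistency_test(ds, d, iters = 100, seed = 5)
    expect_equal(r$observed, 0)
    expect_length(r$null, 100)
    # distinct across electrodes only for orientation; its null is positive
    if (d == "orientation") {
      expect_equal(r$p, 1 / 101)   # minimal attainable p
      expect_gt(mean(r$null), 0)
    }
  }
})

test_that("fully exchangeable drawings give p near 1 under <=-counting", {
  # every drawing identical everywhere: observed = null = 0
  ds <- make_toy_ds(c(45, 45, 45, 45))
  r <- sem_consistency_test(ds, "orientation", iters = 50, seed = 2)
  expect_equal(r$observed, 0)
  expect_equal(r$null, rep(0, 50))
  expect_equal(r$p, 1)
})

test_that("strong per-electrode structure is detected at p < 0.05", {
  ds <- make_toy_ds(c(0, 45, 90 - 1e-9, -45), jitter = 4, seed = 9)
  r <- sem_consistency_test(ds, "orientation", iters = 1000, seed = 3)
  expect_lt(r$p, 0.05)
  # bit-reproducible given (seed, iters)
  r2 <- sem_consistency_test(ds, "orientation", iters = 1000, seed = 3)
  expect_identical(r$null, r2$null)
  expect_identical(r$p, r2$p)
})

test_that("alignment test recovers map-aligned drawings and NM1 is ~45deg", {
  ds <- make_toy_ds(c(0, 0, 0, 0))
  # draw each trial exactly along the local bundle tangent
  tans <- tangent_to_visual(nearest_bundle_tangent(
    as.matrix(ds$electrodes[, c("x", "y")]), fix_map))
  ds$drawings <- lapply(seq_along(tans), function(i)
    lapply(1:3, function(t) ellipse_mask(81, 25, 6, ang = tans[i])))
  names(ds$drawings) <- ds$electrodes$name
  r <- orientation_alignment_test(ds, fix_map, "NM1", iters = 1000, seed = 4)
  expect_lt(r$observed, 3)            # rasterisation error only
  expect_equal(r$p, 1 / 1001)         # never beaten by the null
  expect_equal(mean(r$null), 45, tolerance = 2)
  expect_length(r$null, 1000)
})

test_that("NM2 re-places the array and returns a valid resampling result", {
  ds <- make_toy_ds(c(10, 40, -20, 80), jitter = 5, seed = 13)
  r <- orientation_alignment_test(ds, fix_map, "NM2", iters = 200, seed = 6)
  expect_length(r$null, 200)
  expect_gte(r$p, 0)
  expect_lte(r$p, 1)
  expect_true(all(r$null >= 0 & r$null <= 90))
  r2 <- orientation_alignment_test(ds, fix_map, "NM2", iters = 200, seed = 6)
  expect_identical(r$null, r2$null)
})

test_that("orientation variance explained has its fixed points", {
  ds <- make_toy_ds(c(0, 0, 0, 0))
  tans <- tangent_to_visual(nearest_bundle_tangent(
    as.matrix(ds$electrodes[, c("x", "y")]), fix_map))
  ds$drawings <- lapply(seq_along(tans), function(i)
    lapply(1:3, function(t) ellipse_mask(201, 60, 12, ang = tans[i])))
  names(ds$drawings) <- ds$electrodes$name
  expect_gt(orientation_variance_explained(ds, fix_map), 0.97)
  # a map that predicts only the mean orientation explains ~nothing
  ds2 <- make_toy_ds(c(20, -20, 50, -50), jitter = 0)
  mean_map <- fix_map
  mean_map$tangent <- rep(tangent_to_visual(
    axial_mean(describe_drawings(ds2)$orientation)), length(fix_map$tangent))
  r2 <- orientation_variance_explained(ds2, mean_map)
  expect_lt(abs(r2), 0.1)
})

test_that("elongation-area correlation flags degenerate inputs", {
  d <- data.frame(area = c(10, 20, 30, 40), elongation = c(0.9, 0.7, 0.5, 0.3))
  r <- elongation_area_correlation(d)
  expect_equal(r$r, -1, tolerance = 1e-12)
  d2 <- data.frame(area = 1:10, elongation = rep(0.5, 10))
  expect_warning(r2 <- elongation_area_correlation(d2), "zero variance")
  expect_true(is.na(r2$r))
  set.seed(21)
  d3 <- data.frame(area = rnorm(500), elongation = rnorm(500))
  expect_lt(abs(elongation_area_correlation(d3)$r), 0.15)
  expect_error(elongation_area_correlation(d[1:2, ]), "3")
})
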