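test_that("descriptor R^2 matches hand-computed sums", {
  obs <- c(3, 1, 4, 1, 5)
  expect_equal(descriptor_r2(obs, obs), 1)
  expect_equal(descriptor_r2(obs, rep(mean(obs), 5)), 0)
  pred <- c(2, 2, 3, 2, 4)
  expect_equal(descriptor_r2(obs, pred),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  # axial mode wraps residuals
  expect_equal(descriptor_r2(c(85, -85, 10), c(-85, 85, 10), axial = TRUE),
               1 - (100 + 100) /
                 sum(wrap_axial(c(85, -85, 10) -
                                  axial_mean(c(85, -85, 10)))^2),
               tolerance = 1e-12)
  expect_warning(r <- descriptor_r2(c(1, 1), c(1, 2)), "zero")
  expect_true(is.na(r))
})

test_that("batch mask descriptors equal the per-image implementation", {
  set.seed(31)
  n <- 40
  imgs <- lapply(1:6, function(i) matrix(rbinom(n * n, 1, 0.2), n, n))
  B <- vapply(imgs, as.vector, numeric(n * n))
  xc <- rep(seq_len(n) - 1, each = n)
  yc <- rep(seq_len(n) - 1, times = n)
  basis <- cbind(1, xc, yc, xc^2, yc^2, xc * yc)
  got <- phosphenes:::mask_descriptors(B, basis)
  for (i in 1:6) {
    s <- describe_shape(imgs[[i]])
    expect_equal(got$area[i], s$area)
    expect_equal(got$orientation[i], s$orientation, tolerance = 1e-9)
    expect_equal(got$elongation[i], s$elongation, tolerance = 1e-9)
  }
})

test_that("noiseless drawings at the true parameters give zero cost", {
  cfg0 <- synth_config(n_electrodes = 4, rho = 300, lam = 900,
                       centroid_sd = 0, orientation_sd = 0,
                       area_scale_sd = 0, roughness = 0, seed = 8)
  gen0 <- generate_drawings(fix_sub$geometry, fix_sub$map, cfg0, fix_grid)
  ctx0 <- fit_context(gen0$ds, fix_sub$map, fix_grid)
  c0 <- percept_cost(model_params(300, 900), "axon_map", ctx = ctx0)
  expect_equal(c0, 0)
  # and parameters far from the truth cost more
  expect_gt(percept_cost(model_params(1500, 200), "axon_map", ctx = ctx0), c0)
})

test_that("cost decreases toward the generator truth on noisy data", {
  ctx <- fit_context(fix_ds, fix_sub$map, fix_grid)
  c_true <- percept_cost(model_params(300, 900), "axon_map", ctx = ctx)
  c_mid <- percept_cost(model_params(600, 1800), "axon_map", ctx = ctx)
  c_far <- percept_cost(model_params(1800, 4000), "axon_map", ctx = ctx)
  expect_lt(c_true, c_mid)
  expect_lt(c_mid, c_far)
})

test_that("particle swarm is deterministic and recovers scoreboard data", {
  # drawings that are literally scoreboard percepts at rho* = 300
  geo <- fix_sub$geometry
  arr <- build_array(geo)
  idx <- c(14, 25, 33, 46)
  drawings <- lapply(idx, function(i) {
    list(threshold_percept(render_scoreboard(c(arr$x[i], arr$y[i]),
                                             model_params(300),
                                             fix_grid))$mask)
  })
  names(drawings) <- arr$name[idx]
  ds <- drawing_set(geo, fix_grid, arr[idx, c("name", "x", "y")], drawings)
  ctx <- fit_context(ds)
  fit <- pso_fit("scoreboard", ctx = ctx, seed = 17,
                 control = list(maxit = 40))
  expect_lt(abs(fit$rho - 300) / 300, 0.1)
  fit2 <- pso_fit("scoreboard", ctx = ctx, seed = 17,
                  control = list(maxit = 40))
  expect_identical(fit$rho, fit2$rho)
  expect_identical(attr(fit, "restart_costs"), attr(fit2, "restart_costs"))
  expect_length(attr(fit, "restart_costs"), 5L)   # five restarts
})

test_that("leave-one-electrode-out produces one fold per electrode", {
  ctx <- fit_context(fix_ds, fix_sub$map, fix_grid)
  cv <- loeo_cv("axon_map", ctx = ctx, seed = 5,
                control = list(maxit = 12, stall = 6))
  expect_equal(nrow(cv$folds), length(fix_ds$drawings))
  expect_setequal(cv$folds$electrode, names(fix_ds$drawings))
  expect_true(all(cv$folds$cv_cost >= 0))
  expect_true(all(cv$folds$fit_cost >= 0))
  # clean synthetic data: parameters nearly constant across folds
  expect_lt(cv$summary$rho_sem / cv$summary$rho_mean, 0.1)
  expect_lt(cv$summary$lam_sem / cv$summary$lam_mean, 0.1)
})

test_that("model comparison handles ties, sign and small samples", {
  f <- structure(list(model = "axon_map",
                      folds = data.frame(electrode = letters[1:5],
                                         cv_cost = c(1, 2, 3, 4, 5))),
                 class = "fit_result")
  same <- compare_models(f, f)
  expect_equal(same$p, 1)
  expect_equal(same$statistic, 0)
  g <- f
  g$folds$cv_cost <- f$folds$cv_cost * 2
  ab <- compare_models(f, g)
  ba <- compare_models(g, f)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$n, 5L)
  h <- f
  h$folds$electrode <- letters[6:10]
  expect_error(compare_models(f, h), "different electrodes")
})
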