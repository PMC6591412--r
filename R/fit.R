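#' Coefficient of determination for a shape descriptor
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with
#' \eqn{SS_{res} = \sum_i (s_i - \hat s_i)^2} and
#' \eqn{SS_{tot} = \sum_i (s_i - \bar s)^2}. For orientation descriptors the
#' residuals (and deviations from the mean) are wrapped axially to
#' \eqn{[-90, 90)} and the mean is the circular doubled-angle mean.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 values).
#' @param axial Treat the values as axial angles in degrees.
#' @param ss_tot Optional externally supplied total sum of squares (e.g.
#'   from a training set when scoring held-out data).
#' @return \eqn{R^2} (may be negative). `NA` with a warning if the total
#'   sum of squares is zero.
#' @export
descriptor_r2 <- function(observed, predicted, axial = FALSE, ss_tot = NULL) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  res <- if (axial) wrap_axial(observed - predicted) else observed - predicted
  if (is.null(ss_tot)) {
    dev <- if (axial) wrap_axial(observed - axial_mean(observed))
           else observed - mean(observed)
    ss_tot <- sum(dev^2)
  }
  if (ss_tot == 0) {
    warning("zero total sum of squares; R^2 undefined")
    return(NA_real_)
  }
  1 - sum(res^2) / ss_tot
}

# vectorised shape descriptors for a 0/1 matrix of flattened masks
# (pixels x images). `basis` is the npix x 6 moment basis
# (1, x, y, x^2, y^2, xy) in 0-based pixel coordinates, so that all raw
# moments up to order 2 come from a single matrix product.
mask_descriptors <- function(B, basis) {
  storage.mode(B) <- "double"
  M <- crossprod(basis, B)                 # 6 x n_images
  m00 <- M[1, ]
  mx <- M[2, ];  my <- M[3, ]
  mxx <- M[4, ]; myy <- M[5, ]; mxy <- M[6, ]
  xb <- mx / m00; yb <- my / m00
  mu20 <- mxx / m00 - xb^2
  mu02 <- myy / m00 - yb^2
  mu11 <- mxy / m00 - xb * yb
  theta <- ifelse(mu20 == mu02 & mu11 == 0, 0,
                  wrap_axial(0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi))
  disc <- sqrt(4 * mu11^2 + (mu20 - mu02)^2) / 2
  l1 <- (mu20 + mu02) / 2 + disc
  l2 <- (mu20 + mu02) / 2 - disc
  elong <- ifelse(l1 <= 0, 0, sqrt(pmin(pmax(1 - l2 / l1, 0), 1)))
  empty <- m00 <= 0
  theta[empty] <- NA_real_
  elong[empty] <- NA_real_
  list(area = m00, orientation = theta, elongation = elong)
}

#' Precomputed fitting context
#'
#' Bundles everything the cost function needs that does not depend on the
#' model parameters: the observed descriptor table, electrode positions,
#' the axon-path engine for the map/grid pair, and per-electrode pixel
#' distances for the scoreboard model. Build it once per subject and pass
#' it to [percept_cost()], [pso_fit()] and [loeo_cv()].
#'
#' @param ds A [drawing_set()].
#' @param map The subject's [build_axon_map()] (may be `NULL` if only the
#'   scoreboard model is used).
#' @param grid Rendering [percept_grid()]; defaults to the drawing grid.
#' @param threshold Binarisation threshold for predicted percepts.
#' @param ... Passed to [axon_engine()].
#' @return An object of class `fit_context`.
#' @export
fit_context <- function(ds, map = NULL, grid = NULL,
                        threshold = exp(-0.5), ...) {
  stopifnot(inherits(ds, "drawing_set"))
  if (is.null(grid)) grid <- ds$grid
  obs <- describe_drawings(ds)
  enames <- ds$electrodes$name
  rc <- grid_retinal_coords(grid, ds$geometry$eye)
  ny <- grid$ny
  npix <- ny * grid$nx
  xc <- rep(seq_len(grid$nx) - 1, each = ny)   # 0-based column coord
  yc <- rep(seq_len(ny) - 1, times = grid$nx)  # 0-based row coord
  basis <- cbind(1, xc, yc, xc^2, yc^2, xc * yc)
  d2 <- outer(rc$x, ds$electrodes$x, "-")^2 +
        outer(rc$y, ds$electrodes$y, "-")^2
  engine <- if (!is.null(map)) axon_engine(map, grid, ds$geometry$eye, ...)
  structure(list(ds = ds, obs = obs, enames = enames,
                 ex = ds$electrodes$x, ey = ds$electrodes$y,
                 grid = grid, threshold = threshold,
                 basis = basis, d2 = d2, engine = engine),
            class = "fit_context")
}

# predicted descriptors for a subset of electrodes under given parameters
predict_descriptors <- function(ctx, model, rho, lam = NULL,
                                which_e = seq_along(ctx$enames)) {
  thr <- ctx$threshold
  if (model == "scoreboard") {
    # exp(-d2/(2 rho^2)) >= thr  <=>  d2 <= -2 rho^2 log(thr)
    B <- ctx$d2[, which_e, drop = FALSE] <= -2 * rho^2 * log(thr)
  } else {
    if (is.null(ctx$engine)) stop("fit_context was built without an axon map")
    L <- axon_log_intensity(ctx$engine, ctx$ex[which_e], ctx$ey[which_e],
                            rho, lam)
    cm <- apply(L, 2, max)
    B <- L >= rep(cm + log(thr), each = nrow(L))
    B[, !is.finite(cm)] <- FALSE
  }
  d <- mask_descriptors(B, ctx$basis)
  lapply(d, function(v) { names(v) <- ctx$enames[which_e]; v })
}

# descriptor-wise squared residuals of observed drawings against their
# electrode's prediction; empty predictions get worst-case residuals
descriptor_residuals <- function(obs, pred) {
  e <- obs$electrode
  pa <- pred$area[e]; po <- pred$orientation[e]; pe <- pred$elongation[e]
  empty <- pa <= 0
  r_area <- obs$area - pa
  r_orient <- ifelse(empty | is.na(po), 90, angular_error(obs$orientation, po))
  r_orient[is.na(obs$orientation)] <- NA
  r_elong <- ifelse(empty | is.na(pe),
                    pmax(obs$elongation, 1 - obs$elongation),
                    obs$elongation - pe)
  list(area = r_area, orientation = r_orient, elongation = r_elong)
}

# total sums of squares of the three descriptors over a descriptor table
# (drawings with undefined descriptors are excluded)
descriptor_ss_tot <- function(obs) {
  a <- obs$area[!is.na(obs$area)]
  o <- obs$orientation[!is.na(obs$orientation)]
  e <- obs$elongation[!is.na(obs$elongation)]
  list(area = sum((a - mean(a))^2),
       orientation = sum(wrap_axial(o - axial_mean(o))^2),
       elongation = sum((e - mean(e))^2))
}

#' Model cost for a drawing set
#'
#' The fitting cost \eqn{c = \sum_d (1 - R_d^2)} summed over the three
#' shape descriptors (area, orientation, elongation). Each drawing is
#' compared against the predicted percept of its electrode; position is not
#' compared (the descriptors are location-free). Electrodes whose predicted
#' percept is empty contribute worst-case residuals.
#'
#' @param params A [model_params()].
#' @param model `"axon_map"` or `"scoreboard"`.
#' @param ds A [drawing_set()] (ignored if `ctx` is given).
#' @param map,grid Used to build a context when `ctx` is missing.
#' @param ctx Optional prebuilt [fit_context()].
#' @return The cost, a nonnegative number (3 when every descriptor is
#'   predicted no better than its mean).
#' @export
percept_cost <- function(params, model = c("axon_map", "scoreboard"),
                         ds = NULL, map = NULL, grid = NULL, ctx = NULL) {
  model <- match.arg(model)
  if (is.null(ctx)) ctx <- fit_context(ds, map, grid,
                                       threshold = params$threshold)
  cost_eval(ctx, model, c(params$rho, params$lam),
            which_e = seq_along(ctx$enames), obs = ctx$obs,
            ss_tot = descriptor_ss_tot(ctx$obs))
}

# internal fast path: cost of parameter vector p on a subset of electrodes
cost_eval <- function(ctx, model, p, which_e, obs, ss_tot) {
  pred <- predict_descriptors(ctx, model, rho = p[1],
                              lam = if (length(p) > 1) p[2], which_e)
  res <- descriptor_residuals(obs, pred)
  total <- 0
  for (d in c("area", "orientation", "elongation")) {
    st <- ss_tot[[d]]
    if (st <= 0) next   # degenerate descriptor carries no information
    total <- total + sum(res[[d]]^2, na.rm = TRUE) / st
  }
  total
}

# global-best particle swarm minimiser
pso_minimize <- function(fn, lower, upper, n_particles, maxit = 100,
                         inertia = 0.7, cognitive = 1.5, social = 1.5,
                         tol = 1e-6, stall = 15) {
  d <- length(lower)
  rng <- upper - lower
  X <- vapply(seq_len(d),
              function(k) runif(n_particles, lower[k], upper[k]),
              numeric(n_particles))
  X <- matrix(X, n_particles, d)
  V <- matrix(runif(n_particles * d, -1, 1), n_particles, d) *
    rep(rng / 10, each = n_particles)
  evalf <- function(M) apply(M, 1, fn)
  f <- evalf(X)
  bad <- !is.finite(f)
  while (any(bad)) {   # resample particles with non-finite cost
    X[bad, ] <- vapply(seq_len(d),
                       function(k) runif(sum(bad), lower[k], upper[k]),
                       numeric(sum(bad)))
    f[bad] <- apply(X[bad, , drop = FALSE], 1, fn)
    bad <- !is.finite(f)
  }
  P <- X; pf <- f
  g <- which.min(pf)
  gx <- P[g, ]; gf <- pf[g]
  since <- 0L
  for (it in seq_len(maxit)) {
    r1 <- matrix(runif(n_particles * d), n_particles, d)
    r2 <- matrix(runif(n_particles * d), n_particles, d)
    V <- inertia * V + cognitive * r1 * (P - X) +
      social * r2 * (rep(1, n_particles) %o% gx - X)
    vmax <- rep(rng / 2, each = n_particles)
    V <- pmin(pmax(V, -vmax), vmax)
    X <- X + V
    low <- rep(lower, each = n_particles)
    upp <- rep(upper, each = n_particles)
    out <- X < low | X > upp
    X <- pmin(pmax(X, low), upp)
    V[out] <- 0
    f <- evalf(X)
    f[!is.finite(f)] <- Inf
    imp <- f < pf
    P[imp, ] <- X[imp, ]
    pf[imp] <- f[imp]
    g <- which.min(pf)
    if (pf[g] < gf - tol) since <- 0L else since <- since + 1L
    if (pf[g] < gf) { gf <- pf[g]; gx <- P[g, ] }
    if (since >= stall) break
  }
  list(par = gx, value = gf, iterations = it)
}

default_bounds <- function(model) {
  if (model == "scoreboard") list(lower = 10, upper = 3000)
  else list(lower = c(10, 10), upper = c(3000, 5000))
}

#' Fit percept-model parameters with particle-swarm optimisation
#'
#' Minimises [percept_cost()] over `rho` (scoreboard) or `(rho, lam)`
#' (axon map) with a global-best particle swarm: swarm size is ten times
#' the number of parameters, and the whole search is restarted five times
#' from random initial conditions, keeping the best run. Results are
#' deterministic given `seed`.
#'
#' @inheritParams percept_cost
#' @param bounds List with `lower` and `upper` parameter bounds (microns);
#'   defaults to rho in \[10, 3000\] and lam in \[10, 5000\].
#' @param seed Integer seed.
#' @param control Optional overrides: `maxit`, `inertia`, `cognitive`,
#'   `social`, `tol`, `stall`, `restarts`, `swarm_mult`.
#' @param obs,ss_tot Internal use (training-subset fitting in
#'   cross-validation).
#' @param which_e Indices of the electrodes to fit on (default: all).
#' @return A [model_params()] with attributes `cost` (best cost),
#'   `restart_costs` and `control`.
#' @export
pso_fit <- function(model = c("axon_map", "scoreboard"), ds = NULL,
                    map = NULL, grid = NULL, ctx = NULL, bounds = NULL,
                    seed = 1, control = list(),
                    which_e = NULL, obs = NULL, ss_tot = NULL) {
  model <- match.arg(model)
  if (is.null(ctx)) ctx <- fit_context(ds, map, grid)
  if (is.null(bounds)) bounds <- default_bounds(model)
  if (is.null(which_e)) which_e <- seq_along(ctx$enames)
  if (is.null(obs)) obs <- ctx$obs[ctx$obs$electrode %in%
                                     ctx$enames[which_e], ]
  if (is.null(ss_tot)) ss_tot <- descriptor_ss_tot(obs)
  ctl <- modifyList(list(maxit = 100, inertia = 0.7, cognitive = 1.5,
                         social = 1.5, tol = 1e-6, stall = 15,
                         restarts = 5, swarm_mult = 10), control)
  npar <- length(bounds$lower)
  fn <- function(p) cost_eval(ctx, model, p, which_e, obs, ss_tot)
  set.seed(seed)
  runs <- lapply(seq_len(ctl$restarts), function(i) {
    pso_minimize(fn, bounds$lower, bounds$upper,
                 n_particles = ctl$swarm_mult * npar, maxit = ctl$maxit,
                 inertia = ctl$inertia, cognitive = ctl$cognitive,
                 social = ctl$social, tol = ctl$tol, stall = ctl$stall)
  })
  vals <- vapply(runs, `[[`, 0, "value")
  best <- runs[[which.min(vals)]]
  out <- model_params(rho = best$par[1],
                      lam = if (npar > 1) best$par[2],
                      threshold = ctx$threshold)
  attr(out, "cost") <- best$value
  attr(out, "restart_costs") <- vals
  attr(out, "control") <- ctl
  out
}

#' Leave-one-electrode-out cross-validation
#'
#' For each electrode, fits the model to the drawings of all other
#' electrodes ([pso_fit()]) and scores the held-out electrode's drawings
#' with the fitted parameters. The held-out cost is the descriptor-wise
#' mean squared residual normalised by the training-set descriptor variance
#' (the training total sum of squares per observation), summed over the
#' three descriptors -- the cross-validated analogue of the fitting cost.
#' A single (rho, lam) pair is fitted per fold for the whole array.
#'
#' @inheritParams pso_fit
#' @return An object of class `fit_result` with `folds` (data frame:
#'   held-out electrode, fitted parameters, fit and held-out costs) and
#'   `summary` (mean and SEM of each parameter across folds).
#' @export
loeo_cv <- function(model = c("axon_map", "scoreboard"), ds = NULL,
                    map = NULL, grid = NULL, ctx = NULL, bounds = NULL,
                    seed = 1, control = list()) {
  model <- match.arg(model)
  if (is.null(ctx)) ctx <- fit_context(ds, map, grid)
  ne <- length(ctx$enames)
  stopifnot(ne >= 2L)
  folds <- lapply(seq_len(ne), function(i) {
    fold_seed <- (seed + 7919 * i) %% 2147483647
    train <- setdiff(seq_len(ne), i)
    obs_tr <- ctx$obs[ctx$obs$electrode %in% ctx$enames[train], ]
    ss_tr <- descriptor_ss_tot(obs_tr)
    fit <- tryCatch(
      pso_fit(model, ctx = ctx, bounds = bounds, seed = fold_seed,
              control = control, which_e = train, obs = obs_tr,
              ss_tot = ss_tr),
      error = function(e) {
        warning("fold ", ctx$enames[i], " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) {
      return(data.frame(electrode = ctx$enames[i], rho = NA, lam = NA,
                        fit_cost = NA, cv_cost = NA))
    }
    obs_te <- ctx$obs[ctx$obs$electrode == ctx$enames[i], ]
    pred <- predict_descriptors(ctx, model, fit$rho, fit$lam, which_e = i)
    res <- descriptor_residuals(obs_te, pred)
    n_tr <- nrow(obs_tr)
    cv <- 0
    for (d in c("area", "orientation", "elongation")) {
      v <- ss_tr[[d]] / n_tr
      if (v <= 0) next
      cv <- cv + mean(res[[d]]^2, na.rm = TRUE) / v
    }
    data.frame(electrode = ctx$enames[i], rho = fit$rho,
               lam = if (is.null(fit$lam)) NA_real_ else fit$lam,
               fit_cost = attr(fit, "cost"), cv_cost = cv)
  })
  folds <- do.call(rbind, folds)
  smry <- list(rho_mean = mean(folds$rho, na.rm = TRUE),
               rho_sem = sd(folds$rho, na.rm = TRUE) /
                 sqrt(sum(!is.na(folds$rho))),
               lam_mean = mean(folds$lam, na.rm = TRUE),
               lam_sem = sd(folds$lam, na.rm = TRUE) /
                 sqrt(sum(!is.na(folds$lam))),
               mean_cv_cost = mean(folds$cv_cost, na.rm = TRUE))
  structure(list(model = model, folds = folds, summary = smry,
                 seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("fit_result (%s): %d folds\n", x$model, nrow(x$folds)))
  cat(sprintf("  rho = %.0f +/- %.0f um\n", s$rho_mean, s$rho_sem))
  if (!is.na(s$lam_mean))
    cat(sprintf("  lam = %.0f +/- %.0f um\n", s$lam_mean, s$lam_sem))
  cat(sprintf("  mean held-out cost = %.3f\n", s$mean_cv_cost))
  invisible(x)
}

#' Compare two cross-validated model fits
#'
#' Paired two-sided Wilcoxon signed-rank test on the per-electrode log
#' held-out costs of two [loeo_cv()] results over the same electrodes. The
#' reported `statistic` is the signed rank sum (positive when the first
#' model has the higher prediction error), so swapping the inputs flips its
#' sign. All-zero differences yield p = 1.
#'
#' @param fit_a,fit_b `fit_result` objects over identical electrode sets.
#' @param eps Offset inside the log to guard against zero costs.
#' @return A list with `statistic`, `p`, `log_diffs` (per-electrode
#'   `log(cost_a) - log(cost_b)`) and `n`.
#' @export
compare_models <- function(fit_a, fit_b, eps = 1e-9) {
  stopifnot(inherits(fit_a, "fit_result"), inherits(fit_b, "fit_result"))
  m <- match(fit_a$folds$electrode, fit_b$folds$electrode)
  if (anyNA(m)) stop("fits cover different electrodes")
  la <- log(fit_a$folds$cv_cost + eps)
  lb <- log(fit_b$folds$cv_cost[m] + eps)
  d <- la - lb
  d <- d[!is.na(d)]
  n <- length(d)
  nz <- d[d != 0]
  w <- if (length(nz) == 0) 0 else
    sum(sign(nz) * rank(abs(nz)))
  p <- if (length(nz) == 0) 1 else
    wilcox.test(nz, alternative = "two.sided", exact = n < 6)$p.value
  list(statistic = w, p = p, log_diffs = d, n = n)
}
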