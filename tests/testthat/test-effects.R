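test_that("the natural spline basis has df columns and linear tails", {
  set.seed(1)
  x <- runif(200, 40, 95)
  B <- ncs_basis(x, df = 3)
  expect_equal(ncol(B), 3)
  # fit an arbitrary coefficient combination and check zero curvature
  # outside the boundary knots via second differences on a fine grid
  beta <- c(1.3, -0.7, 2.1)
  spec <- attr(B, "ncs_spec")
  grid <- seq(spec$boundary[2], spec$boundary[2] + 20, length.out = 50)
  f <- drop(qrfcost:::ncs_eval(B, grid) %*% beta)
  expect_lt(max(abs(diff(diff(f)))), 1e-6)
  grid_lo <- seq(spec$boundary[1] - 20, spec$boundary[1], length.out = 50)
  f_lo <- drop(qrfcost:::ncs_eval(B, grid_lo) %*% beta)
  expect_lt(max(abs(diff(diff(f_lo)))), 1e-6)
  expect_error(ncs_basis(c(1, 1, 2, 2), df = 3), "distinct")
})

test_that("the basis spans natural interpolating splines exactly", {
  pts_x <- c(40, 55, 68, 80, 95)
  pts_y <- c(2.0, 5.5, 3.0, 4.2, 1.0)
  # reference natural spline from the banded interpolation system
  ref <- splinefun(pts_x, pts_y, method = "natural")
  grid <- seq(40, 95, length.out = 201)
  B <- ncs_basis(grid, df = 4, knots = pts_x[2:4], boundary = pts_x[c(1, 5)])
  fit <- lm.fit(cbind(1, B), ref(grid))
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("intercept-only quantile regression returns an optimal constant", {
  set.seed(2)
  y <- rlnorm(41, 9, 1)
  for (tau in c(0.1, 0.5, 0.9)) {
    b <- fit_linear_qr(matrix(1, 41, 1), y, tau)
    opt <- sum(pinball_loss(y, sample_quantile_inf(y, tau), tau))
    expect_lte(attr(b, "objective"), opt * (1 + 1e-10))
  }
})

test_that("a single binary covariate recovers the two group quantiles", {
  set.seed(3)
  g <- rep(0:1, c(30, 30))
  y <- c(rlnorm(30, 8), rlnorm(30, 9))
  X <- cbind(1, g)
  for (tau in c(0.25, 0.5, 0.75)) {
    b <- fit_linear_qr(X, y, tau)
    # optimum certified against enumeration of group-quantile candidates
    cands <- expand.grid(q0 = y[g == 0], q1 = y[g == 1])
    objs <- mapply(function(q0, q1)
      sum(pinball_loss(y, ifelse(g == 1, q1, q0), tau)),
      cands$q0, cands$q1)
    expect_lte(attr(b, "objective"), min(objs) * (1 + 1e-8))
  }
})

test_that("the IRLS objective is certified optimal on small instances", {
  set.seed(4)
  for (rep in 1:6) {
    n <- 14; p <- 2
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- drop(X %*% rnorm(p)) + rt(n, 3)
    tau <- sample(c(0.1, 0.3, 0.5, 0.7, 0.9), 1)
    b <- fit_linear_qr(X, y, tau)
    expect_lte(attr(b, "objective"), bf_qr_optimum(X, y, tau) * (1 + 1e-6))
  }
})

test_that("quantile regression is equivariant to response scaling", {
  set.seed(5)
  X <- cbind(1, rnorm(60), rbinom(60, 1, 0.4))
  y <- drop(X %*% c(2, 1, -3)) + rlnorm(60)
  for (tau in c(0.2, 0.8)) {
    b1 <- fit_linear_qr(X, y, tau)
    b2 <- fit_linear_qr(X, 100 * y, tau)
    expect_equal(as.numeric(b2), 100 * as.numeric(b1), tolerance = 1e-6)
  }
  ci1 <- bootstrap_ci(X, y, 0.5, B = 200, seed = 9)
  ci2 <- bootstrap_ci(X, 100 * y, 0.5, B = 200, seed = 9)
  expect_equal(ci2$ci_low, 100 * ci1$ci_low, tolerance = 1e-6)
  expect_equal(ci2$ci_high, 100 * ci1$ci_high, tolerance = 1e-6)
})

test_that("the median fit minimizes least absolute deviations", {
  set.seed(6)
  n <- 12
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  b <- fit_linear_qr(X, y, 0.5)
  # objective at tau = 0.5 is half the sum of absolute deviations
  expect_equal(2 * attr(b, "objective"),
               2 * bf_qr_optimum(X, y, 0.5), tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected naming collinear columns", {
  X <- cbind(a = rep(1, 20), b = rnorm(20))
  X <- cbind(X, c = X[, "b"] * 2)
  expect_error(fit_linear_qr(X, rnorm(20), 0.5), "c")
})

test_that("bootstrap intervals are deterministic and collapse on exact fits", {
  set.seed(7)
  X <- cbind(1, rnorm(30))
  beta <- c(4, -2)
  y <- drop(X %*% beta)                      # no residual variability
  ci <- bootstrap_ci(X, y, 0.7, B = 200, seed = 3)
  expect_equal(ci$ci_low, ci$ci_high, tolerance = 1e-7)
  expect_equal(ci$estimate, beta, tolerance = 1e-7)
  y2 <- y + rlnorm(30)
  c1 <- bootstrap_ci(X, y2, 0.5, B = 200, seed = 5)
  c2 <- bootstrap_ci(X, y2, 0.5, B = 200, seed = 5)
  expect_identical(c1, c2)
})

test_that("the effect table is shaped like the published coefficient tables", {
  tab <- toy_episodes(500, seed = 8)
  sel <- c("chemo_drug", "comorbidity_cat", "age")
  et <- effect_table(tab, sel, taus = c(0.25, 0.75), B = 200, seed = 9)
  expect_s3_class(et, "quantile_effect_table")
  # intercept + 1 + 5 + 1 terms per tau
  expect_equal(nrow(et), 2 * 8)
  expect_setequal(unique(et$covariate), c("(Intercept)", sel))
  expect_equal(unique(et$level[et$covariate == "comorbidity_cat"]),
               c("1", "2", "3", ">=4", "new_enrollee"))
  expect_true(all(et$ci_low <= et$estimate + 1e-9))
  expect_true(all(et$estimate <= et$ci_high + 1e-9))
  expect_error(effect_table(tab, character(0)), "empty")
})

test_that("spline effect curves vanish at the reference value", {
  tab <- toy_episodes(400, seed = 10)
  cur <- spline_effect_curves(tab, c("chemo_drug", "age"), covariate = "age",
                              taus = c(0.5, 0.9), ref = 70)
  expect_setequal(unique(cur$tau), c(0.5, 0.9))
  for (tau in c(0.5, 0.9)) {
    sub <- cur[cur$tau == tau, ]
    at_ref <- approx(sub$value, sub$effect, xout = 70)$y
    expect_lt(abs(at_ref), 0.3)  # grid interpolation near the exact zero
  }
})
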