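test_that("default generator emits the full study-sized table", {
  tab <- generate_episodes(default_generator_config(seed = 4))
  expect_equal(nrow(tab), 2938)
  expect_setequal(names(tab), c(covariate_names(), "cost"))
  expect_false(anyNA(tab))
  expect_true(all(tab$cost >= 461.09 & tab$cost <= 71185.40))
})

test_that("identical config and seed reproduce a bit-identical table", {
  a <- generate_episodes(default_generator_config(n_episodes = 300, seed = 7))
  b <- generate_episodes(default_generator_config(n_episodes = 300, seed = 7))
  attr(a, "config") <- attr(b, "config") <- NULL
  expect_identical(a, b)
})

test_that("noise-free limit returns the pure location part", {
  cfg <- generator_config(
    n_episodes = 50,
    location_coefs = c("chemo_drug.PartB" = 20, "surgery.yes" = 5, age = -1),
    scale_coefs = c(),
    base_location = 6, base_scale = 1,
    noise = noise_law("degenerate"), winsor = NULL, seed = 3
  )
  tab <- generate_episodes(cfg)
  loc <- 6 + 20 * (tab$chemo_drug == "PartB") + 5 * (tab$surgery == "yes") -
    1 * (tab$age - 72) / 10
  expect_equal(tab$cost, 1000 * loc, tolerance = 1e-12)
})

test_that("median-zero noise makes the tau = 0.5 quantile the location part", {
  cfg <- generator_config(
    n_episodes = 10,
    location_coefs = c("radiation.yes" = 4, hrr_relative_cost = 2),
    scale_coefs = c("radiation.yes" = 1),
    base_location = 5, base_scale = 3,
    noise = noise_law("snorm"), winsor = NULL, seed = 1
  )
  x <- generate_episodes(cfg)[1, covariate_names()]
  loc <- 5 + 4 * (x$radiation == "yes") + 2 * x$hrr_relative_cost / 30
  expect_equal(true_conditional_quantile(cfg, x, 0.5), 1000 * loc,
               tolerance = 1e-12)
})

test_that("with homoscedastic scale a covariate shifts all quantiles by b_j", {
  cfg <- generator_config(
    n_episodes = 10,
    location_coefs = c("chemo_drug.PartB" = 17),
    scale_coefs = c(),
    base_location = 5, base_scale = 4, seed = 1, winsor = NULL
  )
  x0 <- generate_episodes(cfg)[1, covariate_names()]
  x0$chemo_drug <- "PartD"
  x1 <- x0; x1$chemo_drug <- "PartB"
  for (tau in c(0.05, 0.3, 0.5, 0.8, 0.99)) {
    expect_equal(true_conditional_quantile(cfg, x1, tau) -
                 true_conditional_quantile(cfg, x0, tau),
                 17000, tolerance = 1e-9)
  }
})

test_that("closed-form conditional quantile matches brute-force simulation", {
  cfg <- default_generator_config(seed = 2, winsorize = FALSE)
  x <- generate_episodes(default_generator_config(n_episodes = 5, seed = 2))[3,
         covariate_names()]
  set.seed(99)
  sigma <- cfg$noise$sigma
  m1 <- exp(sigma^2 / 2); sdl <- sqrt((exp(sigma^2) - 1) * exp(sigma^2))
  eps <- (exp(sigma * rnorm(1e6)) - m1) / sdl
  loc_med <- true_conditional_quantile(cfg, x, 0.5)
  sc <- (true_conditional_quantile(cfg, x, 0.9) - loc_med) /
    (noise_quantile(cfg$noise, 0.9) - noise_quantile(cfg$noise, 0.5))
  sims <- loc_med + sc * (eps - noise_quantile(cfg$noise, 0.5))
  for (tau in c(0.1, 0.5, 0.9)) {
    emp <- unname(quantile(sims, tau, type = 1))
    expect_lt(abs(true_conditional_quantile(cfg, x, tau) - emp), 200)
  }
})

test_that("true conditional quantiles are strictly increasing in tau", {
  cfg <- default_generator_config(seed = 5)
  tab <- generate_episodes(default_generator_config(n_episodes = 25, seed = 5))
  taus <- seq(0.05, 0.95, by = 0.05)
  for (i in seq_len(25)) {
    q <- true_conditional_quantile(cfg, tab[i, covariate_names()], taus)
    expect_true(all(diff(q) > 0))
  }
})

test_that("binary quantile contrasts follow b_j + s_j g(tau) and widen upward", {
  cfg <- default_generator_config(seed = 1)
  tab <- generate_episodes(default_generator_config(n_episodes = 3, seed = 1))
  x0 <- tab[1, covariate_names()]
  x0$chemo_drug <- "PartD"
  x1 <- x0; x1$chemo_drug <- "PartB"
  for (tau in c(0.1, 0.5, 0.9)) {
    contrast <- (true_conditional_quantile(cfg, x1, tau) -
                 true_conditional_quantile(cfg, x0, tau)) / 1000
    expect_equal(contrast, true_quantile_contrast(cfg, "chemo_drug.PartB", tau),
                 tolerance = 1e-9)
  }
  signal <- c("chemo_drug.PartB", "clean_period_cat.1-61", "radiation.yes",
              "surgery.yes", "comorbidity_cat.>=4", "hrr_relative_cost")
  for (term in signal)
    expect_gt(true_quantile_contrast(cfg, term, 0.9),
              true_quantile_contrast(cfg, term, 0.1))
})

test_that("sex, trial and institutional status are null by default", {
  cfg <- default_generator_config()
  for (term in c("sex.male", "trial.yes", "institutional.yes")) {
    expect_identical(cfg$location_coefs[[term]], 0)
    expect_identical(cfg$scale_coefs[[term]], 0)
    expect_identical(true_quantile_contrast(cfg, term, 0.9), 0)
  }
})

test_that("invalid configurations are rejected naming the offending field", {
  cfg <- default_generator_config()
  bad <- cfg$marginals
  bad$insurance <- c(NoPartD = 0.5, PartD_LIS = 0.2, PartD_NoLIS = 0.2,
                     FullDual = 0.2)
  expect_error(generator_config(marginals = bad,
                                location_coefs = cfg$location_coefs,
                                scale_coefs = cfg$scale_coefs,
                                base_location = 6, base_scale = 10),
               "insurance")
  s <- cfg$scale_coefs; s[["chemo_drug.PartB"]] <- -50
  expect_error(generator_config(location_coefs = cfg$location_coefs,
                                scale_coefs = s,
                                base_location = 6, base_scale = 10),
               "scale")
  expect_error(true_conditional_quantile(cfg, NULL, 1.2), "tau")
})

test_that("winsorization caps costs at the configured bounds only when enabled", {
  on <- generate_episodes(default_generator_config(n_episodes = 2000, seed = 13))
  off <- generate_episodes(default_generator_config(n_episodes = 2000, seed = 13,
                                                    winsorize = FALSE))
  expect_true(min(on$cost) >= 461.09 && max(on$cost) <= 71185.40)
  expect_true(min(off$cost) < 461.09 || max(off$cost) > 71185.40)
  inside <- off$cost > 461.09 & off$cost < 71185.40
  expect_equal(on$cost[inside], off$cost[inside])
})
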