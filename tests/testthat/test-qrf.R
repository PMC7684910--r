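test_that("node-size bound forces root-only trees and bootstrap-mean weights", {
  tab <- toy_episodes(10, seed = 2)
  fit <- qrf_fit(tab, n_trees = 25, min_node_size = 10, seed = 5)
  # every tree is a single root leaf
  expect_true(all(apply(fit$leaf_train, 2, function(l) length(unique(l)) == 1)))
  # each tree's in-bag multiplicities sum to n
  expect_true(all(colSums(fit$inbag) == 10))
  # weights reduce to the per-tree normalized in-bag counts, tree-averaged
  W <- leaf_weights(fit, tab[1:3, ])
  expected <- rowMeans(fit$inbag / 10)
  for (i in 1:3) expect_equal(unname(W[i, ]), unname(expected))
  # and conditional quantiles reduce to the weighted unconditional quantile,
  # with the extreme upper tail reaching the sample maximum
  q <- conditional_quantile(fit, tab[1:3, ], 0.5)
  expect_equal(unname(q), rep(bf_quantile(fit$y, expected, 0.5), 3))
  expect_true(all(conditional_quantile(fit, tab[1:3, ], 0.999) == max(fit$y)))
})

test_that("identical data, parameters and seed give identical forests", {
  tab <- toy_episodes(60, seed = 3)
  f1 <- qrf_fit(tab, n_trees = 30, seed = 11)
  f2 <- qrf_fit(tab, n_trees = 30, seed = 11)
  expect_identical(f1$leaf_train, f2$leaf_train)
  expect_identical(f1$inbag, f2$inbag)
  expect_identical(oob_quantile_predictions(f1, 0.9),
                   oob_quantile_predictions(f2, 0.9))
})

test_that("a perfectly separating binary covariate is fit exactly by deep trees", {
  tab <- toy_episodes(20, seed = 4)
  tab$cost <- ifelse(tab$chemo_drug == "PartB", 50000, 5000)
  fit <- qrf_fit(tab, covariates = "chemo_drug", n_trees = 40,
                 min_node_size = 1, seed = 6)
  W <- leaf_weights(fit, tab)
  expect_equal(drop(W %*% fit$y), tab$cost)   # zero in-sample mean error
  expect_equal(unname(conditional_quantile(fit, tab, 0.5)), tab$cost)
})

test_that("leaf weights match exhaustive co-membership enumeration exactly", {
  tab <- toy_episodes(30, seed = 7)
  fit <- qrf_fit(tab, n_trees = 3, min_node_size = 5, seed = 8)
  new <- toy_episodes(12, seed = 9)
  W <- leaf_weights(fit, new)
  W_bf <- bf_weights(fit, qrfcost:::eval_leaves(fit, qrfcost:::encode_newdata(fit, new)))
  expect_equal(W, W_bf, tolerance = 1e-12)
  expect_equal(unname(rowSums(W)), rep(1, 12), tolerance = 1e-10)
})

test_that("conditional quantiles invert the explicitly accumulated weighted ECDF", {
  tab <- toy_episodes(50, seed = 10)
  fit <- qrf_fit(tab, n_trees = 3, min_node_size = 8, seed = 12)
  new <- toy_episodes(8, seed = 13)
  W <- leaf_weights(fit, new)
  taus <- seq(0.1, 0.9, by = 0.1)
  Q <- conditional_quantile(fit, new, taus)
  for (i in seq_len(nrow(new)))
    for (k in seq_along(taus))
      expect_equal(unname(Q[i, k]), bf_quantile(fit$y, W[i, ], taus[k]))
  # atom inversion: weight 0.5 on each of two values, tau = 0.5 -> lower atom
  expect_equal(bf_quantile(c(1, 3), c(0.5, 0.5), 0.5), 1)
  expect_error(conditional_quantile(fit, new, 1.5), "tau")
})

test_that("conditional quantiles are nondecreasing in tau", {
  tab <- toy_episodes(150, seed = 14)
  fit <- qrf_fit(tab, n_trees = 50, seed = 15)
  new <- toy_episodes(40, seed = 16)
  Q <- conditional_quantile(fit, new, seq(0.05, 0.95, by = 0.05))
  expect_true(all(apply(Q, 1, function(r) all(diff(r) >= 0))))
  # upper-tail limit lands on the top of each row's weight support
  W <- leaf_weights(fit, new)
  q_hi <- conditional_quantile(fit, new, 0.9999)
  for (i in seq_len(nrow(new)))
    expect_equal(unname(q_hi[i]), bf_quantile(fit$y, W[i, ], 0.9999))
})

test_that("out-of-bag predictions use only trees where the row is left out", {
  tab <- toy_episodes(20, seed = 17)
  fit <- qrf_fit(tab, n_trees = 60, min_node_size = 20, seed = 18)
  q_oob <- oob_quantile_predictions(fit, 0.5)
  expect_equal(sum(attr(q_oob, "masked")), 0)
  W_bf <- bf_weights(fit, fit$leaf_train, oob = TRUE)
  for (i in 1:20) {
    expect_equal(W_bf[i, i], 0)  # own contribution excluded
    expect_equal(q_oob[[i]], bf_quantile(fit$y, W_bf[i, ], 0.5))
  }
  # root-leaf forest: OOB quantile approaches the leave-one-out sample median
  loo <- vapply(1:20, function(i) sample_quantile_inf(fit$y[-i], 0.5),
                numeric(1))
  expect_lt(mean(abs(q_oob - loo)), diff(range(fit$y)) * 0.15)
})

test_that("permutation importance separates signal from independent noise", {
  set.seed(21)
  tab <- toy_episodes(400, seed = 21)
  fit <- qrf_fit(tab, covariates = c("chemo_drug", "sex"), n_trees = 100,
                 seed = 22)
  imp <- permutation_importance(fit, mode = "pinball", tau = 0.9, seed = 23)
  # chemo drives cost; sex is null in the generator
  expect_gt(imp[["chemo_drug"]], 0)
  expect_gt(imp[["chemo_drug"]], 20 * abs(imp[["sex"]]))
  imp_mse <- permutation_importance(fit, mode = "mse", seed = 24)
  expect_gt(imp_mse[["chemo_drug"]], 0)
})
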