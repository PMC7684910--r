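#' Fit a quantile regression forest
#'
#' Grows a regression forest on bootstrap samples (with replacement, sample
#' size n) by binary recursive splitting minimizing within-node response
#' variance, and retains everything the quantile machinery needs: per-tree
#' in-bag multiplicities and the terminal-node assignment of every training
#' row. Categorical covariates are one-hot encoded against fixed reference
#' levels ([encode_design()]), so splits and downstream effect contrasts
#' share reference levels.
#'
#' Tree growing is delegated to \pkg{ranger}; conditional-distribution
#' weights, quantile inversion, out-of-bag prediction and importance are
#' computed by this package.
#'
#' @param data episode table containing `response` and the covariates.
#' @param covariates character vector of covariate names (schema names).
#' @param response response column name (default `"cost"`).
#' @param n_trees number of trees (default 1000).
#' @param mtry candidate columns per split; default `ceiling(p/3)` over the
#'   encoded design columns.
#' @param min_node_size nodes at or below this in-bag size are not split.
#'   The default 100 keeps roughly `min_node_size * (1 - tau)` in-bag points
#'   above the tau-quantile inside a leaf (about 10 at tau = 0.9), enough to
#'   resolve upper-tail leaf quantiles; reduce it for central quantiles or
#'   small samples.
#' @param seed integer seed; identical data + parameters + seed give an
#'   identical forest.
#' @return object of class `qrf_fit`.
#' @export
qrf_fit <- function(data, covariates = NULL, response = "cost",
                    n_trees = 1000, mtry = NULL, min_node_size = 100,
                    seed = 1L) {
  if (nrow(data) < 2) stop("need at least two rows to fit a forest")
  if (!response %in% names(data)) stop("response column '", response, "' missing")
  enc <- encode_design(data, covariates)
  if (ncol(enc$X) < 1) stop("no covariates to fit")
  y <- as.numeric(data[[response]])
  if (is.null(mtry)) mtry <- ceiling(ncol(enc$X) / 3)
  rf <- ranger::ranger(
    x = as.data.frame(enc$X, check.names = FALSE), y = y,
    num.trees = n_trees, mtry = min(mtry, ncol(enc$X)),
    min.node.size = min_node_size, replace = TRUE, sample.fraction = 1,
    keep.inbag = TRUE, seed = seed, num.threads = 1
  )
  inbag <- do.call(cbind, rf$inbag.counts)
  storage.mode(inbag) <- "integer"
  leaf_train <- stats::predict(rf,
    data = as.data.frame(enc$X, check.names = FALSE),
    type = "terminalNodes", num.threads = 1)$predictions
  storage.mode(leaf_train) <- "integer"
  structure(list(
    rf = rf, X = enc$X, y = y, ord = order(y),
    groups = enc$groups, covariates = names(enc$groups),
    inbag = inbag, leaf_train = leaf_train,
    params = list(n_trees = n_trees, mtry = mtry,
                  min_node_size = min_node_size, seed = seed)
  ), class = "qrf_fit")
}

#' @export
print.qrf_fit <- function(x, ...) {
  cat("Quantile regression forest:", x$params$n_trees, "trees,",
      length(x$y), "training rows,", length(x$covariates), "covariates\n")
  invisible(x)
}

# terminal-node assignments of arbitrary encoded rows
eval_leaves <- function(fit, Xnew) {
  ln <- stats::predict(fit$rf,
    data = as.data.frame(Xnew, check.names = FALSE),
    type = "terminalNodes", num.threads = 1)$predictions
  if (is.null(dim(ln))) ln <- matrix(ln, nrow = 1)
  storage.mode(ln) <- "integer"
  ln
}

encode_newdata <- function(fit, newdata) {
  enc <- encode_design(newdata, fit$covariates)
  miss <- setdiff(colnames(fit$X), colnames(enc$X))
  if (length(miss)) stop("newdata missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  enc$X[, colnames(fit$X), drop = FALSE]
}

#' Conditional-distribution weights at prediction points
#'
#' For each row of `newdata`, the per-training-observation weights
#' \eqn{w_i(x)}: in tree t, training row i gets weight
#' `inbag[i,t] / (total in-bag multiplicity of the leaf containing x)` if it
#' is in-bag in that leaf, else 0; weights are averaged over trees and sum
#' to 1.
#'
#' @param fit a [qrf_fit()].
#' @param newdata data frame with the fitted covariates.
#' @return matrix (rows of `newdata` x training rows) of weights.
#' @export
leaf_weights <- function(fit, newdata) {
  Xn <- encode_newdata(fit, newdata)
  res <- qrf_weights_cpp(fit$leaf_train, fit$inbag, eval_leaves(fit, Xn), FALSE)
  res$weights
}

#' Conditional quantiles from a fitted forest
#'
#' Left-continuous inversion of the weighted empirical CDF over training
#' responses: the smallest training response whose cumulative weight reaches
#' tau. No interpolation is applied.
#'
#' @inheritParams leaf_weights
#' @param tau quantile level(s) in (0, 1).
#' @return matrix (rows of `newdata` x `length(tau)`) of quantiles, or a
#'   vector when a single tau is given.
#' @export
conditional_quantile <- function(fit, newdata, tau) {
  if (any(tau <= 0 | tau >= 1)) stop("tau must lie strictly in (0, 1)")
  Xn <- encode_newdata(fit, newdata)
  ts <- sort(tau)
  res <- qrf_quantiles_cpp(fit$leaf_train, fit$inbag, eval_leaves(fit, Xn),
                           FALSE, fit$y, fit$ord, ts)
  Q <- res$quantiles[, match(tau, ts), drop = FALSE]
  colnames(Q) <- paste0("tau_", tau)
  if (length(tau) == 1) drop(Q) else Q
}

# Shared driver for out-of-bag prediction: weights for row i are averaged
# only over trees where i is out of bag (its own in-bag contribution is then
# automatically zero). leaf_eval defaults to the training assignments but can
# carry assignments under a permuted covariate for importance.
oob_predict <- function(fit, tau, leaf_eval = fit$leaf_train,
                        warn_masked = TRUE) {
  ts <- sort(tau)
  res <- qrf_quantiles_cpp(fit$leaf_train, fit$inbag, leaf_eval, TRUE,
                           fit$y, fit$ord, ts)
  masked <- res$trees_used == 0
  if (warn_masked && any(masked))
    warning(sum(masked), " row(s) in-bag in every tree; out-of-bag ",
            "predictions masked (NA)")
  list(quantiles = res$quantiles[, match(tau, ts), drop = FALSE],
       mean = res$mean, masked = masked)
}

#' Out-of-bag conditional quantile predictions
#'
#' The forest's internal validation device: for each training row, quantiles
#' are inverted from weights computed only over trees where the row was left
#' out of the bootstrap sample. Rows that are in-bag in every tree (vanishing
#' probability for forests of realistic size) are returned as `NA` with a
#' warning and flagged in the `"masked"` attribute.
#'
#' @inheritParams conditional_quantile
#' @return vector (or matrix over taus) of out-of-bag quantile predictions
#'   with attribute `"masked"`.
#' @export
oob_quantile_predictions <- function(fit, tau) {
  if (any(tau <= 0 | tau >= 1)) stop("tau must lie strictly in (0, 1)")
  res <- oob_predict(fit, tau)
  Q <- res$quantiles
  colnames(Q) <- paste0("tau_", tau)
  out <- if (length(tau) == 1) drop(Q) else Q
  attr(out, "masked") <- res$masked
  out
}

# out-of-bag error of a forest under a given leaf-assignment matrix
oob_error <- function(fit, mode, tau, leaf_eval = fit$leaf_train) {
  res <- oob_predict(fit, tau, leaf_eval, warn_masked = FALSE)
  ok <- !res$masked
  if (mode == "mse") mean((fit$y[ok] - res$mean[ok])^2)
  else average_quantile_loss(fit$y[ok], res$quantiles[ok, 1], tau)
}

#' Permutation variable importance
#'
#' Increase in out-of-bag error when a covariate is permuted across rows.
#' All one-hot columns of a categorical covariate are permuted jointly, so
#' importance attaches to the covariate, not to dummy columns. Error is the
#' out-of-bag mean squared error of the weighted-mean prediction
#' (`mode = "mse"`) or the out-of-bag average quantile loss at `tau`
#' (`mode = "pinball"`).
#'
#' @param fit a [qrf_fit()].
#' @param mode `"mse"` or `"pinball"`.
#' @param tau quantile level for pinball mode (default 0.9).
#' @param seed seed for the permutation draws (one sub-stream per covariate).
#' @return named numeric vector, one score per covariate.
#' @export
permutation_importance <- function(fit, mode = c("mse", "pinball"),
                                   tau = 0.9, seed = 1L) {
  mode <- match.arg(mode)
  base <- oob_error(fit, mode, tau)
  n <- nrow(fit$X)
  imp <- stats::setNames(numeric(length(fit$covariates)), fit$covariates)
  for (k in seq_along(fit$covariates)) {
    cov <- fit$covariates[k]
    set.seed(stream_seed(seed, k))
    perm <- sample.int(n)
    Xp <- fit$X
    Xp[, fit$groups[[cov]]] <- fit$X[perm, fit$groups[[cov]], drop = FALSE]
    imp[cov] <- oob_error(fit, mode, tau, eval_leaves(fit, Xp)) - base
  }
  imp
}
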