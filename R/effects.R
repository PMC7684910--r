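#' Natural cubic spline basis
#'
#' df-column natural cubic spline basis (linear beyond the boundary knots).
#' Interior knots sit at evenly spaced quantiles of `x` and boundary knots at
#' its range, unless given explicitly. A `"ncs_spec"` attribute carries the
#' knots so the basis can be re-evaluated on new points (prediction grids).
#'
#' @param x numeric vector with at least `df + 2` distinct values (when knots
#'   are not supplied).
#' @param df degrees of freedom (default 3).
#' @param knots,boundary optional interior and boundary knots.
#' @return basis matrix with `df` columns.
#' @export
ncs_basis <- function(x, df = 3, knots = NULL, boundary = NULL) {
  if (is.null(knots) && length(unique(x)) < df + 2)
    stop("need at least df + 2 distinct values to place spline knots")
  if (is.null(boundary)) boundary <- range(x)
  if (is.null(knots)) {
    # df - 1 interior knots at evenly spaced quantiles (plus the two
    # boundary knots) give exactly df basis columns
    probs <- seq_len(df - 1) / df
    knots <- stats::quantile(x, probs, names = FALSE, type = 7)
  }
  B <- splines::ns(x, knots = knots, Boundary.knots = boundary)
  attr(B, "ncs_spec") <- list(df = df, knots = knots, boundary = boundary)
  B
}

# re-evaluate a basis built by ncs_basis at new points
ncs_eval <- function(basis, xnew) {
  spec <- attr(basis, "ncs_spec")
  splines::ns(xnew, knots = spec$knots, Boundary.knots = spec$boundary)
}

#' Linear quantile regression by iteratively reweighted least squares
#'
#' Minimizes the total pinball loss \eqn{\sum_i \rho_\tau(y_i - x_i'\beta)}
#' by a majorize-minimize scheme: the absolute residual is majorized by a
#' quadratic at the current iterate, giving a weighted least-squares update
#' with weights \eqn{|\tau - 1\{r_i<0\}| / \max(|r_i|, \epsilon)}; the
#' smoothing \eqn{\epsilon} is tightened as the objective stalls. A final
#' polish re-solves the interpolation through the observations with the
#' smallest absolute residuals (a candidate vertex of the underlying linear
#' program) and keeps it when it lowers the objective.
#'
#' @param X design matrix including the intercept column; must have full
#'   column rank.
#' @param y response vector.
#' @param tau quantile level in (0, 1).
#' @param max_iter iteration cap per smoothing level.
#' @param rtol relative objective tolerance.
#' @param init optional starting coefficients (e.g. a full-data fit when
#'   refitting bootstrap resamples).
#' @return named coefficient vector with attributes `"objective"` (achieved
#'   total pinball loss) and `"iterations"`.
#' @export
fit_linear_qr <- function(X, y, tau, max_iter = 30, rtol = 1e-9,
                          init = NULL) {
  if (any(tau <= 0 | tau >= 1)) stop("tau must lie strictly in (0, 1)")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  obj <- function(b) sum(pinball_loss(y, drop(X %*% b), tau))
  beta <- if (is.null(init)) qr.coef(qrX, y) else init
  best <- beta; best_obj <- obj(beta)
  scale_y <- max(stats::mad(y), stats::sd(y) * 1e-3, 1e-12)
  iters <- 0L
  # small problems afford a deep smoothing schedule (certified to 1e-6
  # relative of the exact optimum in the test suite); large fits use a
  # bounded schedule and rely on the vertex polish for the last digits
  small <- n <= 300
  stages <- if (small) 10^seq(-2, -12, by = -2) else 10^c(-2, -4, -6, -8)
  stage_iter <- if (small) max(max_iter, 150L) else max_iter
  for (eps in scale_y * stages) {
    prev_obj <- Inf
    for (it in seq_len(stage_iter)) {
      iters <- iters + 1L
      r <- y - drop(X %*% beta)
      w <- abs(tau - (r < 0)) / pmax(abs(r), eps)
      beta_new <- stats::lm.wfit(X, y, w)$coefficients
      o <- obj(beta_new)
      if (o < best_obj) { best <- beta_new; best_obj <- o }
      delta <- sum(abs(beta_new - beta))
      beta <- beta_new
      if (delta <= rtol * (1 + sum(abs(beta))) ||
          prev_obj - o <= rtol * (1 + abs(o)) && it > 2) break
      prev_obj <- o
    }
  }
  # vertex polish: quantile-regression optima interpolate p observations, so
  # repeatedly solve through the p smallest-residual rows and accept
  # improvements until the active set stabilises
  seen <- character(0)
  for (round in seq_len(25L)) {
    r <- y - drop(X %*% best)
    cand <- sort(order(abs(r))[seq_len(p)])
    key <- paste(cand, collapse = ",")
    if (key %in% seen) break
    seen <- c(seen, key)
    bv <- tryCatch(solve(X[cand, , drop = FALSE], y[cand]),
                   error = function(e) NULL)
    if (is.null(bv) || !all(is.finite(bv))) break
    ov <- obj(bv)
    if (ov < best_obj) { best <- bv; best_obj <- ov } else break
  }
  best <- stats::setNames(as.numeric(best), colnames(X))
  attr(best, "objective") <- best_obj
  attr(best, "iterations") <- iters
  best
}

#' Paired bootstrap percentile confidence intervals for quantile regression
#'
#' Row-resamples (x, y) pairs with replacement, refits [fit_linear_qr()] in
#' each replicate, and forms percentile intervals. Replicates whose refit
#' fails (e.g., a rank-deficient resample) are dropped and counted.
#'
#' @inheritParams fit_linear_qr
#' @param B number of bootstrap replicates (>= 200).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return data frame with `term`, `estimate`, `ci_low`, `ci_high`;
#'   attribute `"dropped"` counts failed replicates.
#' @export
bootstrap_ci <- function(X, y, tau, B = 1000, seed = 1L, level = 0.95) {
  if (B < 200) stop("B must be at least 200")
  X <- as.matrix(X)
  est <- fit_linear_qr(X, y, tau)
  set.seed(stream_seed(seed, 1L))
  idx <- matrix(sample.int(length(y), length(y) * B, replace = TRUE), ncol = B)
  boots <- matrix(NA_real_, nrow = ncol(X), ncol = B)
  dropped <- 0L
  for (b in seq_len(B)) {
    bi <- idx[, b]
    # warm-started at the full-data solution; resamples sit close to it
    cb <- tryCatch(fit_linear_qr(X[bi, , drop = FALSE], y[bi], tau,
                                 init = as.numeric(est)),
                   error = function(e) NULL)
    if (is.null(cb)) dropped <- dropped + 1L else boots[, b] <- cb
  }
  if (dropped > 0)
    warning(dropped, " bootstrap replicate(s) dropped (refit failure)")
  a <- (1 - level) / 2
  ci <- apply(boots, 1, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- data.frame(term = names(est), estimate = as.numeric(est),
                    ci_low = ci[1, ], ci_high = ci[2, ], row.names = NULL)
  attr(out, "dropped") <- dropped
  out
}

# design for the effect fits: intercept + one-hot dummies + scaled
# continuous terms (age per 10 years, HRR relative cost per 30 units)
effect_design <- function(data, selected) {
  enc <- encode_design(data, selected)
  X <- cbind("(Intercept)" = 1, enc$X)
  list(X = X, groups = enc$groups)
}

#' Quantile-varying effect table
#'
#' Fits a linear quantile regression of episode cost (thousands of USD) on
#' the selected covariates at each level of `taus`, with paired-bootstrap
#' percentile confidence intervals: the classical "unblackboxing" companion
#' to the forest. Categorical covariates enter as one-hot contrasts against
#' the fixed reference levels; age enters per 10 years and HRR relative cost
#' per 30 units.
#'
#' @param data episode table with a `cost` column in dollars.
#' @param selected covariate names to include.
#' @param taus quantile grid (default `c(0.1, 0.25, 0.5, 0.75, 0.9)`).
#' @param B bootstrap replicates per tau (default 1000).
#' @param seed integer seed.
#' @param level confidence level.
#' @return data frame of class `quantile_effect_table` with `covariate`,
#'   `level`, `term`, `tau`, `estimate`, `ci_low`, `ci_high` (thousands of
#'   USD).
#' @export
effect_table <- function(data, selected, taus = c(0.1, 0.25, 0.5, 0.75, 0.9),
                         B = 1000, seed = 1L, level = 0.95) {
  if (length(selected) == 0) stop("empty covariate selection")
  des <- effect_design(data, selected)
  y <- as.numeric(data$cost) / 1000
  term_cov <- c("(Intercept)", rep(names(des$groups),
                                   lengths(des$groups)))
  rows <- list()
  for (i in seq_along(taus)) {
    ci <- bootstrap_ci(des$X, y, taus[i], B = B,
                       seed = stream_seed(seed, i), level = level)
    lev <- sub("^[^.]*\\.", "", ci$term)
    lev[!grepl("\\.", ci$term)] <- ""
    rows[[i]] <- data.frame(covariate = term_cov, level = lev,
                            term = ci$term, tau = taus[i],
                            estimate = ci$estimate, ci_low = ci$ci_low,
                            ci_high = ci$ci_high)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("quantile_effect_table", "data.frame")
  out
}

#' Smoothed continuous-covariate effect curves across quantiles
#'
#' Refits the quantile regressions with natural cubic spline bases (default
#' 3 df) for the continuous covariates and returns, for each tau, the fitted
#' effect of one covariate along a grid, centred at a reference value
#' (effect at the reference is 0). This is the nonlinear companion to the
#' linear per-unit effects in [effect_table()].
#'
#' @param data episode table.
#' @param selected covariates in the model.
#' @param covariate continuous covariate to profile (default `"age"`).
#' @param taus quantile levels (default `c(0.1, 0.5, 0.9)`).
#' @param df spline degrees of freedom.
#' @param grid_length points along the covariate range.
#' @param ref reference covariate value (default: sample median).
#' @param seed integer seed (fits are deterministic; kept for interface
#'   symmetry).
#' @return data frame with `covariate`, `value`, `tau`, `effect` (thousands
#'   of USD relative to the reference value).
#' @export
spline_effect_curves <- function(data, selected, covariate = "age",
                                 taus = c(0.1, 0.5, 0.9), df = 3,
                                 grid_length = 60, ref = NULL, seed = 1L) {
  sch <- covariate_schema()
  cont <- intersect(names(sch)[vapply(sch, function(d) d$type == "cont",
                                      logical(1))], selected)
  if (!covariate %in% cont)
    stop("covariate must be a selected continuous covariate")
  cat_sel <- setdiff(selected, cont)
  enc <- if (length(cat_sel)) encode_design(data, cat_sel) else NULL
  bases <- lapply(cont, function(cv) ncs_basis(as.numeric(data[[cv]]), df = df))
  names(bases) <- cont
  X <- cbind("(Intercept)" = 1, if (!is.null(enc)) enc$X)
  for (cv in cont) {
    B <- bases[[cv]]
    colnames(B) <- paste0(cv, ".ns", seq_len(ncol(B)))
    X <- cbind(X, B)
  }
  y <- as.numeric(data$cost) / 1000
  xg <- seq(min(data[[covariate]]), max(data[[covariate]]),
            length.out = grid_length)
  if (is.null(ref)) ref <- stats::median(as.numeric(data[[covariate]]))
  Bg <- ncs_eval(bases[[covariate]], xg)
  Br <- ncs_eval(bases[[covariate]], ref)
  cols <- paste0(covariate, ".ns", seq_len(ncol(Bg)))
  rows <- lapply(taus, function(tau) {
    beta <- fit_linear_qr(X, y, tau)
    eff <- drop((Bg - matrix(Br, nrow = nrow(Bg), ncol = ncol(Bg),
                             byrow = TRUE)) %*% beta[cols])
    data.frame(covariate = covariate, value = xg, tau = tau, effect = eff)
  })
  do.call(rbind, rows)
}
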