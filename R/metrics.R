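#' Pinball (check) loss
#'
#' \eqn{\rho_\tau(y - q) = \tau (y - q)} if \eqn{y \ge q}, else
#' \eqn{(1 - \tau)(q - y)}; the asymmetric absolute loss whose minimizing
#' constant is the tau-quantile.
#'
#' @param y observed values.
#' @param q predicted tau-quantiles.
#' @param tau quantile level in (0, 1).
#' @return elementwise nonnegative losses.
#' @export
pinball_loss <- function(y, q, tau) {
  if (any(tau <= 0 | tau >= 1)) stop("tau must lie strictly in (0, 1)")
  r <- y - q
  ifelse(r >= 0, tau * r, (tau - 1) * r)
}

#' Average quantile loss (AQL)
#'
#' Mean pinball loss over observations; the out-of-bag AQL at tau = 0.9 is
#' the model-selection criterion of the backward stepwise algorithm.
#'
#' @inheritParams pinball_loss
#' @export
average_quantile_loss <- function(y, q, tau) {
  if (length(y) != length(q)) stop("y and q must have equal length")
  if (length(y) == 0) stop("empty input")
  mean(pinball_loss(y, q, tau))
}

#' Unconditional sample quantile, left-continuous ECDF inversion
#'
#' `inf{y : ECDF(y) >= tau}` over the sample values; the convention used for
#' the null (intercept-only) quantile model and for forest quantile
#' inversion, so empirical identities hold exactly on toy examples.
#'
#' @param y numeric sample.
#' @param tau quantile level(s) in (0, 1).
#' @export
sample_quantile_inf <- function(y, tau) {
  if (any(tau <= 0 | tau >= 1)) stop("tau must lie strictly in (0, 1)")
  ys <- sort(y)
  n <- length(ys)
  ys[pmin(n, ceiling(n * tau - 1e-9))]
}

#' R1 goodness of fit of a conditional quantile model
#'
#' One minus the ratio of the model's total check loss to the total check
#' loss of the null (non-conditional) quantile model, whose predictor is the
#' unconditional sample tau-quantile. At tau = 0.5 the check losses are half
#' the absolute deviations, so the ratio coincides with the classical
#' absolute-deviation ratio. R1 is at most 1, and 1 only at zero total loss.
#'
#' @param y observed values (length >= 2, not all equal).
#' @param q_model per-observation model quantile predictions.
#' @param tau quantile level in (0, 1).
#' @export
r1_goodness_of_fit <- function(y, q_model, tau) {
  if (length(y) != length(q_model)) stop("y and q_model must have equal length")
  if (length(y) < 2) stop("need at least two observations")
  q_null <- sample_quantile_inf(y, tau)
  denom <- sum(pinball_loss(y, q_null, tau))
  if (denom == 0)
    stop("null quantile loss is zero (all responses identical); R1 undefined")
  1 - sum(pinball_loss(y, q_model, tau)) / denom
}
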