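# Brute-force oracles kept deliberately naive (explicit loops, no sharing
# with the package implementation) so they certify the fast paths.

# Per-observation weights by direct enumeration over trees and leaves.
bf_weights <- function(fit, leaf_eval, oob = FALSE) {
  n <- nrow(fit$leaf_train); Tn <- ncol(fit$leaf_train)
  m <- nrow(leaf_eval)
  W <- matrix(0, m, n)
  for (i in seq_len(m)) {
    used <- 0
    for (t in seq_len(Tn)) {
      if (oob && fit$inbag[i, t] > 0) next
      leaf <- leaf_eval[i, t]
      members <- which(fit$leaf_train[, t] == leaf & fit$inbag[, t] > 0)
      S <- sum(fit$inbag[members, t])
      wt <- numeric(n)
      for (j in members) wt[j] <- fit$inbag[j, t] / S
      W[i, ] <- W[i, ] + wt
      used <- used + 1
    }
    if (used > 0) W[i, ] <- W[i, ] / used
  }
  W
}

# Left-continuous inversion of an explicitly accumulated weighted ECDF.
bf_quantile <- function(y, w, tau) {
  o <- order(y)
  cum <- cumsum(w[o])
  y[o][which(cum >= tau - 1e-10)[1]]
}

# Exact linear-quantile-regression optimum by enumerating basic solutions
# (exact fits through every size-p subset of observations).
bf_qr_optimum <- function(X, y, tau) {
  p <- ncol(X)
  best <- Inf
  for (idx in utils::combn(nrow(X), p, simplify = FALSE)) {
    Xi <- X[idx, , drop = FALSE]
    if (abs(det(Xi)) < 1e-10) next
    b <- solve(Xi, y[idx])
    r <- y - drop(X %*% b)
    o <- sum(ifelse(r >= 0, tau * r, (tau - 1) * r))
    if (o < best) best <- o
  }
  best
}

# Small calibrated episode table for forest tests.
toy_episodes <- function(n, seed = 1, winsorize = TRUE) {
  generate_episodes(default_generator_config(n_episodes = n, seed = seed,
                                             winsorize = winsorize))
}
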