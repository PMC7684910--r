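#' Backward stepwise covariate selection by out-of-bag AQL
#'
#' Starting from the full covariate set, repeatedly: fit a quantile
#' regression forest, record its out-of-bag average quantile loss at `tau`,
#' compute permutation importance, and remove the least important covariate —
#' until a single covariate remains. The trace also records the null
#' (intercept-only) model's AQL, whose predictor is the unconditional sample
#' tau-quantile. Importance is recomputed at every step on a freshly fitted
#' forest; each step's forest and permutations draw their seeds from a
#' deterministic sequence off the master seed, so the full trace is
#' reproducible. Ties in least importance break by covariate declaration
#' order.
#'
#' @param data episode table.
#' @param covariates covariates to search over (default: all schema
#'   covariates present in `data`).
#' @param tau selection quantile level (default 0.9, the high-cost
#'   threshold).
#' @param response response column name.
#' @param n_trees,mtry,min_node_size forest parameters (see [qrf_fit()]).
#' @param importance_mode `"pinball"` (default) ranks covariates by the same
#'   out-of-bag check loss at `tau` that drives selection, so removal targets
#'   the quantile being modelled; `"mse"` ranks by mean-prediction error and
#'   is blind to purely heteroscedastic (scale-driven) effects.
#' @param seed master seed for the whole trace.
#' @return object of class `selection_trace`: `steps` (data frame with
#'   `step`, `n_vars`, `variables` (list column), `removed`, `oob_aql`,
#'   `forest_seed`), `null_aql`, `tau`, `optimal_set`.
#' @export
backward_stepwise <- function(data, covariates = NULL, tau = 0.9,
                              response = "cost", n_trees = 1000, mtry = NULL,
                              min_node_size = 100,
                              importance_mode = c("pinball", "mse"),
                              seed = 1L) {
  importance_mode <- match.arg(importance_mode)
  if (is.null(covariates))
    covariates <- intersect(covariate_names(), names(data))
  if (length(covariates) < 1) stop("empty covariate set")
  y <- as.numeric(data[[response]])
  null_aql <- average_quantile_loss(
    y, rep(sample_quantile_inf(y, tau), length(y)), tau)
  p <- length(covariates)
  vars <- covariates
  steps <- vector("list", p)
  for (k in seq_len(p)) {
    fseed <- stream_seed(seed, k)
    fit <- qrf_fit(data, covariates = vars, response = response,
                   n_trees = n_trees, mtry = mtry,
                   min_node_size = min_node_size, seed = fseed)
    q_oob <- oob_quantile_predictions(fit, tau)
    ok <- !attr(q_oob, "masked")
    aql <- average_quantile_loss(y[ok], q_oob[ok], tau)
    if (!is.finite(aql))
      stop("non-finite out-of-bag AQL at step ", k, " (",
           length(vars), " covariates)")
    if (length(vars) > 1) {
      imp <- permutation_importance(fit, mode = importance_mode, tau = tau,
                                    seed = stream_seed(seed, 1000L + k))
      # ties resolved toward the earliest-declared covariate
      removed <- vars[which.min(imp[vars])]
    } else removed <- vars
    steps[[k]] <- data.frame(step = k, n_vars = length(vars),
                             removed = removed, oob_aql = aql,
                             forest_seed = fseed)
    steps[[k]]$variables <- I(list(vars))
    vars <- setdiff(vars, removed)
  }
  trace <- structure(list(steps = do.call(rbind, steps), null_aql = null_aql,
                          tau = tau, covariates = covariates,
                          params = list(n_trees = n_trees, mtry = mtry,
                                        min_node_size = min_node_size,
                                        importance_mode = importance_mode,
                                        seed = seed)),
                     class = "selection_trace")
  trace$optimal_set <- select_optimal(trace)
  trace
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Backward stepwise selection at tau =", x$tau, "\n")
  cat("Null (intercept-only) AQL:", format(x$null_aql), "\n")
  df <- x$steps
  for (k in seq_len(nrow(df)))
    cat(sprintf("  step %2d: %2d vars, AQL %s, removed %s\n", df$step[k],
                df$n_vars[k], format(df$oob_aql[k]), df$removed[k]))
  cat("Optimal set (", length(x$optimal_set), " vars): ",
      paste(x$optimal_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Optimal covariate set of a selection trace
#'
#' The variable set of the model with the smallest recorded out-of-bag AQL;
#' ties break toward the smaller model.
#'
#' @param trace a [backward_stepwise()] trace.
#' @export
select_optimal <- function(trace) {
  aql <- trace$steps$oob_aql
  best <- max(which(aql <= min(aql)))  # later step = fewer variables
  trace$steps$variables[[best]]
}

#' Relative importance by AQL reduction
#'
#' Orders the optimal set by reverse removal order (the last-removed variable
#' is the first added on top of the null model) and attributes to the k-th
#' added variable the drop in out-of-bag AQL from the (k-1)-variable model
#' (or the null model) to the k-variable model. Shares are these drops as
#' fractions of the total null-to-optimal reduction and telescope to 1.
#'
#' @param trace a [backward_stepwise()] trace.
#' @return data frame with `variable`, `delta_aql`, `share` (ordered by
#'   addition order).
#' @export
relative_importance <- function(trace) {
  opt <- select_optimal(trace)
  m <- length(opt)
  if (m == 0) stop("empty optimal set")
  df <- trace$steps
  p <- nrow(df)
  aql_at <- function(nv) {          # AQL of the recorded model with nv vars
    if (nv == 0) trace$null_aql else df$oob_aql[df$n_vars == nv]
  }
  total <- trace$null_aql - aql_at(m)
  if (total <= 0)
    stop("null AQL does not exceed the optimal model's AQL; ",
         "relative shares are undefined")
  added <- vapply(seq_len(m), function(j) df$removed[df$n_vars == j],
                  character(1))
  delta <- vapply(seq_len(m), function(j) aql_at(j - 1) - aql_at(j),
                  numeric(1))
  data.frame(variable = added, delta_aql = delta, share = delta / total)
}

#' Export a selection trace
#'
#' Writes the trace as a JSON document (steps, AQL values, seeds, optimal
#' set) and, optionally, the two-column elbow series (model label, AQL) used
#' for AQL-versus-step plots.
#'
#' @param trace a [backward_stepwise()] trace.
#' @param path JSON destination.
#' @param elbow_path optional TSV destination of the elbow series.
#' @export
write_selection_trace <- function(trace, path, elbow_path = NULL) {
  obj <- list(
    tau = trace$tau, null_aql = trace$null_aql,
    params = trace$params[!vapply(trace$params, is.null, logical(1))],
    optimal_set = trace$optimal_set,
    steps = lapply(seq_len(nrow(trace$steps)), function(k) {
      s <- trace$steps[k, ]
      list(step = s$step, n_vars = s$n_vars,
           variables = s$variables[[1]], removed = s$removed,
           oob_aql = s$oob_aql, forest_seed = s$forest_seed)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(elbow_path)) {
    elbow <- data.frame(
      model = c(paste0("k=", rev(trace$steps$n_vars)), "null"),
      oob_aql = c(rev(trace$steps$oob_aql), trace$null_aql)
    )
    utils::write.table(elbow, elbow_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
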