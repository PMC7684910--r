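#' Run configuration for the full analysis pipeline
#'
#' Exactly one of `input` (path to an episode CSV) or `generator` (a
#' [generator_config()]) must be supplied.
#'
#' @param input path to a delimited episode table, or `NULL`.
#' @param generator a [generator_config()], or `NULL`.
#' @param tau_selection selection quantile (default 0.9).
#' @param tau_grid effect-table quantile grid.
#' @param n_trees,mtry,min_node_size forest parameters.
#' @param importance_mode `"mse"` or `"pinball"`.
#' @param bootstrap_B bootstrap replicates for effect CIs.
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir directory for artifacts (`NULL`: nothing written).
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL, tau_selection = 0.9,
                       tau_grid = c(0.1, 0.25, 0.5, 0.75, 0.9),
                       n_trees = 1000, mtry = NULL, min_node_size = 100,
                       importance_mode = "pinball", bootstrap_B = 1000,
                       seed = 1L, output_dir = NULL) {
  if (is.null(input) == is.null(generator))
    stop("run_config: exactly one of 'input' and 'generator' must be given")
  structure(list(input = input, generator = generator,
                 tau_selection = tau_selection, tau_grid = tau_grid,
                 n_trees = n_trees, mtry = mtry,
                 min_node_size = min_node_size,
                 importance_mode = importance_mode,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read and validate an episode table
#'
#' Reads a comma-separated episode table and validates it against the
#' covariate schema: required columns, known category labels, numeric
#' continuous columns, nonnegative costs, no missing values. All offenses
#' are collected and reported together, with row numbers for label errors.
#'
#' @param path CSV path with a header row.
#' @return validated episode table (data frame).
#' @export
read_episode_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_episode_table(tab)
}

#' @rdname read_episode_table
#' @param table an in-memory episode table to validate.
#' @export
validate_episode_table <- function(table) {
  sch <- covariate_schema()
  problems <- character(0)
  need <- c(names(sch), "cost")
  miss <- setdiff(need, names(table))
  if (length(miss))
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(miss, collapse = ", ")))
  for (cov in intersect(names(sch), names(table))) {
    def <- sch[[cov]]
    if (def$type == "cat") {
      v <- as.character(table[[cov]])
      bad <- which(is.na(v) | !v %in% def$levels)
      if (length(bad))
        problems <- c(problems, paste0(
          "unknown ", cov, " label at row(s) ",
          paste(utils::head(bad, 10L), collapse = ", ")))
    } else {
      v <- suppressWarnings(as.numeric(table[[cov]]))
      if (any(is.na(v)))
        problems <- c(problems, paste0(
          cov, " has missing or non-numeric value at row(s) ",
          paste(utils::head(which(is.na(v)), 10L), collapse = ", ")))
      table[[cov]] <- v
    }
  }
  if ("cost" %in% names(table)) {
    cost <- suppressWarnings(as.numeric(table$cost))
    if (any(is.na(cost)))
      problems <- c(problems, paste0(
        "cost has missing or non-numeric value at row(s) ",
        paste(utils::head(which(is.na(cost)), 10L), collapse = ", ")))
    else if (any(cost < 0))
      problems <- c(problems, paste0(
        "negative cost at row(s) ",
        paste(utils::head(which(cost < 0), 10L), collapse = ", ")))
    table$cost <- cost
  }
  if (length(problems))
    stop("episode table validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  table
}

#' Run the full analysis pipeline
#'
#' Generate (or load) the episode table, run backward stepwise selection at
#' the selection quantile, derive the optimal set and relative-importance
#' shares, compute fit diagnostics (out-of-bag AQL and R1 of the optimal
#' forest), and fit the quantile effect table on the selected covariates.
#' With an `output_dir`, all artifacts are written as delimited/JSON text.
#'
#' @param config a [run_config()].
#' @return object of class `run_report` with elements `table`, `trace`,
#'   `optimal_set`, `relative_importance`, `diagnostics`, `effects`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tab <- stage("input", {
    if (!is.null(config$generator)) generate_episodes(config$generator)
    else read_episode_table(config$input)
  })
  tab <- stage("validate", validate_episode_table(tab))
  trace <- stage("selection", backward_stepwise(
    tab, tau = config$tau_selection, n_trees = config$n_trees,
    mtry = config$mtry, min_node_size = config$min_node_size,
    importance_mode = config$importance_mode,
    seed = stream_seed(config$seed, 11L)))
  optimal <- trace$optimal_set
  relimp <- stage("relative_importance", relative_importance(trace))
  diagnostics <- stage("diagnostics", {
    opt_step <- trace$steps[trace$steps$n_vars == length(optimal), ]
    fit <- qrf_fit(tab, covariates = optimal, n_trees = config$n_trees,
                   mtry = config$mtry,
                   min_node_size = config$min_node_size,
                   seed = opt_step$forest_seed)
    q_oob <- oob_quantile_predictions(fit, config$tau_selection)
    ok <- !attr(q_oob, "masked")
    list(tau = config$tau_selection,
         aql = average_quantile_loss(tab$cost[ok], q_oob[ok],
                                     config$tau_selection),
         r1 = r1_goodness_of_fit(tab$cost[ok], q_oob[ok],
                                 config$tau_selection),
         n_used = sum(ok))
  })
  effects <- stage("effects", effect_table(
    tab, optimal, taus = config$tau_grid, B = config$bootstrap_B,
    seed = stream_seed(config$seed, 13L)))
  report <- structure(list(table = tab, trace = trace,
                           optimal_set = optimal,
                           relative_importance = relimp,
                           diagnostics = diagnostics, effects = effects,
                           config = config),
                      class = "run_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Episode-cost quantile analysis (n =", nrow(x$table), ")\n")
  cat("Optimal set:", paste(x$optimal_set, collapse = ", "), "\n")
  cat(sprintf("OOB AQL at tau=%.2f: %.2f; R1: %.3f\n", x$diagnostics$tau,
              x$diagnostics$aql, x$diagnostics$r1))
  invisible(x)
}

#' Write all artifacts of a run report
#'
#' @param report a [run_pipeline()] report.
#' @param dir destination directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$config$generator))
    write_episode_table(report$table, file.path(dir, "episodes.csv"),
                        file.path(dir, "generator_config.txt"))
  write_selection_trace(report$trace, file.path(dir, "selection_trace.json"),
                        file.path(dir, "elbow.tsv"))
  utils::write.csv(report$relative_importance,
                   file.path(dir, "relative_importance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$diagnostics,
                       file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report$effects),
                   file.path(dir, "effect_table.csv"), row.names = FALSE)
  cfg <- report$config
  lines <- c(
    paste0("seed: ", cfg$seed),
    paste0("tau_selection: ", cfg$tau_selection),
    paste0("tau_grid: ", paste(cfg$tau_grid, collapse = " ")),
    paste0("n_trees: ", cfg$n_trees),
    paste0("mtry: ", if (is.null(cfg$mtry)) "default" else cfg$mtry),
    paste0("min_node_size: ", cfg$min_node_size),
    paste0("importance_mode: ", cfg$importance_mode),
    paste0("bootstrap_B: ", cfg$bootstrap_B),
    paste0("input: ", if (is.null(cfg$input)) "generator" else cfg$input)
  )
  writeLines(lines, file.path(dir, "run_config.txt"))
  invisible(dir)
}
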