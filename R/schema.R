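#' Episode covariate schema
#'
#' The eleven OCM risk-adjustment covariates used throughout the package,
#' with their category labels (reference level first) or, for the two
#' continuous covariates, the centring and unit used when they enter models
#' linearly: age is measured per 10 years (centred at 72), HRR relative cost
#' per 30 percentage points.
#'
#' @return Named list; each element has `type` (`"cat"` or `"cont"`) and
#'   either `levels` (reference level first) or `center`/`unit`.
#' @export
covariate_schema <- function() {
  list(
    sex = list(type = "cat", levels = c("female", "male")),
    chemo_drug = list(type = "cat", levels = c("PartD", "PartB")),
    surgery = list(type = "cat", levels = c("no", "yes")),
    insurance = list(type = "cat",
                     levels = c("NoPartD", "PartD_LIS", "PartD_NoLIS", "FullDual")),
    radiation = list(type = "cat", levels = c("no", "yes")),
    trial = list(type = "cat", levels = c("no", "yes")),
    comorbidity_cat = list(type = "cat",
                           levels = c("0", "1", "2", "3", ">=4", "new_enrollee")),
    clean_period_cat = list(type = "cat",
                            levels = c("62-730", "1-61", ">730_or_none")),
    institutional = list(type = "cat", levels = c("no", "yes")),
    age = list(type = "cont", center = 72, unit = 10),
    hrr_relative_cost = list(type = "cont", center = 0, unit = 30)
  )
}

#' All covariate names in declaration order
#' @return character vector of the eleven covariate names.
#' @export
covariate_names <- function() names(covariate_schema())

# Column label for a categorical dummy.
dummy_name <- function(cov, level) paste(cov, level, sep = ".")

#' One-hot design encoding with fixed reference levels
#'
#' Encodes an episode table into the numeric design used by both the forest
#' and the linear quantile fits: one dummy column per non-reference category
#' level, and centred/scaled columns for the continuous covariates
#' (age per 10 years, HRR relative cost per 30 units). Column order follows
#' the schema declaration order, so the encoding is deterministic.
#'
#' @param data episode table (data frame).
#' @param covariates character vector of covariate names to encode
#'   (default: all present in the schema).
#' @return list with `X` (numeric matrix), `groups` (named list mapping each
#'   covariate to its column indices).
#' @export
encode_design <- function(data, covariates = NULL) {
  sch <- covariate_schema()
  if (is.null(covariates)) covariates <- intersect(names(sch), names(data))
  covariates <- names(sch)[names(sch) %in% covariates] # declaration order
  cols <- list(); groups <- list()
  for (cov in covariates) {
    def <- sch[[cov]]
    if (!cov %in% names(data)) stop("covariate missing from table: ", cov)
    if (def$type == "cat") {
      v <- as.character(data[[cov]])
      bad <- !v %in% def$levels
      if (any(bad))
        stop("unknown ", cov, " label at row(s) ",
             paste(utils::head(which(bad), 5L), collapse = ", "))
      idx <- integer(0)
      for (lev in def$levels[-1]) {
        cols[[dummy_name(cov, lev)]] <- as.numeric(v == lev)
        idx <- c(idx, length(cols))
      }
      groups[[cov]] <- idx
    } else {
      cols[[cov]] <- (as.numeric(data[[cov]]) - def$center) / def$unit
      groups[[cov]] <- length(cols)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  list(X = X, groups = groups)
}

# Deterministic derivation of sub-stream seeds from one master seed.
# Kept below 2^31 - 1 so the result is always a valid integer seed.
stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 2654435) %% 2147483629) + 1L
}
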