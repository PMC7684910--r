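#' Hospital Referral Region relative cost
#'
#' Percent deviation of an HRR's average episode cost from the average across
#' all HRRs: `((avg_cost_hrr / avg_cost_all_hrr) - 1) * 100`.
#'
#' @param avg_cost_hrr average episode cost for the HRR (dollars).
#' @param avg_cost_all_hrr average episode cost across all HRRs (dollars,
#'   strictly positive).
#' @return percent deviation (vectorized).
#' @examples
#' hrr_relative_cost(110, 100) # 10
#' @export
hrr_relative_cost <- function(avg_cost_hrr, avg_cost_all_hrr) {
  if (any(avg_cost_all_hrr <= 0))
    stop("avg_cost_all_hrr must be strictly positive")
  (avg_cost_hrr / avg_cost_all_hrr - 1) * 100
}

#' Categorize comorbidity burden from HCC flag counts
#'
#' Six categories: "0", "1", "2", "3", ">=4" for four or more treated-condition
#' flags, and "new_enrollee" for beneficiaries without a prior-year claims
#' history. The new-enrollee marker takes precedence over any count.
#'
#' @param hcc_flags nonnegative integer count of HCC flags (may be `NA` where
#'   `new_enrollee` is `TRUE`).
#' @param new_enrollee logical marker (recycled).
#' @return character vector of category labels.
#' @export
categorize_comorbidity <- function(hcc_flags, new_enrollee = FALSE) {
  new_enrollee <- rep_len(new_enrollee, length(hcc_flags))
  if (any(!new_enrollee & (is.na(hcc_flags) | hcc_flags < 0)))
    stop("hcc_flags must be a nonnegative count unless new_enrollee is TRUE")
  out <- ifelse(hcc_flags >= 4, ">=4", as.character(hcc_flags))
  out[new_enrollee] <- "new_enrollee"
  out
}

#' Categorize the chemotherapy clean period
#'
#' Days between episode start and the most recent prior chemotherapy claim,
#' binned as in the OCM risk model: 1-61 days, 62-730 days, and more than 730
#' days or no prior chemotherapy claim (`NA` input).
#'
#' @param days positive integer days, or `NA` for no prior claim.
#' @return character vector in `{"1-61", "62-730", ">730_or_none"}`.
#' @export
categorize_clean_period <- function(days) {
  if (any(!is.na(days) & days <= 0))
    stop("days since last chemotherapy must be >= 1 when present")
  out <- rep(">730_or_none", length(days))
  out[!is.na(days) & days <= 61] <- "1-61"
  out[!is.na(days) & days >= 62 & days <= 730] <- "62-730"
  out
}

#' Categorize prescription-drug insurance status
#'
#' Four categories: full Medicaid benefits imply `"FullDual"` regardless of
#' the other flags; otherwise no Part D enrollment is `"NoPartD"`, Part D with
#' the low-income subsidy is `"PartD_LIS"`, and Part D without it is
#' `"PartD_NoLIS"`.
#'
#' @param part_d_enrolled,low_income_subsidy,full_medicaid logical flags
#'   (recycled to a common length).
#' @return character vector of insurance category labels.
#' @export
categorize_insurance <- function(part_d_enrolled, low_income_subsidy,
                                 full_medicaid) {
  n <- max(length(part_d_enrolled), length(low_income_subsidy),
           length(full_medicaid))
  part_d_enrolled <- rep_len(part_d_enrolled, n)
  low_income_subsidy <- rep_len(low_income_subsidy, n)
  full_medicaid <- rep_len(full_medicaid, n)
  ifelse(full_medicaid, "FullDual",
         ifelse(!part_d_enrolled, "NoPartD",
                ifelse(low_income_subsidy, "PartD_LIS", "PartD_NoLIS")))
}
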