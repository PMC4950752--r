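#' Caregiver-time costing options
#'
#' Controls how informal-caregiver time is valued when building total
#' societal costs. The base case uses the opportunity-cost approach with
#' separate unit costs for working and non-working caregivers, excludes
#' supervision time, and costs the higher of caregiving time or missed work.
#' The three alternatives studied are: including supervision time; the
#' replacement-cost approach (one market unit cost for every caregiver,
#' supervision included); and costing only working caregivers' time.
#'
#' The default unit costs are illustrative placeholders, not the
#' country-specific wages of any study; set them from your own unit-cost
#' source for substantive use.
#'
#' @param include_supervision include supervision hours in costed time.
#' @param valuation `"opportunity"` (unit cost depends on working status) or
#'   `"replacement"` (single market unit cost; supervision included by
#'   convention unless explicitly disabled).
#' @param working_only if `TRUE`, non-working caregivers' time is not costed.
#' @param unit_cost_working,unit_cost_nonworking EUR/hour under the
#'   opportunity approach.
#' @param unit_cost_replacement EUR/hour under the replacement approach.
#' @param hour_cap_per_day cap on costed care hours, hours/day.
#' @param days_per_month days used to convert the cap to a monthly total.
#' @return A list of class `"cm_costing"`.
#' @export
costing_options <- function(include_supervision = FALSE,
                            valuation = c("opportunity", "replacement"),
                            working_only = FALSE,
                            unit_cost_working = 20,
                            unit_cost_nonworking = 10,
                            unit_cost_replacement = 15,
                            hour_cap_per_day = 24,
                            days_per_month = 30.4) {
  valuation <- match.arg(valuation)
  stopifnot(unit_cost_working >= 0, unit_cost_nonworking >= 0,
            unit_cost_replacement >= 0,
            hour_cap_per_day > 0, hour_cap_per_day <= 24)
  structure(list(include_supervision = include_supervision,
                 valuation = valuation, working_only = working_only,
                 unit_cost_working = unit_cost_working,
                 unit_cost_nonworking = unit_cost_nonworking,
                 unit_cost_replacement = unit_cost_replacement,
                 hour_cap_per_day = hour_cap_per_day,
                 days_per_month = days_per_month),
            class = "cm_costing")
}

#' Informal-care cost of a record
#'
#' Costed hours are basic plus instrumental ADL time (plus supervision if
#' included), capped at the daily cap times days/month. The unit cost is the
#' caregiver's opportunity cost (working vs non-working wage) or the single
#' replacement cost. The returned cost is the higher of costed caregiving
#' time and caregiver missed work, both valued at the same unit cost; with
#' `working_only = TRUE` a non-working caregiver contributes zero.
#'
#' @param cohort cohort data frame (one or more records).
#' @param options a [costing_options()] list.
#' @return Numeric vector, EUR/month.
#' @export
informal_care_cost <- function(cohort, options = costing_options()) {
  stopifnot(inherits(options, "cm_costing"))
  H <- cohort$hours_adl + cohort$hours_iadl +
    if (options$include_supervision) cohort$hours_supervision else 0
  H <- pmin(H, options$hour_cap_per_day * options$days_per_month)
  u <- if (options$valuation == "replacement")
    rep(options$unit_cost_replacement, nrow(cohort))
  else ifelse(cohort$caregiver_working, options$unit_cost_working,
              options$unit_cost_nonworking)
  cost <- pmax(H * u, cohort$hours_missed_work * u)
  if (options$working_only) cost[!cohort$caregiver_working] <- 0
  cost
}

#' Total societal cost of a record under a costing rule
#'
#' Patient health care + patient social care + caregiver health care +
#' informal care valued under `options`.
#'
#' @inheritParams informal_care_cost
#' @return Numeric vector, EUR/month.
#' @export
total_societal_cost <- function(cohort, options = costing_options()) {
  cohort$cost_patient_healthcare + cohort$cost_patient_social +
    cohort$cost_caregiver_healthcare + informal_care_cost(cohort, options)
}

#' Cohort mean cost under the base case and the three alternatives
#'
#' Evaluates the cohort's mean total societal cost under the base case,
#' supervision included, replacement cost (single unit cost, supervision
#' included), and working caregivers only, with percent differences from
#' the base case.
#'
#' @param cohort analysis-set cohort.
#' @param base a [costing_options()] describing the base case.
#' @return A data.frame with one row per variant: `variant`, `mean_cost`,
#'   `pct_change_vs_base`.
#' @export
cost_variants <- function(cohort, base = costing_options()) {
  variants <- list(
    base_case = base,
    supervision_included = utils::modifyList(base,
      list(include_supervision = TRUE)),
    replacement_cost = utils::modifyList(base,
      list(valuation = "replacement", include_supervision = TRUE)),
    working_caregivers_only = utils::modifyList(base,
      list(working_only = TRUE)))
  means <- vapply(variants, function(o) {
    class(o) <- "cm_costing"
    mean(total_societal_cost(cohort, o))
  }, 0)
  data.frame(variant = names(variants), mean_cost = as.numeric(means),
             pct_change_vs_base = 100 * (means - means[["base_case"]]) /
               means[["base_case"]],
             row.names = NULL, stringsAsFactors = FALSE)
}
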