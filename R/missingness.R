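#' Missingness masks
#'
#' A mask is a data frame with one row per analysis-set patient:
#' `patient_id`, `is_missing` (logical) and `reason`, one of `observed`,
#' `generic`, `institutionalised`, `died`, `lost_to_followup`.
#' `reason == "observed"` iff `is_missing` is `FALSE`.
#'
#' @name masks
NULL

new_mask <- function(patient_id, reason, mechanism, params = list()) {
  stopifnot(!anyDuplicated(patient_id))
  reason <- factor(reason, levels = c("observed", "generic",
                                      "institutionalised", "died",
                                      "lost_to_followup"))
  m <- data.frame(patient_id = patient_id,
                  is_missing = reason != "observed",
                  reason = reason, stringsAsFactors = FALSE)
  attr(m, "mechanism") <- mechanism
  attr(m, "mask_params") <- params
  class(m) <- c("cm_mask", "data.frame")
  m
}

check_volume <- function(volume) {
  if (volume < 0 || volume >= 1)
    stop("volume must be in [0, 1)")
  volume
}

#' Missing completely at random
#'
#' Selects exactly `round(volume * n)` patients uniformly without
#' replacement; their total cost is flagged missing with reason `generic`.
#'
#' @param cohort analysis-set cohort data frame.
#' @param volume target missing fraction in `[0, 1)`.
#' @param seed RNG seed for the draw.
#' @return A mask data frame (see [masks]).
#' @export
mcar_mask <- function(cohort, volume, seed = 1L) {
  check_volume(volume)
  n <- nrow(cohort)
  k <- round(volume * n)
  set.seed(seed)
  idx <- if (k > 0) sample.int(n, k) else integer(0)
  reason <- rep("observed", n)
  reason[idx] <- "generic"
  new_mask(cohort$patient_id, reason, "MCAR",
           list(volume = volume, seed = seed))
}

#' Missing at random on cognition and function
#'
#' Computes the combined severity score `z(MMSE) + z(ADCS-ADL)` (within-cohort
#' standardisation) and flags the `round(volume * n)` patients with the
#' lowest score (worst cognition and function) as missing. Deterministic
#' given the cohort; ties broken by stable patient order.
#'
#' @inheritParams mcar_mask
#' @return A mask data frame.
#' @export
mar_mask <- function(cohort, volume) {
  check_volume(volume)
  if (anyNA(cohort$mmse) || anyNA(cohort$adcs_adl))
    stop("mar_mask requires MMSE and ADCS-ADL for all records")
  n <- nrow(cohort)
  k <- round(volume * n)
  s <- as.numeric(scale(cohort$mmse)) + as.numeric(scale(cohort$adcs_adl))
  idx <- order(s, seq_len(n))[seq_len(k)]
  reason <- rep("observed", n)
  reason[idx] <- "generic"
  new_mask(cohort$patient_id, reason, "MAR", list(volume = volume))
}

#' Missing not at random on the cost value itself
#'
#' Flags the `round(volume * n)` patients with the highest total cost as
#' missing, so missingness is driven by the unobserved value: every missing
#' cost exceeds every observed cost (ties broken by stable patient order and
#' flagged with a warning).
#'
#' @inheritParams mcar_mask
#' @return A mask data frame.
#' @export
mnar_mask <- function(cohort, volume) {
  check_volume(volume)
  if (anyNA(cohort$cost_total))
    stop("mnar_mask requires total cost for all analysis-set records")
  n <- nrow(cohort)
  k <- round(volume * n)
  ord <- order(-cohort$cost_total, seq_len(n))
  idx <- ord[seq_len(k)]
  if (k > 0 && k < n) {
    cutoff <- cohort$cost_total[ord[k]]
    if (any(cohort$cost_total[ord[(k + 1):n]] == cutoff))
      warning("ties at the deletion threshold broken by stable patient order")
  }
  reason <- rep("observed", n)
  reason[idx] <- "generic"
  new_mask(cohort$patient_id, reason, "MNAR", list(volume = volume))
}

#' Mixed-reason dropout configuration
#'
#' Rates and sub-model settings for [dropout_pattern_mask()], emulating the
#' 18-month dropout of a dementia cohort: 15% institutionalised, 6% died,
#' 12% lost to follow-up (33% missing in total).
#'
#' @param rate_institutionalised,rate_died,rate_ltfu target fractions of the
#'   cohort assigned to each dropout reason.
#' @param variant `"mar_inst"`: institutionalisation follows a logistic
#'   model on MMSE, ADCS-ADL and caregiver time (missing at random given
#'   observed data). `"mnar_inst"`: institutionalisation is the
#'   deterministic rule caregiver time > `caregiver_time_threshold`
#'   (missing not at random, since caregiver time is withheld from the
#'   imputation models).
#' @param caregiver_time_threshold hours/month, strict `>` rule.
#' @param coef_inst,coef_died logistic slopes of the institutionalisation
#'   sub-model (MMSE, ADCS-ADL, caregiver hours) and the death sub-model
#'   (MMSE, ADCS-ADL, age); intercepts are solved numerically to hit the
#'   target rates.
#' @return A list of class `"cm_dropout_config"`.
#' @export
dropout_config <- function(rate_institutionalised = 0.15,
                           rate_died = 0.06,
                           rate_ltfu = 0.12,
                           variant = c("mar_inst", "mnar_inst"),
                           caregiver_time_threshold = 470,
                           coef_inst = c(mmse = -0.08, adl = -0.03,
                                         hours = 0.002),
                           coef_died = c(mmse = -0.05, adl = -0.02,
                                         age = 0.05)) {
  variant <- match.arg(variant)
  rates <- c(rate_institutionalised, rate_died, rate_ltfu)
  if (any(rates < 0) || sum(rates) > 1)
    stop("dropout rates must be >= 0 and sum to at most 1")
  structure(list(rate_institutionalised = rate_institutionalised,
                 rate_died = rate_died, rate_ltfu = rate_ltfu,
                 variant = variant,
                 caregiver_time_threshold = caregiver_time_threshold,
                 coef_inst = coef_inst, coef_died = coef_died),
            class = "cm_dropout_config")
}

# solve the logistic intercept so the mean selection probability hits `rate`
calibrate_intercept <- function(lp, rate) {
  f <- function(a) mean(stats::plogis(a + lp)) - rate
  stats::uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
}

# exact-count probability-proportional draw: k patients, weights plogis(lp)
weighted_draw <- function(candidates, lp, rate, n_total) {
  k <- round(rate * n_total)
  if (k == 0) return(integer(0))
  a <- calibrate_intercept(lp, rate * n_total / length(candidates))
  w <- stats::plogis(a + lp)
  candidates[sample.int(length(candidates), k, prob = w)]
}

#' Mixed-reason dropout mask
#'
#' Assigns missingness by reason, in order: institutionalised, then died
#' (among the remainder), then lost to follow-up (uniformly at random among
#' the remainder). Under `variant = "mar_inst"` institutionalisation is a
#' calibrated logistic draw on MMSE, ADCS-ADL and caregiver hours selecting
#' exactly `round(rate * n)` patients (probability proportional to the
#' logistic weight, without replacement); under `"mnar_inst"` it is the
#' deterministic caregiver-time threshold rule, and a warning is raised if
#' the realised institutionalisation fraction deviates more than 20%
#' relatively from the target rate. Death is always a calibrated logistic
#' draw on MMSE, ADCS-ADL and age; loss to follow-up is completely at
#' random. At the default rates the overall missing fraction is 33%.
#'
#' @param cohort analysis-set cohort data frame.
#' @param config a [dropout_config()] list.
#' @param seed RNG seed.
#' @return A mask data frame with reason channels.
#' @export
dropout_pattern_mask <- function(cohort, config = dropout_config(),
                                 seed = 1L) {
  stopifnot(inherits(config, "cm_dropout_config"))
  n <- nrow(cohort)
  hours <- total_caregiver_hours(cohort)
  set.seed(seed)
  reason <- rep("observed", n)

  if (config$variant == "mnar_inst") {
    inst <- which(hours > config$caregiver_time_threshold)
    realised <- length(inst) / n
    if (config$rate_institutionalised > 0 &&
        abs(realised - config$rate_institutionalised) /
          config$rate_institutionalised > 0.2)
      warning(sprintf(
        "threshold rule institutionalises %.1f%% vs target %.1f%%",
        100 * realised, 100 * config$rate_institutionalised))
  } else {
    lp <- config$coef_inst[["mmse"]] * cohort$mmse +
      config$coef_inst[["adl"]] * cohort$adcs_adl +
      config$coef_inst[["hours"]] * hours
    inst <- weighted_draw(seq_len(n), lp, config$rate_institutionalised, n)
  }
  reason[inst] <- "institutionalised"

  rem <- which(reason == "observed")
  lp_d <- config$coef_died[["mmse"]] * cohort$mmse[rem] +
    config$coef_died[["adl"]] * cohort$adcs_adl[rem] +
    config$coef_died[["age"]] * cohort$age[rem]
  died <- weighted_draw(rem, lp_d, config$rate_died, n)
  reason[died] <- "died"

  rem <- which(reason == "observed")
  k_ltfu <- round(config$rate_ltfu * n)
  ltfu <- rem[sample.int(length(rem), min(k_ltfu, length(rem)))]
  reason[ltfu] <- "lost_to_followup"

  new_mask(cohort$patient_id, reason,
           paste0("DROPOUT_", toupper(config$variant)),
           list(config = unclass(config), seed = seed))
}

#' Apply a mask to a cost vector
#'
#' @param cohort cohort data frame.
#' @param mask mask data frame aligned to the cohort by `patient_id`.
#' @return The cohort's `cost_total` with masked entries set to `NA`.
#' @export
masked_costs <- function(cohort, mask) {
  if (!identical(cohort$patient_id, mask$patient_id))
    mask <- mask[match(cohort$patient_id, mask$patient_id), , drop = FALSE]
  if (anyNA(mask$is_missing))
    stop("mask does not cover every cohort patient")
  ifelse(mask$is_missing, NA_real_, cohort$cost_total)
}

#' @export
print.cm_mask <- function(x, ...) {
  cat(sprintf("Missingness mask (%s): %d of %d missing (%.1f%%)\n",
              attr(x, "mechanism"), sum(x$is_missing), nrow(x),
              100 * mean(x$is_missing)))
  print(table(x$reason))
  invisible(x)
}
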