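# shared fixtures, built once per test run

# default-calibrated cohort at the study's analysis-set scale
default_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- analysis_set(
      generate_cohort(cohort_params(seed = 7)))
    coh
  }
})

# small cohort for fast unit tests
small_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- analysis_set(
      generate_cohort(cohort_params(n = 300, seed = 11)))
    coh
  }
})

# MI settings scaled for test runtime; chain mechanics are unchanged
fast_mi <- function(m = 3L, seed = 1L) {
  mi_config(m = m, burn_in = 100L, thin = 25L, seed = seed)
}

# hand-built toy cohort with explicit values
toy_cohort <- function(cost, mmse = rep(20L, length(cost)),
                       adl = rep(40L, length(cost)),
                       hours = rep(100, length(cost))) {
  n <- length(cost)
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = rep(75, n), sex = rep("female", n),
    mmse = as.integer(mmse), adcs_adl = as.integer(adl),
    hours_adl = hours * 0.4, hours_iadl = hours * 0.4,
    hours_supervision = hours * 0.2,
    hours_missed_work = rep(0, n),
    caregiver_working = rep(FALSE, n),
    cost_patient_healthcare = cost * 0.2,
    cost_patient_social = cost * 0.1,
    cost_caregiver_healthcare = cost * 0.1,
    cost_informal_care = cost * 0.6,
    cost_total = cost,
    baseline_complete = TRUE,
    stringsAsFactors = FALSE)
}

# mask flagging the given patient positions as missing
toy_mask <- function(cohort, missing_idx, reason = "generic") {
  r <- rep("observed", nrow(cohort))
  r[missing_idx] <- reason
  costmiss:::new_mask(cohort$patient_id, r, "TOY")
}
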