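test_that("MCAR mask hits its count exactly and uses the generic reason", {
  coh <- toy_cohort(rep(1000, 100))
  m <- mcar_mask(coh, 0.10, seed = 1)
  expect_equal(sum(m$is_missing), 10)
  expect_true(all(m$reason[m$is_missing] == "generic"))
  expect_true(all(m$reason[!m$is_missing] == "observed"))

  expect_equal(sum(mcar_mask(coh, 0, seed = 1)$is_missing), 0)

  big <- toy_cohort(rep(1000, 1497))
  expect_equal(sum(mcar_mask(big, 0.40, seed = 2)$is_missing), 599)

  expect_error(mcar_mask(coh, 1), "volume")
})

test_that("MCAR leaves missing and observed subgroups exchangeable", {
  a <- default_cohort()
  # average MMSE difference over seeds is centred at zero
  d <- vapply(1:20, function(s) {
    m <- mcar_mask(a, 0.3, seed = s)
    mean(a$mmse[m$is_missing]) - mean(a$mmse[!m$is_missing])
  }, 0)
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 0.2)
})

test_that("MAR mask removes the worst-functioning patients", {
  coh <- toy_cohort(c(1000, 2000), mmse = c(10, 25), adl = c(20, 60))
  m <- mar_mask(coh, 0.5)
  expect_true(m$is_missing[1])   # lowest z(MMSE) + z(ADL)
  expect_false(m$is_missing[2])

  expect_equal(sum(mar_mask(coh, 0)$is_missing), 0)

  a <- default_cohort()
  m <- mar_mask(a, 0.3)
  expect_equal(sum(m$is_missing), round(0.3 * nrow(a)))
  expect_lt(mean(a$mmse[m$is_missing]), mean(a$mmse[!m$is_missing]))
  expect_lt(mean(a$adcs_adl[m$is_missing]), mean(a$adcs_adl[!m$is_missing]))
  # deterministic given the cohort
  expect_identical(m, mar_mask(a, 0.3))
  expect_error(mar_mask(a, 1.2), "volume")
})

test_that("MNAR mask deletes the top costs", {
  coh <- toy_cohort((1:10) * 100)
  m <- mnar_mask(coh, 0.2)
  expect_equal(which(m$is_missing), c(9, 10))
  # separation: every missing cost above every observed cost
  expect_gt(min(coh$cost_total[m$is_missing]),
            max(coh$cost_total[!m$is_missing]))

  # degenerate all-equal costs: stable order, flagged
  flat <- toy_cohort(rep(500, 10))
  expect_warning(mf <- mnar_mask(flat, 0.2), "ties")
  expect_equal(which(mf$is_missing), c(1, 2))

  expect_error(mnar_mask(coh, 1), "volume")
})

test_that("MNAR complete-case mean approaches the truncated-mean benchmark", {
  a <- default_cohort()
  m <- mnar_mask(a, 0.1)
  cc <- mean(a$cost_total[!m$is_missing])
  oracle <- truncated_lognormal_mean(2101, 2381.39, 0.9)
  expect_lt(abs(cc - oracle) / oracle, 0.05)
})

test_that("dropout pattern assigns exclusive reasons at the target rates", {
  a <- default_cohort()
  m <- dropout_pattern_mask(a, dropout_config(), seed = 3)
  n <- nrow(a)
  tab <- table(m$reason)
  expect_equal(unname(tab[["institutionalised"]]), round(0.15 * n))
  expect_equal(unname(tab[["died"]]), round(0.06 * n))
  expect_equal(unname(tab[["lost_to_followup"]]), round(0.12 * n))
  # reasons partition the missing set
  expect_equal(sum(m$is_missing), sum(tab[c("institutionalised", "died",
                                            "lost_to_followup")]))
  expect_true(all((m$reason == "observed") == !m$is_missing))
  # overall volume ~33%
  expect_equal(100 * mean(m$is_missing), 33, tolerance = 0.02)
})

test_that("dropout sub-models select on their stated covariates", {
  a <- default_cohort()
  m <- dropout_pattern_mask(a, dropout_config(), seed = 3)
  inst <- m$reason == "institutionalised"
  obs <- m$reason == "observed"
  expect_gt(mean(total_caregiver_hours(a)[inst]),
            mean(total_caregiver_hours(a)[obs]))
  expect_lt(mean(a$mmse[inst]), mean(a$mmse[obs]))
  died <- m$reason == "died"
  expect_gt(mean(a$age[died]), mean(a$age[obs]))
})

test_that("threshold variant institutionalises exactly the >470 h group", {
  coh <- toy_cohort(rep(1000, 40), hours = c(rep(470, 20), rep(500, 20)))
  cfg <- dropout_config(variant = "mnar_inst", rate_died = 0,
                        rate_ltfu = 0, rate_institutionalised = 0.5)
  m <- dropout_pattern_mask(coh, cfg, seed = 1)
  # strict ">": exactly 470 h stays observed
  expect_true(all(m$reason[1:20] == "observed"))
  expect_true(all(m$reason[21:40] == "institutionalised"))

  # calibration warning when the threshold rate is far from target
  cfg2 <- dropout_config(variant = "mnar_inst", rate_died = 0,
                         rate_ltfu = 0, rate_institutionalised = 0.05)
  expect_warning(dropout_pattern_mask(coh, cfg2, seed = 1),
                 "target")
})

test_that("threshold variant hits the calibrated rate on a default cohort", {
  a <- default_cohort()
  m <- dropout_pattern_mask(a, dropout_config(variant = "mnar_inst"),
                            seed = 3)
  inst_rate <- mean(m$reason == "institutionalised")
  expect_lt(abs(inst_rate - 0.15), 0.03)  # binomial tolerance
  expect_equal(100 * mean(m$is_missing), 33, tolerance = 3)
})

test_that("dropout rates are validated", {
  expect_error(dropout_config(rate_institutionalised = 0.6, rate_died = 0.3,
                              rate_ltfu = 0.2), "sum")
  expect_error(dropout_config(rate_died = -0.1), ">= 0")
})

test_that("masked_costs aligns by patient id and rejects partial masks", {
  coh <- toy_cohort(c(100, 200, 300))
  m <- toy_mask(coh, 2)
  shuffled <- m[c(3, 1, 2), ]
  expect_equal(masked_costs(coh, shuffled), c(100, NA, 300))
  expect_error(masked_costs(coh, m[1:2, ]), "cover")
})
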