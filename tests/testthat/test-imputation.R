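test_that("complete-case estimate is the observed-only mean", {
  coh <- toy_cohort(c(100, 200, 300))
  est <- complete_case_estimate(coh, toy_mask(coh, 3))
  expect_equal(est$estimate, 150)
  expect_equal(est$se, sd(c(100, 200)) / sqrt(2))

  # no missing: identical to the full-sample mean
  est0 <- complete_case_estimate(coh, toy_mask(coh, integer(0)))
  expect_equal(est0$estimate, 200)
  expect_error(complete_case_estimate(coh, toy_mask(coh, 2:3)),
               "fewer than 2")
})

test_that("grouped-means imputation fills by MMSE severity group", {
  coh <- toy_cohort(c(1000, 2000, 5000, 700, 800),
                    mmse = c(25, 23, 10, 24, 12))
  m <- toy_mask(coh, 4:5)
  out <- grouped_means_impute(coh, m)
  expect_equal(out$cost_total[4], 1500)  # mild observed {1000, 2000}
  expect_equal(out$cost_total[5], 5000)  # severe observed {5000}
  expect_equal(out$cost_total[1:3], coh$cost_total[1:3])  # untouched

  # post-imputation group means equal the observed-only group means
  grp <- severity_group(out$mmse)
  obs_means <- tapply(masked_costs(coh, m), grp, mean, na.rm = TRUE)
  post_means <- tapply(out$cost_total, grp, mean)
  expect_equal(post_means[!is.na(obs_means)], obs_means[!is.na(obs_means)])

  # identity with no missing data
  expect_identical(grouped_means_impute(coh, toy_mask(coh, integer(0))),
                   coh)

  # empty observed group falls back to the overall mean, with a warning
  coh2 <- toy_cohort(c(1000, 2000, 900), mmse = c(25, 23, 10))
  expect_warning(out2 <- grouped_means_impute(coh2, toy_mask(coh2, 3)),
                 "overall mean")
  expect_equal(out2$cost_total[3], 1500)
})

test_that("fixed-cost imputation respects the reason filter", {
  coh <- toy_cohort(c(1000, 2000, 3000, 4000))
  r <- rep("observed", 4)
  r[2] <- "institutionalised"; r[3] <- "died"
  m <- costmiss:::new_mask(coh$patient_id, r, "TOY")
  out <- fixed_cost_impute(coh, m, fixed_cost = 2940,
                           reason_filter = "institutionalised")
  expect_equal(out$cost_total[2], 2940)
  expect_true(is.na(out$cost_total[3]))  # died stays missing
  expect_equal(out$cost_total[c(1, 4)], c(1000, 4000))

  out0 <- fixed_cost_impute(coh, m, fixed_cost = 0,
                            reason_filter = "institutionalised")
  expect_equal(out0$cost_total[2], 0)
  expect_error(fixed_cost_impute(coh, m, fixed_cost = -5), "non-negative")
})

test_that("EM on complete data equals the closed-form MLE", {
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  fit <- em_mvn(X)
  expect_equal(fit$mean, colMeans(X), ignore_attr = TRUE)
  expect_equal(fit$cov, cov(X) * 49 / 50, ignore_attr = TRUE)
})

test_that("EM handles a single variable with missing values", {
  fit <- em_mvn(matrix(c(1, 2, 3, NA), 4, 1))
  expect_equal(unname(fit$mean), 2)
})

test_that("EM log-likelihood is non-decreasing and parameters are recovered", {
  set.seed(42)
  n <- 2000
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  X <- matrix(rnorm(2 * n), n, 2) %*% chol(S)
  X[sample(n, 0.2 * n), 2] <- NA  # 20% MCAR
  fit <- em_mvn(X)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik) >= -1e-8 * abs(fit$loglik[-1])))
  expect_equal(unname(fit$mean), c(0, 0), tolerance = 0.1)
  expect_equal(unname(fit$cov[1, 2]), 0.5, tolerance = 0.1)
  expect_equal(unname(diag(fit$cov)), c(1, 1), tolerance = 0.1)
})

test_that("EM input validation and non-convergence carry diagnostics", {
  expect_error(em_mvn(matrix(c(1, NA, NA, 1, 2, 3), 3, 2)),
               "observed at least twice")
  set.seed(2)
  X <- matrix(rnorm(600), 200, 3)
  X[sample(600, 150)] <- NA
  err <- tryCatch(em_mvn(X, tol = 0, max_iter = 2L), error = identity)
  expect_s3_class(err, "error")
  expect_s3_class(attr(err, "last"), "cm_mvn")
})

test_that("MI with nothing to impute returns m identical copies", {
  X <- matrix(rnorm(40), 20, 2)
  out <- mi_mcmc(X, fast_mi(m = 4))
  expect_length(out, 4)
  for (j in 1:4) expect_equal(out[[j]], X)
})

test_that("MI preserves observed cells and varies imputed ones", {
  set.seed(3)
  X <- matrix(rnorm(300), 100, 3)
  X[1:20, 1] <- NA
  out <- mi_mcmc(X, fast_mi(m = 3))
  obs <- !is.na(X)
  for (j in 1:3) {
    expect_equal(out[[j]][obs], X[obs])
    expect_false(anyNA(out[[j]]))
  }
  expect_false(identical(out[[1]][1:20, 1], out[[2]][1:20, 1]))
})

test_that("single and multiple chain topologies both produce m datasets", {
  set.seed(4)
  X <- matrix(rnorm(200), 100, 2)
  X[1:10, 1] <- NA
  single <- mi_mcmc(X, mi_config(m = 3, burn_in = 50, thin = 10,
                                 chains = "single", seed = 9))
  multi <- mi_mcmc(X, mi_config(m = 3, burn_in = 50, thin = 10,
                                chains = "multiple", seed = 9))
  expect_length(single, 3)
  expect_length(multi, 3)
  expect_false(anyNA(unlist(single)))
  expect_false(anyNA(unlist(multi)))
})

test_that("Rubin pooling matches hand-computed values", {
  # between-variance only: means 1900/2100, SEs 0 -> SE = sqrt(1.5 * 20000)
  p <- pool_rubin(c(1900, 2100), c(0, 0))
  expect_equal(p$estimate, 2000)
  expect_equal(p$standard_error, sqrt(30000))
  expect_equal(p$within_variance, 0)
  expect_equal(p$between_variance, 20000)

  # no between-variance: SE equals the single-dataset SE
  p2 <- pool_rubin(rep(2000, 5), rep(50, 5))
  expect_equal(p2$estimate, 2000)
  expect_equal(p2$standard_error, 50)
  expect_equal(p2$df, Inf)

  # total variance identity and variance inflation
  p3 <- pool_rubin(c(1950, 2000, 2080), c(40, 45, 50))
  expect_equal(p3$standard_error^2,
               p3$within_variance + (1 + 1 / 3) * p3$between_variance)
  expect_gt(p3$standard_error, sqrt(p3$within_variance))
  # Barnard-Rubin df never exceeds the unadjusted df and respects dfcom
  expect_lt(pool_rubin(c(1950, 2000, 2080), c(40, 45, 50),
                       dfcom = 100)$df, p3$df)
  expect_error(pool_rubin(2000, 50), "m >= 2")
})

test_that("MI pooled estimates are unbiased under MCAR and MAR on MVN data", {
  # correctly specified model: trivariate normal, cost + two covariates
  mu <- c(cost = 2000, x1 = 0, x2 = 0)
  S <- matrix(c(250000, 250, 200,
                250, 1, 0.4,
                200, 0.4, 1), 3, 3, byrow = TRUE)
  ch <- chol(S)
  n <- 300
  reps <- 200
  est_mcar <- est_mar <- cc_mar <- numeric(reps)
  set.seed(99)
  seeds <- sample.int(1e6, reps)
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    X <- matrix(rnorm(3 * n), n, 3) %*% ch
    X <- sweep(X, 2, mu, "+")
    colnames(X) <- names(mu)

    Xm <- X
    Xm[sample(n, 0.2 * n), 1] <- NA  # MCAR 20%
    out <- mi_mcmc(Xm, fast_mi(seed = seeds[r]))
    means <- vapply(out, function(d) mean(d[, 1]), 0)
    ses <- vapply(out, function(d) sd(d[, 1]) / sqrt(n), 0)
    est_mcar[r] <- pool_rubin(means, ses)$estimate

    Xa <- X
    drop <- order(X[, 2] + X[, 3])[seq_len(0.2 * n)]  # MAR on covariates
    Xa[drop, 1] <- NA
    out <- mi_mcmc(Xa, fast_mi(seed = seeds[r] + 1L))
    means <- vapply(out, function(d) mean(d[, 1]), 0)
    ses <- vapply(out, function(d) sd(d[, 1]) / sqrt(n), 0)
    est_mar[r] <- pool_rubin(means, ses)$estimate
    cc_mar[r] <- mean(Xa[, 1], na.rm = TRUE)
  }
  mcse <- sd(est_mcar) / sqrt(reps)
  expect_lt(abs(mean(est_mcar) - 2000), 3 * mcse)
  mcse_mar <- sd(est_mar) / sqrt(reps)
  expect_lt(abs(mean(est_mar) - 2000), 3 * mcse_mar)
  # and MI removes the complete-case MAR bias
  expect_lt(abs(mean(est_mar) - 2000), abs(mean(cc_mar) - 2000))
})

test_that("combination imputation routes each reason to its method", {
  coh <- small_cohort()
  # only institutionalised missing + Scenario B reduces to fixed cost
  r <- rep("observed", nrow(coh))
  r[1:30] <- "institutionalised"
  m <- costmiss:::new_mask(coh$patient_id, r, "TOY")
  est <- combination_impute(coh, m, "B", fast_mi(), fixed_cost = 2940)
  manual <- mean(c(coh$cost_total[-(1:30)], rep(2940, 30)))
  expect_equal(est$estimate, manual)

  # no missing: full-sample mean
  m0 <- toy_mask(coh, integer(0))
  est0 <- combination_impute(coh, m0, "A", fast_mi())
  expect_equal(est0$estimate, mean(coh$cost_total))

  # generic-reason masks are rejected with a pointer to the dropout mask
  mg <- mcar_mask(coh, 0.1, seed = 1)
  expect_error(combination_impute(coh, mg, "A"), "dropout_pattern_mask")
})

test_that("no imputation method alters an observed cost", {
  coh <- small_cohort()
  m <- dropout_pattern_mask(coh, dropout_config(), seed = 5)
  obs <- !m$is_missing
  gm <- grouped_means_impute(coh, m)
  expect_equal(gm$cost_total[obs], coh$cost_total[obs])
  fc <- fixed_cost_impute(coh, m)
  expect_equal(fc$cost_total[obs], coh$cost_total[obs])
  y <- masked_costs(coh, m)
  X <- cbind(cost = y, mmse = coh$mmse, adl = coh$adcs_adl)
  out <- mi_mcmc(X, fast_mi())
  for (d in out) expect_equal(d[obs, "cost"], y[obs], ignore_attr = TRUE)
})
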