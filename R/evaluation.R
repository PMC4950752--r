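#' Mechanism specification for the simulation engine
#'
#' @param mechanism `"MCAR"`, `"MAR"`, `"MNAR"`, or the mixed dropout
#'   patterns `"dropout_mar_inst"` / `"dropout_mnar_inst"`.
#' @param volume missing fraction for MCAR/MAR/MNAR; ignored for dropout
#'   patterns, whose volume is set by `config`'s rates.
#' @param config a [dropout_config()] for the dropout patterns.
#' @return A list of class `"cm_mechanism"`.
#' @export
mechanism_spec <- function(mechanism = c("MCAR", "MAR", "MNAR",
                                         "dropout_mar_inst",
                                         "dropout_mnar_inst"),
                           volume = 0.1, config = NULL) {
  mechanism <- match.arg(mechanism)
  if (startsWith(mechanism, "dropout")) {
    variant <- sub("dropout_", "", mechanism)
    if (is.null(config)) config <- dropout_config(variant = variant)
    if (config$variant != variant) stop("config variant mismatch")
    volume <- config$rate_institutionalised + config$rate_died +
      config$rate_ltfu
  } else {
    check_volume(volume)
  }
  structure(list(mechanism = mechanism, volume = volume, config = config),
            class = "cm_mechanism")
}

apply_mechanism <- function(cohort, spec, seed) {
  switch(spec$mechanism,
    MCAR = mcar_mask(cohort, spec$volume, seed = seed),
    MAR = mar_mask(cohort, spec$volume),
    MNAR = suppressWarnings(mnar_mask(cohort, spec$volume)),
    dropout_mar_inst = ,
    dropout_mnar_inst = suppressWarnings(
      dropout_pattern_mask(cohort, spec$config, seed = seed))
  )
}

#' Run one simulation cell
#'
#' The resampling experiment for one (mechanism, method) pair: each
#' iteration bootstrap-resamples the analysis set with replacement to its
#' own size, re-derives the missingness mask on the resample (thresholds and
#' calibrations are re-solved, so MAR/MNAR volumes stay exact), applies the
#' estimation method, and records the mean, SE and 95% CI. A master seed
#' spawns one independent seed per iteration, recorded in the result for
#' replay.
#'
#' @param cohort complete analysis set (its mean is the "true" cost).
#' @param mechanism a [mechanism_spec()].
#' @param method method name passed to [estimate_mean()].
#' @param n_iter number of bootstrap iterations (1000 in the full design;
#'   reduce for desk-scale runs).
#' @param seed master seed.
#' @param ... further arguments to [estimate_mean()] (e.g. `config`,
#'   `mi_covariates`, `fixed_cost`).
#' @return A data.frame of class `"cm_iterations"` with columns `iteration`,
#'   `mean_estimate`, `se_estimate`, `ci_low`, `ci_high`; attributes carry
#'   the true mean, per-iteration seeds and the cell description.
#' @export
run_cell <- function(cohort, mechanism, method = "complete_case",
                     n_iter = 1000L, seed = 1L, ...) {
  stopifnot(inherits(mechanism, "cm_mechanism"))
  if (anyNA(cohort$cost_total))
    stop("cohort must be the complete analysis set; see analysis_set()")
  if (startsWith(method, "combination") &&
      !startsWith(mechanism$mechanism, "dropout"))
    stop("combination methods need reason channels; ",
         "use a dropout mechanism")
  true_mean <- mean(cohort$cost_total)
  n <- nrow(cohort)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)

  dots <- list(...)
  res <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[i])
    boot <- cohort[sample.int(n, n, replace = TRUE), , drop = FALSE]
    boot$patient_id <- sprintf("B%05d", seq_len(n))  # resample identities
    mask <- apply_mechanism(boot, mechanism, seed = iter_seeds[i])
    args <- c(list(cohort = boot, mask = mask, method = method), dots)
    if (startsWith(method, "mi") || startsWith(method, "combination")) {
      cfg <- if (!is.null(dots$config)) dots$config else mi_config()
      cfg$seed <- iter_seeds[i]
      args$config <- cfg
    }
    est <- do.call(estimate_mean, args)
    res[[i]] <- data.frame(iteration = i, mean_estimate = est$estimate,
                           se_estimate = est$se, ci_low = est$ci_low,
                           ci_high = est$ci_high)
  }
  out <- do.call(rbind, res)
  attr(out, "true_mean") <- true_mean
  attr(out, "seeds") <- iter_seeds
  attr(out, "cell") <- list(mechanism = mechanism$mechanism,
                            volume = mechanism$volume, method = method,
                            n = n, n_iter = n_iter, seed = seed)
  class(out) <- c("cm_iterations", "data.frame")
  out
}

#' Summarise a simulation cell
#'
#' The six outcome measures of the resampling experiment: mean cost
#' (average of iteration means); absolute bias (mean cost minus true mean)
#' and relative bias (100 x absolute bias / true mean; negative =
#' underestimation); SSE, the sampling standard error (SD of the iteration
#' means); SEE, the mean of the iteration SEs; the SEE/SSE ratio (an
#' adequate SE estimator gives a ratio near 1); and the coverage
#' probability, the fraction of iterations whose 95% CI contains the true
#' mean.
#'
#' @param iterations a `"cm_iterations"` frame from [run_cell()], or any
#'   data frame with its columns.
#' @param true_mean the complete-sample mean; defaults to the value recorded
#'   by [run_cell()].
#' @return A one-row data.frame of class `"cm_summary"`.
#' @export
summarize_cell <- function(iterations, true_mean = attr(iterations,
                                                        "true_mean")) {
  if (is.null(true_mean)) stop("true_mean is required")
  if (true_mean == 0) stop("relative bias undefined for true_mean = 0")
  if (nrow(iterations) < 2) stop("need at least 2 iterations")
  mean_cost <- mean(iterations$mean_estimate)
  abs_bias <- mean_cost - true_mean
  sse <- stats::sd(iterations$mean_estimate)
  see <- mean(iterations$se_estimate)
  cp <- mean(iterations$ci_low <= true_mean & true_mean <= iterations$ci_high)
  cell <- attr(iterations, "cell")
  out <- data.frame(
    method = if (!is.null(cell)) cell$method else NA_character_,
    mechanism = if (!is.null(cell)) cell$mechanism else NA_character_,
    volume = if (!is.null(cell)) cell$volume else NA_real_,
    true_mean = true_mean, mean_cost = mean_cost,
    absolute_bias = abs_bias,
    relative_bias_pct = 100 * abs_bias / true_mean,
    sse = sse, see = see,
    see_sse_ratio = if (sse > 0) see / sse else NA_real_,
    coverage_probability = cp,
    n_iter = nrow(iterations))
  class(out) <- c("cm_summary", "data.frame")
  out
}

#' Run a grid of simulation cells
#'
#' One [run_cell()]/[summarize_cell()] pass per (mechanism x method)
#' combination, mirroring the full design: three mechanisms at four volumes
#' plus the two mixed dropout patterns, crossed with the estimation methods.
#'
#' @param cohort complete analysis set.
#' @param mechanisms list of [mechanism_spec()] objects.
#' @param methods character vector of method names.
#' @param n_iter iterations per cell.
#' @param seed master seed; each cell gets an independent derived seed.
#' @param ... passed to [run_cell()].
#' @return A data.frame of class `"cm_summary"`, one row per cell.
#' @export
run_grid <- function(cohort, mechanisms, methods, n_iter = 1000L,
                     seed = 1L, ...) {
  stopifnot(length(mechanisms) > 0, length(methods) > 0)
  set.seed(seed)
  cells <- expand.grid(mech = seq_along(mechanisms),
                       method = methods, stringsAsFactors = FALSE)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    it <- run_cell(cohort, mechanisms[[cells$mech[k]]],
                   method = cells$method[k], n_iter = n_iter,
                   seed = cell_seeds[k], ...)
    summarize_cell(it)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cm_summary", "data.frame")
  out
}

#' Default mechanism grid
#'
#' MCAR, MAR and MNAR at 10/20/30/40% missing plus the two mixed dropout
#' patterns — the fourteen simulation datasets of the full design.
#'
#' @return A named list of [mechanism_spec()] objects.
#' @export
default_mechanisms <- function() {
  specs <- list()
  for (mech in c("MCAR", "MAR", "MNAR"))
    for (v in c(0.1, 0.2, 0.3, 0.4))
      specs[[sprintf("%s_%d", mech, round(100 * v))]] <-
        mechanism_spec(mech, v)
  specs$dropout_mar_inst <- mechanism_spec("dropout_mar_inst")
  specs$dropout_mnar_inst <- mechanism_spec("dropout_mnar_inst")
  specs
}
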