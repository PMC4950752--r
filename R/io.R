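#' Write and read cohorts and masks as delimited tables
#'
#' Comma-separated, UTF-8, header row, missing cells empty ("." and "NA"
#' are also accepted on read). Round-trips preserve every field to full
#' precision. The generating seed is echoed into a JSON metadata sidecar
#' (`<path>.meta.json`).
#'
#' @param cohort,mask object to serialise.
#' @param path output file.
#' @return `path`, invisibly; readers return the reconstructed object.
#' @name serialisation
NULL

write_meta <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname serialisation
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], format, digits = 17, trim = TRUE,
                    scientific = FALSE)
  df[df == "NA"] <- ""
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  p <- attr(cohort, "params")
  write_meta(path, list(type = "cohort",
                        seed = attr(cohort, "seed"),
                        params = if (!is.null(p)) unclass(p) else NULL))
  invisible(path)
}

#' @rdname serialisation
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "."),
                        fileEncoding = "UTF-8")
  df$caregiver_working <- as.logical(df$caregiver_working)
  df$baseline_complete <- as.logical(df$baseline_complete)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(df, "seed") <- meta$seed
  }
  class(df) <- c("cm_cohort", "data.frame")
  df
}

#' @rdname serialisation
#' @export
write_mask <- function(mask, path) {
  utils::write.csv(data.frame(patient_id = mask$patient_id,
                              reason = as.character(mask$reason)),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  write_meta(path, list(type = "mask", mechanism = attr(mask, "mechanism"),
                        params = attr(mask, "mask_params")))
  invisible(path)
}

#' @rdname serialisation
#' @export
read_mask <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  m <- new_mask(df$patient_id, df$reason, mechanism = NA_character_)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(m, "mechanism") <- meta$mechanism
    attr(m, "mask_params") <- meta$params
  }
  m
}

config_defaults <- function() {
  list(
    n = 1497L, seed = 1L,
    completeness_rate = 0.994,
    cost_mean = 2101, cost_sd = 2381.39,
    mechanism = "MCAR", volume = 0.1,
    method = "complete_case",
    scenario = NA_character_,
    n_iter = 1000L,
    m = 5L, burn_in = 2000L, thin = 500L,
    fixed_cost = 2940,
    rate_institutionalised = 0.15, rate_died = 0.06, rate_ltfu = 0.12,
    caregiver_time_threshold = 470
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML configuration (by file extension; `.json` vs
#' `.yml`/`.yaml`), fills defaults for absent keys, rejects unknown keys,
#' and validates every parameter against its type invariant.
#'
#' @param path configuration file.
#' @return A named list of class `"cm_config"` with all defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  # YAML 1.1 would read a bare key like "n" as a boolean; keep such scalars
  # as literal strings (no config field is logical)
  keep_yn <- function(x) if (x %in% c("y", "Y", "n", "N")) x else
    as.logical(toupper(x) %in% c("TRUE", "YES", "ON"))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yml", "yaml"))
    yaml::read_yaml(path, handlers = list("bool#yes" = keep_yn,
                                          "bool#no" = keep_yn))
  else stop("config must be JSON or YAML")
  if (is.null(cfg)) cfg <- list()
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  full <- utils::modifyList(defaults, cfg)

  if (full$n <= 0) stop("invalid 'n': must be positive")
  if (full$completeness_rate <= 0 || full$completeness_rate > 1)
    stop("invalid 'completeness_rate': must be in (0, 1]")
  if (full$cost_sd < 0) stop("invalid 'cost_sd': must be non-negative")
  if (full$volume < 0 || full$volume >= 1)
    stop("invalid 'volume': must be in [0, 1)")
  if (full$m < 2) stop("invalid 'm': multiple imputation requires m >= 2")
  if (full$burn_in < 0 || full$thin < 1)
    stop("invalid MCMC settings: burn_in >= 0 and thin >= 1 required")
  if (full$n_iter < 1) stop("invalid 'n_iter': must be at least 1")
  if (full$fixed_cost < 0) stop("invalid 'fixed_cost': must be >= 0")
  rates <- c(full$rate_institutionalised, full$rate_died, full$rate_ltfu)
  if (any(rates < 0) || sum(rates) > 1)
    stop("invalid dropout rates: each >= 0, sum <= 1")
  structure(full, class = c("cm_config", "list"))
}

#' Render a simulation summary table
#'
#' Writes the cell summaries in the layout of the study's results tables:
#' method, mechanism, volume, mean cost, bias (EUR and %), SSE, SEE,
#' SEE/SSE, CP. Costs are rendered to the euro, coverage probability to two
#' decimals.
#'
#' @param summaries a `"cm_summary"` data frame (one row per cell).
#' @param path output file.
#' @param format `"delimited"` (CSV) or `"text"` (aligned, human-readable).
#' @return `path`, invisibly.
#' @export
write_report <- function(summaries, path, format = c("delimited", "text")) {
  format <- match.arg(format)
  if (is.null(summaries) || nrow(summaries) == 0)
    stop("no summaries to report")
  tab <- data.frame(
    method = summaries$method,
    mechanism = summaries$mechanism,
    volume = summaries$volume,
    mean_cost = sprintf("%.0f", summaries$mean_cost),
    bias = sprintf("%.0f", summaries$absolute_bias),
    bias_pct = sprintf("%.1f", summaries$relative_bias_pct),
    sse = sprintf("%.0f", summaries$sse),
    see = sprintf("%.0f", summaries$see),
    see_sse = sprintf("%.2f", summaries$see_sse_ratio),
    cp = sprintf("%.2f", summaries$coverage_probability),
    stringsAsFactors = FALSE)
  if (format == "delimited") {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    m <- as.matrix(tab)
    m[is.na(m)] <- ""
    widths <- pmax(nchar(names(tab)), apply(nchar(m), 2, max))
    fmt_row <- function(r) paste(mapply(formatC, r, width = widths),
                                 collapse = "  ")
    writeLines(c(fmt_row(names(tab)), apply(m, 1, fmt_row)), path,
               useBytes = TRUE)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to replay a run: the configuration snapshot,
#' master and derived seeds, package version, timestamp, and md5 digests of
#' the input/output files.
#'
#' @param path manifest file (JSON).
#' @param config configuration list used for the run.
#' @param seed master seed.
#' @param stage_seeds named list/vector of per-stage seeds.
#' @param files character vector of input/output paths to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, stage_seeds = NULL,
                           files = character(0)) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "costmiss",
    version = as.character(utils::packageVersion("costmiss")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = seed,
    stage_seeds = stage_seeds,
    config = if (inherits(config, "cm_config")) unclass(config) else config,
    file_digests = if (length(files))
      as.list(stats::setNames(unname(tools::md5sum(files)), files))
    else NULL)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
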