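# CSV dialects: UTF-8, comma separated, '.' decimal, header required.
# One neutral schema instead of the vendors' proprietary exports.

partition_cols <- c("run_id", "day", "well_id", "sample_id", "role",
                    "target", "n_total", "n_positive")

#' Read a partition-count CSV
#'
#' Reads the long per-channel partition-count table (columns `run_id`, `day`,
#' `well_id`, `sample_id`, `role`, `target`, `n_total`, `n_positive`,
#' optional `n_rain` defaulting to 0, optional `nominal_level`). Strict: a
#' missing required column or a duplicated (run, well, target) row is an
#' error, not a warning.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `well_data`.
#' @export
read_partition_csv <- function(path) {
  if (!file.exists(path)) {
    stop_dpcr("invalid_argument", "file not found: %s", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, partition_cols, sprintf("'%s'", path))
  if (!"n_rain" %in% names(df)) df$n_rain <- 0L
  for (col in c("n_total", "n_positive", "n_rain")) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]]) ||
        any(df[[col]] != round(df[[col]])) || any(df[[col]] < 0)) {
      stop_dpcr("schema_error",
                "column '%s' must contain non-negative integer counts", col)
    }
    df[[col]] <- as.integer(df[[col]])
  }
  bad_role <- setdiff(unique(df$role), c("sample", "ntc", "positive_control"))
  if (length(bad_role)) {
    stop_dpcr("schema_error", "unknown role value(s): %s",
              paste(bad_role, collapse = ", "))
  }
  if (any(df$n_positive > df$n_total) || any(df$n_rain > df$n_total)) {
    stop_dpcr("schema_error", "n_positive/n_rain may not exceed n_total")
  }
  key <- paste(df$run_id, df$well_id, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("run_id", "well_id", "target")][1, ]
    stop_dpcr("duplicate_row", "duplicate (well, target) row: %s / %s / %s",
              dup$run_id, dup$well_id, dup$target)
  }
  class(df) <- c("well_data", "data.frame")
  df
}

#' Write a partition-count CSV
#'
#' @param wells A `well_data` table (see [read_partition_csv()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_partition_csv <- function(wells, path) {
  assert_columns(wells, partition_cols, "`wells`")
  utils::write.csv(as.data.frame(wells), path, row.names = FALSE)
  invisible(path)
}

#' Read a per-partition amplitude CSV
#'
#' Columns `well_id`, `target`, `amplitude`; one row per partition. Per-well
#' amplitude lists preserve file order. A non-numeric amplitude is a parse
#' error reported with its line number.
#'
#' @param path Path to the CSV file.
#' @return A named list of numeric amplitude vectors, one element per
#'   `well_id.target` combination, in order of first appearance.
#' @export
read_amplitude_csv <- function(path) {
  if (!file.exists(path)) {
    stop_dpcr("invalid_argument", "file not found: %s", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  assert_columns(df, c("well_id", "target", "amplitude"),
                 sprintf("'%s'", path))
  amp <- suppressWarnings(as.numeric(df$amplitude))
  if (anyNA(amp)) {
    # +1 for the header line
    stop_dpcr("parse_error", "non-numeric amplitude at line %d of %s",
              which(is.na(amp))[1] + 1L, path)
  }
  if (!nrow(df)) return(list())
  key <- paste(df$well_id, df$target, sep = ".")
  split(amp, factor(key, levels = unique(key)))
}

#' Run configuration for the analysis pipeline
#'
#' Collects all tunables of a pipeline run: platform, conversion factor,
#' certified reference values, acceptance thresholds and the simulation
#' design. Unknown keys are rejected by name, so typos cannot silently fall
#' back to defaults.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return An object of class `run_config`.
#' @section Keys:
#' `platform` (a [platform_profile()] or preset name), `conversion_factor`,
#' `reference_values` (named numeric, level -> accepted value),
#' `u_ref_relative`, `design` (a [simulation_design()]),
#' `robustness_factors` (character vector), and the thresholds
#' `trueness_threshold` (25), `precision_threshold` (25),
#' `robustness_threshold` (30), `rain_threshold` (0.025), `r2_min` (0.98),
#' `slope_tol` (0.25), plus `seed`.
#' @examples
#' run_config(platform = "qiacuity26k", seed = 11)
#' @export
run_config <- function(...) {
  defaults <- list(
    platform = "qx200",
    conversion_factor = 1,
    reference_values = NULL,
    u_ref_relative = 0,
    design = simulation_design(),
    robustness_factors = c("mastermix_-10pct", "annealing_+1C",
                           "ramp_+0.5C_s", "oligo_-10pct"),
    trueness_threshold = 25,
    precision_threshold = 25,
    robustness_threshold = 30,
    rain_threshold = 0.025,
    r2_min = 0.98,
    slope_tol = 0.25,
    seed = NULL
  )
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(names(overrides) == ""))) {
    stop_dpcr("invalid_argument", "all configuration values must be named")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_dpcr("invalid_argument", "unknown configuration key(s): %s",
              paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  if (is.character(cfg$platform)) cfg$platform <- platform_profile(cfg$platform)
  if (!inherits(cfg$platform, "platform_profile")) {
    stop_dpcr("invalid_argument", "`platform` must be a platform_profile or preset name")
  }
  for (key in c("trueness_threshold", "precision_threshold",
                "robustness_threshold", "rain_threshold", "r2_min",
                "slope_tol", "conversion_factor")) {
    assert_scalar_number(cfg[[key]], key, min = 0, strict_min = TRUE)
  }
  if (!is.null(cfg$seed)) {
    cfg$seed <- assert_count(cfg$seed, "seed")
    cfg$design$seed <- cfg$seed
  }
  structure(cfg, class = "run_config")
}

write_manifest <- function(path, config, extra = list()) {
  cfg_hash <- substr(tools::md5sum(
    files = {
      tmp <- tempfile()
      writeLines(deparse(unclass(config)), tmp)
      tmp
    }), 1, 12)
  lines <- c(
    sprintf("config_hash=%s", unname(cfg_hash)),
    sprintf("seed=%s", if (is.null(config$seed)) "NA" else config$seed),
    sprintf("package_version=%s",
            as.character(utils::packageVersion("dpcrval"))),
    vapply(names(extra), function(k) sprintf("%s=%s", k, extra[[k]]),
           character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

pipeline_stages <- c("simulate", "quantify", "gm_content", "validate",
                     "robustness", "report")

#' Run the analysis pipeline
#'
#' Chains the stages `simulate` (write a synthetic partition-count CSV and
#' run manifest), `quantify` (per-well lambda/concentration CSV),
#' `gm_content` (per-sample GM % CSV), `validate` (per-level validation
#' report with linearity and dynamic range), `robustness` (simulated
#' multifactorial experiment at the lowest design level), and `report`
#' (combined validation-report CSV). Stages run in fixed order; each output
#' is a CSV next to a `manifest.txt` recording the config hash and seed.
#' Existing outputs are only overwritten with `overwrite = TRUE`.
#'
#' @param config A [run_config()].
#' @param stages Subset of the stage names above (default: all).
#' @param out_dir Output directory (created if missing).
#' @param overwrite Overwrite existing outputs.
#' @return Invisibly, a named list of the paths written.
#' @examples
#' cfg <- run_config(design = simulation_design(levels = c(1, 10),
#'                                              replicates_per_level = 2,
#'                                              runs = 2, seed = 5))
#' out <- run_pipeline(cfg, out_dir = tempfile())
#' @export
run_pipeline <- function(config, stages = pipeline_stages,
                         out_dir = ".", overwrite = FALSE) {
  if (!inherits(config, "run_config")) {
    stop_dpcr("invalid_argument", "`config` must be a run_config")
  }
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    partitions = file.path(out_dir, "partitions.csv"),
    quantification = file.path(out_dir, "quantification.csv"),
    gm_content = file.path(out_dir, "gm_content.csv"),
    validation = file.path(out_dir, "validation_report.csv"),
    linearity = file.path(out_dir, "linearity.csv"),
    robustness = file.path(out_dir, "robustness.csv"),
    report = file.path(out_dir, "report.csv"),
    manifest = file.path(out_dir, "manifest.txt")
  )
  need_out <- function(p) {
    if (file.exists(p) && !overwrite) {
      stop_dpcr("exists_error",
                "output '%s' exists; pass overwrite = TRUE to replace it", p)
    }
    p
  }
  need_in <- function(p, stage) {
    if (!file.exists(p)) {
      stop_dpcr("missing_input",
                "stage '%s' needs '%s'; run the earlier stages first", stage, p)
    }
    p
  }
  written <- list()

  if ("simulate" %in% stages) {
    wells <- simulate_experiment(config$design, config$platform,
                                 config$conversion_factor)
    write_partition_csv(wells, need_out(paths$partitions))
    write_manifest(paths$manifest, config,
                   extra = list(stage = "simulate"))
    written$partitions <- paths$partitions
    written$manifest <- paths$manifest
  }
  if ("quantify" %in% stages) {
    wells <- read_partition_csv(need_in(paths$partitions, "quantify"))
    quant <- quantify_wells(wells, config$platform)
    utils::write.csv(quant, need_out(paths$quantification), row.names = FALSE)
    written$quantification <- paths$quantification
  }
  if ("gm_content" %in% stages) {
    quant <- utils::read.csv(need_in(paths$quantification, "gm_content"),
                             stringsAsFactors = FALSE)
    gm <- gm_measurements(quant, config$conversion_factor)
    utils::write.csv(gm, need_out(paths$gm_content), row.names = FALSE)
    written$gm_content <- paths$gm_content
  }
  if ("validate" %in% stages) {
    gm <- utils::read.csv(need_in(paths$gm_content, "validate"),
                          stringsAsFactors = FALSE)
    vs <- validation_summary(gm, config$reference_values,
                             config$u_ref_relative,
                             config$trueness_threshold,
                             config$precision_threshold)
    utils::write.csv(vs, need_out(paths$validation), row.names = FALSE)
    lin <- linearity(gm, r2_min = config$r2_min,
                     slope_tol = config$slope_tol)
    utils::write.csv(lin$per_run, need_out(paths$linearity),
                     row.names = FALSE)
    written$validation <- paths$validation
    written$linearity <- paths$linearity
  }
  if ("robustness" %in% stages) {
    design <- robustness_design(config$robustness_factors)
    level <- min(config$design$levels)
    seed <- if (is.null(config$design$seed)) NULL else config$design$seed + 1L
    meas <- with_seed(seed, {
      do.call(rbind, lapply(design$condition, function(cond) {
        data.frame(condition = cond,
                   gm_percent = level *
                     rlnorm_cv(config$design$replicates_per_level * 2L,
                               config$design$noise_cv))
      }))
    })
    rb <- robustness_evaluate(meas, level, config$robustness_threshold)
    utils::write.csv(rb$table, need_out(paths$robustness), row.names = FALSE)
    written$robustness <- paths$robustness
  }
  if ("report" %in% stages) {
    vs <- utils::read.csv(need_in(paths$validation, "report"),
                          stringsAsFactors = FALSE)
    dr <- dynamic_range_assessment(vs, config$trueness_threshold,
                                   config$precision_threshold)
    rep_tab <- dr$table
    rep_tab$platform <- config$platform$name
    utils::write.csv(rep_tab, need_out(paths$report), row.names = FALSE)
    written$report <- paths$report
  }
  invisible(written)
}
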