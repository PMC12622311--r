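#' Trueness (relative bias) against an accepted reference value
#'
#' Bias is the relative deviation of the mean measured value from the
#' accepted reference value, in percent. The acceptance rule for GMO
#' quantification methods is that the measured value stays within +/- 25% of
#' the reference over the whole dynamic range. Bias is computed signed;
#' reports conventionally print its magnitude.
#'
#' @param measured Non-empty numeric vector of measured GM % values.
#' @param reference_value Accepted reference value (> 0).
#' @param threshold Acceptance threshold on `|bias|`, percent (default 25).
#' @return A list with `mean`, `bias_percent` (signed),
#'   `bias_abs_percent`, `pass`.
#' @examples
#' trueness(c(98.5, 98.9, 98.6), 99.6)
#' @export
trueness <- function(measured, reference_value, threshold = 25) {
  if (!is.numeric(measured) || !length(measured) || anyNA(measured)) {
    stop_dpcr("invalid_argument", "`measured` must be non-empty and numeric")
  }
  assert_scalar_number(reference_value, "reference_value",
                       min = 0, strict_min = TRUE)
  m <- mean(measured)
  bias <- 100 * (m - reference_value) / reference_value
  list(mean = m, bias_percent = bias, bias_abs_percent = abs(bias),
       pass = abs(bias) <= threshold)
}

#' Repeatability and intermediate precision
#'
#' Decomposes replicate measurements grouped by run into a within-run
#' (repeatability) and a between-run variance component. The repeatability
#' standard deviation `sr` is the pooled within-run SD (square root of the
#' one-way ANOVA residual mean square, fitted with [stats::aov()]); the
#' between-run component uses the standard one-way random-effects moment
#' estimator, and intermediate precision combines the two. With a single run
#' (or no run labels) `sr` falls back to the plain SD of all measurements.
#'
#' @param measured Numeric vector of measurements (>= 2 values).
#' @param run Optional run labels, one per measurement.
#' @param threshold Acceptance threshold on RSDr, percent (default 25).
#' @return A list with `mean`, `sr`, `rsdr_percent`, `s_between`,
#'   `s_intermediate`, `rsd_intermediate_percent`, `n`, `n_runs`, `pass`.
#' @examples
#' precision(c(0.9, 1.0, 1.1))
#' precision(c(1, 1, 2, 2), run = c("a", "a", "b", "b"))
#' @export
precision <- function(measured, run = NULL, threshold = 25) {
  if (!is.numeric(measured) || anyNA(measured)) {
    stop_dpcr("invalid_argument", "`measured` must be numeric without NA")
  }
  n <- length(measured)
  if (n < 2L) {
    stop_dpcr("undefined_sd", "need at least two measurements for a SD")
  }
  m <- mean(measured)
  if (is.null(run)) run <- rep("run1", n)
  if (length(run) != n) {
    stop_dpcr("invalid_argument", "`run` must have one label per measurement")
  }
  run <- factor(run)
  k <- nlevels(run)
  sizes <- as.integer(table(run))
  if (k < 2L || all(sizes < 2L)) {
    # single group (or no replication within runs): flat SD, no decomposition
    sr <- stats::sd(measured)
    s_b <- NA_real_
    s_ip <- sr
  } else {
    fit <- stats::aov(measured ~ run)
    sq <- summary(fit)[[1]]
    msw <- sq["Residuals", "Mean Sq"]
    msb <- sq[1, "Mean Sq"]
    sr <- sqrt(msw)
    n0 <- (n - sum(sizes^2) / n) / (k - 1)
    s_b <- sqrt(max(0, (msb - msw) / n0))
    s_ip <- sqrt(sr^2 + s_b^2)
  }
  rsdr <- if (m > 0) 100 * sr / m else NA_real_
  list(mean = m, sr = sr, rsdr_percent = rsdr,
       s_between = s_b, s_intermediate = s_ip,
       rsd_intermediate_percent = if (m > 0) 100 * s_ip / m else NA_real_,
       n = n, n_runs = k,
       pass = !is.na(rsdr) && rsdr <= threshold)
}

#' Per-level validation summary table
#'
#' Builds the standard per-level validation report from replicate GM
#' measurements: n, mean, repeatability SD, RSDr %, signed and absolute bias
#' %, bias-component standard uncertainty, expanded measurement uncertainty
#' (k = 2) and the trueness/precision pass flags.
#'
#' @param measurements A `data.frame` with columns `nominal_level`,
#'   `gm_percent` and optionally `run_id`.
#' @param reference_values Named numeric vector mapping `nominal_level`
#'   (as formatted by `format()`) to the accepted reference value; levels
#'   not named use the nominal level itself as reference.
#' @param u_ref_relative Relative standard uncertainty of the reference
#'   values (default 0).
#' @param trueness_threshold,precision_threshold Acceptance thresholds in
#'   percent (default 25/25).
#' @return A `data.frame` with one row per level: `level`, `n`,
#'   `mean_measured`, `sr`, `rsdr_percent`, `bias_percent`,
#'   `bias_abs_percent`, `u_bias`, `expanded_u_percent`, `pass_trueness`,
#'   `pass_precision`.
#' @examples
#' m <- simulate_gm_measurements(c(0.1, 1, 10), cv = 0.1, seed = 1)
#' validation_summary(m)
#' @export
validation_summary <- function(measurements, reference_values = NULL,
                               u_ref_relative = 0,
                               trueness_threshold = 25,
                               precision_threshold = 25) {
  assert_columns(measurements, c("nominal_level", "gm_percent"),
                 "`measurements`")
  levels_ <- sort(unique(measurements$nominal_level))
  rows <- lapply(levels_, function(L) {
    sub <- measurements[measurements$nominal_level == L, , drop = FALSE]
    ref <- L
    if (!is.null(reference_values)) {
      key <- format(L)
      if (key %in% names(reference_values)) ref <- reference_values[[key]]
    }
    tr <- trueness(sub$gm_percent, ref, threshold = trueness_threshold)
    pr <- precision(sub$gm_percent,
                    run = if ("run_id" %in% names(sub)) sub$run_id else NULL,
                    threshold = precision_threshold)
    mu <- measurement_uncertainty(mean_measured = tr$mean,
                                  rsdr_percent = pr$rsdr_percent,
                                  n = pr$n,
                                  bias_percent = tr$bias_percent,
                                  u_ref_relative = u_ref_relative)
    data.frame(level = L, n = pr$n, mean_measured = tr$mean,
               sr = pr$sr, rsdr_percent = pr$rsdr_percent,
               bias_percent = tr$bias_percent,
               bias_abs_percent = tr$bias_abs_percent,
               u_bias = mu$u_bias_relative * tr$mean,
               expanded_u_percent = mu$expanded_u,
               pass_trueness = tr$pass, pass_precision = pr$pass)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dynamic range assessment
#'
#' Flags every level of a per-level validation summary on the trueness and
#' precision criteria and reports the validated dynamic range: the widest
#' contiguous span of levels on which both criteria pass.
#'
#' @param summary A per-level table as returned by [validation_summary()]
#'   (needs `level`, `rsdr_percent`, `bias_abs_percent` or `bias_percent`).
#' @param trueness_threshold,precision_threshold Thresholds in percent.
#' @return A list with `table` (levels plus `pass_both`), `range`
#'   (`c(low, high)` of the widest passing span, or `NULL` if none), and
#'   `all_pass`.
#' @export
dynamic_range_assessment <- function(summary, trueness_threshold = 25,
                                     precision_threshold = 25) {
  assert_columns(summary, c("level", "rsdr_percent"), "`summary`")
  if (nrow(summary) < 2L) {
    stop_dpcr("invalid_argument", "need at least two levels")
  }
  bias <- if ("bias_abs_percent" %in% names(summary))
    summary$bias_abs_percent else abs(summary$bias_percent)
  tab <- summary[order(summary$level), , drop = FALSE]
  bias <- bias[order(summary$level)]
  tab$pass_trueness <- bias <= trueness_threshold
  tab$pass_precision <- tab$rsdr_percent <= precision_threshold
  tab$pass_both <- tab$pass_trueness & tab$pass_precision
  # widest contiguous run of passing levels
  r <- rle(tab$pass_both)
  range_out <- NULL
  if (any(r$values)) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    range_out <- c(tab$level[starts[best]], tab$level[ends[best]])
  }
  rownames(tab) <- NULL
  list(table = tab, range = range_out, all_pass = all(tab$pass_both))
}

#' Linearity of measured against nominal GM level
#'
#' Fits, per run, an ordinary least squares regression of measured GM % on
#' nominal GM % (linear scale). Replicates are averaged within run x level
#' before fitting by default, matching the convention of per-run validation
#' reports; set `aggregate = FALSE` to fit on raw replicate pairs. Acceptance
#' requires R^2 >= 0.98 and slope within 1 +/- 0.25 for every run.
#'
#' @param measurements A `data.frame` with `nominal_level`, `gm_percent`,
#'   and optionally `run_id` (a single run is assumed if absent).
#' @param aggregate Average replicates within run x level before the fit.
#' @param r2_min Minimum R^2 (default 0.98).
#' @param slope_tol Half-width of the slope acceptance band about 1
#'   (default 0.25).
#' @return An object of class `linearity_result`: `per_run` `data.frame`
#'   (`run_id`, `slope`, `intercept`, `r_squared`, `pass`), `mean_slope`,
#'   `mean_intercept`, `mean_r_squared`, `pass`.
#' @examples
#' m <- simulate_gm_measurements(c(0.1, 1, 10, 100), cv = 0.05, seed = 2)
#' linearity(m)
#' @export
linearity <- function(measurements, aggregate = TRUE,
                      r2_min = 0.98, slope_tol = 0.25) {
  assert_columns(measurements, c("nominal_level", "gm_percent"),
                 "`measurements`")
  df <- measurements
  if (!"run_id" %in% names(df)) df$run_id <- "run1"
  per_run <- lapply(split(df, df$run_id), function(sub) {
    if (length(unique(sub$nominal_level)) < 3L) {
      stop_dpcr("invalid_argument",
                "run '%s' has fewer than 3 distinct nominal levels",
                sub$run_id[1])
    }
    if (aggregate) {
      sub <- aggregate(gm_percent ~ nominal_level + run_id, sub, mean)
    }
    fit <- stats::lm(gm_percent ~ nominal_level, data = sub)
    co <- stats::coef(fit)
    # suppressed: summary.lm warns on noiseless (perfect-fit) inputs
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(run_id = sub$run_id[1], slope = unname(co[2]),
               intercept = unname(co[1]), r_squared = r2,
               pass = r2 >= r2_min && abs(co[2] - 1) <= slope_tol,
               stringsAsFactors = FALSE)
  })
  per_run <- do.call(rbind, per_run)
  rownames(per_run) <- NULL
  structure(list(per_run = per_run,
                 mean_slope = mean(per_run$slope),
                 mean_intercept = mean(per_run$intercept),
                 mean_r_squared = mean(per_run$r_squared),
                 pass = all(per_run$pass)),
            class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  print(x$per_run)
  cat(sprintf("mean slope %.4f, intercept %.4f, R^2 %.4f -> %s\n",
              x$mean_slope, x$mean_intercept, x$mean_r_squared,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Asymmetric limit of quantification
#'
#' The asymmetric LOQ is the smallest amount of the GM target, in copies per
#' reaction, quantifiable with acceptable precision when the reference gene
#' is present in large excess. Operationally: among candidate low GM levels
#' measured with at least `min_replicates` replicates, find the lowest level
#' whose GM-% replicates satisfy RSDr <= `rsdr_max`; the LOQ is the mean
#' measured GM copies per reaction at that level.
#'
#' @param candidates A `data.frame` with columns `nominal_level`,
#'   `gm_percent`, `copies_per_reaction` and optionally `run_id`.
#' @param min_replicates Minimum replicates a candidate level must have
#'   (default 30).
#' @param rsdr_max RSDr acceptance threshold in percent (default 25).
#' @return A list with `established` (logical), `loq_copies_per_reaction`,
#'   `level`, `n`, `rsdr_percent`, and a per-candidate `table`.
#' @export
loq_asym <- function(candidates, min_replicates = 30L, rsdr_max = 25) {
  assert_columns(candidates,
                 c("nominal_level", "gm_percent", "copies_per_reaction"),
                 "`candidates`")
  assert_count(min_replicates, "min_replicates", min = 2L)
  levels_ <- sort(unique(candidates$nominal_level))
  tab <- lapply(levels_, function(L) {
    sub <- candidates[candidates$nominal_level == L, , drop = FALSE]
    n <- nrow(sub)
    enough <- n >= min_replicates
    rsdr <- if (n >= 2L) {
      precision(sub$gm_percent,
                run = if ("run_id" %in% names(sub)) sub$run_id else NULL,
                threshold = rsdr_max)$rsdr_percent
    } else NA_real_
    data.frame(level = L, n = n,
               mean_copies_per_reaction = mean(sub$copies_per_reaction),
               rsdr_percent = rsdr,
               enough_replicates = enough,
               pass = enough && !is.na(rsdr) && rsdr <= rsdr_max)
  })
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  hit <- which(tab$pass)
  if (!length(hit)) {
    return(list(established = FALSE, loq_copies_per_reaction = NA_real_,
                level = NA_real_, n = NA_integer_, rsdr_percent = NA_real_,
                table = tab))
  }
  i <- hit[1]
  list(established = TRUE,
       loq_copies_per_reaction = tab$mean_copies_per_reaction[i],
       level = tab$level[i], n = tab$n[i], rsdr_percent = tab$rsdr_percent[i],
       table = tab)
}

#' Full-factorial robustness design
#'
#' Builds the 2^k condition table of a multifactorial ruggedness experiment:
#' every combination of `k` two-level factors (e.g. mastermix volume -10%,
#' annealing temperature +1 degC, slower ramp rate, oligonucleotide
#' concentration -10%), in deterministic standard order (first factor varies
#' fastest). Zero factors yield the single baseline condition.
#'
#' @param factors Either a character vector of factor names (levels default
#'   to `"baseline"`/`"changed"`) or a named list of length-2 level vectors.
#'   At most 6 factors.
#' @return An object of class `robustness_design`: a `data.frame` with one
#'   row per condition, a `condition` id column plus one column per factor.
#' @examples
#' robustness_design(c("mastermix_-10pct", "annealing_+1C",
#'                     "ramp_+0.5C_s", "oligo_-10pct"))
#' @export
robustness_design <- function(factors = character()) {
  if (is.character(factors)) {
    factors <- stats::setNames(
      rep(list(c("baseline", "changed")), length(factors)), factors)
  }
  if (!is.list(factors)) {
    stop_dpcr("invalid_argument",
              "`factors` must be a character vector or named list of 2-level factors")
  }
  k <- length(factors)
  if (k > 6L) {
    stop_dpcr("invalid_argument", "at most 6 two-level factors are supported")
  }
  if (k > 0L && (is.null(names(factors)) || any(names(factors) == ""))) {
    stop_dpcr("invalid_argument", "all factors must be named")
  }
  if (any(vapply(factors, length, integer(1)) != 2L)) {
    stop_dpcr("invalid_argument", "every factor needs exactly two levels")
  }
  if (k == 0L) {
    design <- data.frame(condition = 1L)
  } else {
    design <- expand.grid(factors, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    design <- cbind(condition = seq_len(nrow(design)), design)
  }
  structure(design, class = c("robustness_design", "data.frame"))
}

#' Evaluate a robustness experiment
#'
#' Per-condition mean, RSDr and bias against the nominal level, with the
#' overall verdict: the method is robust if every condition keeps both RSDr
#' and |bias| strictly below `threshold` (default 30%). Conditions with
#' fewer than two replicates are flagged incomplete and fail the overall
#' verdict rather than being silently passed.
#'
#' @param measurements A `data.frame` with columns `condition` and
#'   `gm_percent`.
#' @param nominal_level The nominal GM level of the test material, % (m/m).
#' @param threshold Acceptance threshold in percent (default 30).
#' @return A list with `table` (per-condition `n`, `mean`, `rsdr_percent`,
#'   `bias_percent`, `complete`, `pass`), `pass`, `complete`.
#' @export
robustness_evaluate <- function(measurements, nominal_level, threshold = 30) {
  assert_columns(measurements, c("condition", "gm_percent"), "`measurements`")
  assert_scalar_number(nominal_level, "nominal_level", min = 0,
                       strict_min = TRUE)
  tab <- lapply(split(measurements, measurements$condition), function(sub) {
    n <- nrow(sub)
    complete <- n >= 2L
    if (complete) {
      tr <- trueness(sub$gm_percent, nominal_level, threshold = threshold)
      pr <- precision(sub$gm_percent, threshold = threshold)
      data.frame(condition = sub$condition[1], n = n, mean = tr$mean,
                 rsdr_percent = pr$rsdr_percent,
                 bias_percent = tr$bias_percent, complete = TRUE,
                 pass = abs(tr$bias_percent) < threshold &&
                   pr$rsdr_percent < threshold)
    } else {
      data.frame(condition = sub$condition[1], n = n,
                 mean = mean(sub$gm_percent), rsdr_percent = NA_real_,
                 bias_percent = NA_real_, complete = FALSE, pass = FALSE)
    }
  })
  tab <- do.call(rbind, tab)
  rownames(tab) <- NULL
  list(table = tab, pass = all(tab$pass), complete = all(tab$complete))
}

#' Expanded measurement uncertainty (k = 2)
#'
#' Combines the repeatability and trueness components of a validation level
#' into an expanded measurement uncertainty, following the relative
#' combination pattern of GMO-analysis uncertainty guidance: the relative
#' repeatability component of the mean is `(RSDr/100)/sqrt(n)`; the relative
#' bias component combines the observed relative bias with the reference
#' material's relative standard uncertainty in quadrature; the combined
#' relative uncertainty is their quadrature sum, expanded with coverage
#' factor k = 2 and scaled by the mean to the GM-% scale.
#'
#' @param mean_measured Mean measured GM % of the level (> 0).
#' @param rsdr_percent Repeatability RSD in percent.
#' @param n Number of replicates behind the mean (>= 2).
#' @param bias_percent Signed relative bias in percent.
#' @param u_ref_relative Relative standard uncertainty of the reference
#'   value (default 0).
#' @return A list with `u_rep_relative`, `u_bias_relative`, `u_c_relative`,
#'   and `expanded_u` (k = 2, on the GM-% scale).
#' @examples
#' measurement_uncertainty(1, rsdr_percent = 10, n = 25, bias_percent = 0)
#' @export
measurement_uncertainty <- function(mean_measured, rsdr_percent, n,
                                    bias_percent = 0, u_ref_relative = 0) {
  assert_scalar_number(mean_measured, "mean_measured", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(rsdr_percent, "rsdr_percent", min = 0)
  assert_count(n, "n", min = 2L)
  assert_scalar_number(bias_percent, "bias_percent")
  assert_scalar_number(u_ref_relative, "u_ref_relative", min = 0)
  u_rep <- (rsdr_percent / 100) / sqrt(n)
  u_bias <- sqrt((bias_percent / 100)^2 + u_ref_relative^2)
  u_c <- sqrt(u_rep^2 + u_bias^2)
  list(u_rep_relative = u_rep, u_bias_relative = u_bias,
       u_c_relative = u_c, expanded_u = 2 * u_c * mean_measured)
}
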