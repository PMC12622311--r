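#' Estimate mean copies per partition from partition counts
#'
#' The Poisson occupancy estimator used throughout digital PCR: with
#' `n_positive` of `n_total` partitions positive, the mean target copies per
#' partition is `lambda = -log((n_total - n_positive) / n_total)`. The
#' delta-method variance of the estimator is `(exp(lambda) - 1) / n_total`.
#'
#' Saturated wells (every partition positive) carry no quantitative
#' information and raise a `saturation_error` rather than returning a clipped
#' estimate.
#'
#' @param n_positive Positive partitions (0 <= n_positive < n_total).
#' @param n_total Total accepted partitions (> 0).
#' @return A list with `lambda`, `var_lambda`, `n_total`, `n_positive`.
#' @examples
#' estimate_lambda(5000, 10000)  # lambda = log 2
#' @export
estimate_lambda <- function(n_positive, n_total) {
  n_total <- assert_count(n_total, "n_total", min = 1L)
  n_positive <- assert_count(n_positive, "n_positive", min = 0L)
  if (n_positive >= n_total) {
    stop_dpcr("saturation_error",
              "all %d partitions positive: concentration above the quantifiable range",
              n_total)
  }
  lambda <- -log((n_total - n_positive) / n_total)
  list(lambda = lambda,
       var_lambda = (exp(lambda) - 1) / n_total,
       n_total = n_total, n_positive = n_positive)
}

#' Convert a lambda estimate into concentrations with a 95% CI
#'
#' Copies per microlitre of reaction are `lambda / partition volume (ul)`;
#' copies per reaction scale by the reaction volume. The 95% confidence
#' interval is the normal-approximation interval on lambda
#' (`lambda +/- 1.96 sd`), transformed to the concentration scale and floored
#' at zero.
#'
#' @param est A lambda estimate from [estimate_lambda()], or a single
#'   non-negative number (taken as lambda with zero variance).
#' @param platform A [platform_profile()] supplying partition and reaction
#'   volumes.
#' @return An object of class `quant_result`: a list with `lambda`,
#'   `copies_per_ul`, `copies_per_reaction`, `ci_low`, `ci_high` (copies/ul),
#'   `n_total`, `n_positive`.
#' @examples
#' concentration(estimate_lambda(5000, 10000), platform_profile("qx200"))
#' @export
concentration <- function(est, platform) {
  if (!inherits(platform, "platform_profile")) {
    stop_dpcr("invalid_argument", "`platform` must be a platform_profile")
  }
  if (is.numeric(est) && length(est) == 1L) {
    assert_scalar_number(est, "est", min = 0)
    est <- list(lambda = est, var_lambda = 0,
                n_total = NA_integer_, n_positive = NA_integer_)
  }
  pv_ul <- platform$partition_volume_nl / 1000
  sd_lambda <- sqrt(est$var_lambda)
  lam_lo <- max(0, est$lambda - 1.96 * sd_lambda)
  lam_hi <- est$lambda + 1.96 * sd_lambda
  copies_per_ul <- est$lambda / pv_ul
  structure(list(
    lambda = est$lambda,
    copies_per_ul = copies_per_ul,
    copies_per_reaction = copies_per_ul * platform$reaction_volume_ul,
    ci_low = lam_lo / pv_ul,
    ci_high = lam_hi / pv_ul,
    n_total = est$n_total, n_positive = est$n_positive
  ), class = "quant_result")
}

#' Classify partition amplitudes into negative, rain, and positive
#'
#' Partitions at or above the positive fence are positive; partitions
#' strictly between the negative fence (`neg centre + f * neg spread`) and the
#' positive fence (`pos centre - f * pos spread`) are rain. Rain partitions
#' count as negative for quantification.
#'
#' Fences can be supplied three ways: an [amplitude_model()] (fences at the
#' model's `f`-sigma points), a numeric vector `c(neg_fence, pos_fence)`, a
#' single numeric positive threshold (no rain band), or `NULL` (default), in
#' which case the two populations are found by 2-means clustering initialised
#' at the amplitude extremes and the fences placed `f` robust spreads
#' (median absolute deviation) beyond each population median. This two-fence
#' rule is a deliberately simple approximation of percentile-fence rain
#' classifiers used with droplet readers.
#'
#' @param amplitudes Non-empty numeric vector of per-partition fluorescence.
#' @param model_or_threshold Fence specification as described above.
#' @param f Number of spreads beyond each population centre (default 3).
#' @return A list with `n_total`, `n_positive`, `n_rain`, and the fences used.
#' @examples
#' amp <- simulate_amplitudes(10000, 400, amplitude_model(), 0.02, seed = 1)
#' classify_partitions(amp)
#' @export
classify_partitions <- function(amplitudes, model_or_threshold = NULL, f = 3) {
  if (!is.numeric(amplitudes) || !length(amplitudes) ||
      anyNA(amplitudes)) {
    stop_dpcr("invalid_argument",
              "`amplitudes` must be a non-empty numeric vector without NA")
  }
  assert_scalar_number(f, "f", min = 0, strict_min = TRUE)
  spec <- model_or_threshold
  if (inherits(spec, "amplitude_model")) {
    fences <- c(spec$neg_mean + f * spec$neg_sd, spec$pos_mean - f * spec$pos_sd)
  } else if (is.numeric(spec) && length(spec) == 2L) {
    fences <- sort(spec)
  } else if (is.numeric(spec) && length(spec) == 1L) {
    fences <- c(spec, spec)
  } else if (is.null(spec)) {
    if (diff(range(amplitudes)) == 0) {
      stop_dpcr("single_population_error",
                "all amplitudes identical: cannot place a threshold")
    }
    km <- suppressWarnings(
      stats::kmeans(amplitudes, centers = matrix(range(amplitudes), ncol = 1)))
    lowclust <- which.min(km$centers)
    neg <- amplitudes[km$cluster == lowclust]
    pos <- amplitudes[km$cluster != lowclust]
    if (!length(pos) || !length(neg)) {
      stop_dpcr("single_population_error",
                "amplitudes form a single population: cannot place a threshold")
    }
    spread <- function(x) max(stats::mad(x), 1e-8 * abs(stats::median(x)), 1e-12)
    fences <- c(stats::median(neg) + f * spread(neg),
                stats::median(pos) - f * spread(pos))
    if (fences[1] >= fences[2]) {
      stop_dpcr("single_population_error",
                "populations are not separable: fences overlap")
    }
  } else {
    stop_dpcr("invalid_argument",
              "`model_or_threshold` must be an amplitude_model, 1 or 2 numbers, or NULL")
  }
  n_total <- length(amplitudes)
  n_positive <- sum(amplitudes >= fences[2])
  n_rain <- sum(amplitudes > fences[1] & amplitudes < fences[2])
  list(n_total = n_total, n_positive = as.integer(n_positive),
       n_rain = as.integer(n_rain),
       neg_fence = fences[1], pos_fence = fences[2])
}

#' Rain fraction of a well with its acceptance flag
#'
#' The fraction of partitions with intermediate fluorescence ("rain") is a
#' quality metric: it must stay below 2.5% of the total partitions.
#'
#' @param n_rain Rain partitions (or a list with `n_rain`/`n_total`, e.g.
#'   the result of [classify_partitions()]).
#' @param n_total Total partitions (> 0); ignored when `n_rain` is a list.
#' @param threshold Acceptance threshold on the fraction (default 0.025).
#' @return A list with `fraction` and `pass` (`fraction < threshold`).
#' @examples
#' rain_fraction(300, 20000)  # 1.5%, pass
#' rain_fraction(600, 20000)  # 3.0%, fail
#' @export
rain_fraction <- function(n_rain, n_total = NULL, threshold = 0.025) {
  if (is.list(n_rain)) {
    n_total <- n_rain$n_total
    n_rain <- n_rain$n_rain
  }
  n_total <- assert_count(n_total, "n_total", min = 1L)
  n_rain <- assert_count(n_rain, "n_rain", min = 0L)
  if (n_rain > n_total) {
    stop_dpcr("invalid_argument", "n_rain exceeds n_total")
  }
  frac <- n_rain / n_total
  list(fraction = frac, pass = frac < threshold)
}

#' Well-level quality control verdicts
#'
#' Applies the well acceptance rules to every well in a long per-channel
#' table: a sample or positive-control well passes if every channel has at
#' least the platform's minimum accepted partitions and the reference (lec)
#' channel shows more positives than the NTC limit; an NTC well passes if no
#' channel exceeds the NTC limit. Failing wells are flagged with reason
#' codes, never dropped.
#'
#' @param wells A `data.frame` in the partition-count layout (columns
#'   `run_id`, `well_id`, `role`, `target`, `n_total`, `n_positive`; see
#'   [read_partition_csv()]).
#' @param platform A [platform_profile()].
#' @return A `data.frame` with one row per well: `run_id`, `well_id`, `role`,
#'   `pass`, `reasons` (`;`-separated codes, `""` when passing). Reason codes:
#'   `insufficient_partitions`, `ntc_contamination`, `no_amplification`.
#' @examples
#' d <- simulation_design(levels = 1, replicates_per_level = 2, runs = 1,
#'                        seed = 2)
#' well_qc(simulate_experiment(d), platform_profile("qx200"))
#' @export
well_qc <- function(wells, platform) {
  assert_columns(wells, c("run_id", "well_id", "role", "target",
                          "n_total", "n_positive"), "`wells`")
  if (!inherits(platform, "platform_profile")) {
    stop_dpcr("invalid_argument", "`platform` must be a platform_profile")
  }
  key <- interaction(wells$run_id, wells$well_id, drop = TRUE)
  out <- lapply(split(wells, key), function(w) {
    reasons <- character()
    if (any(w$n_total < platform$min_accepted_partitions)) {
      reasons <- c(reasons, "insufficient_partitions")
    }
    role <- w$role[1]
    if (role == "ntc") {
      if (any(w$n_positive > platform$ntc_max_positive)) {
        reasons <- c(reasons, "ntc_contamination")
      }
    } else {
      lec <- w[w$target == "lec", , drop = FALSE]
      if (nrow(lec) && all(lec$n_positive <= platform$ntc_max_positive)) {
        reasons <- c(reasons, "no_amplification")
      }
      if (role == "positive_control") {
        gm <- w[w$target == "gm", , drop = FALSE]
        if (nrow(gm) && all(gm$n_positive <= platform$ntc_max_positive)) {
          reasons <- c(reasons, "no_amplification")
        }
      }
    }
    data.frame(run_id = w$run_id[1], well_id = w$well_id[1], role = role,
               pass = !length(reasons),
               reasons = paste(unique(reasons), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-talk check on reference-gene-only wells
#'
#' For wells whose sample contains only the reference gene (no GM event), any
#' signal on the GM channel can only be optical cross-talk or contamination.
#' The check passes if the GM channel of every eligible well satisfies the
#' NTC rule (at most `ntc_max_positive` positives).
#'
#' A GM-channel positive fraction above `max_positive_fraction` is treated as
#' genuine amplification — the input is then not a cross-talk layout and an
#' `invalid_argument` error is raised, instead of silently failing the check.
#'
#' @param wells Long per-channel table of the lec-only wells.
#' @param platform A [platform_profile()].
#' @param gm_target Name of the GM channel in `target` (default `"gm"`).
#' @param max_positive_fraction Positive fraction on the GM channel above
#'   which the well is considered genuinely GM-positive (default 0.005).
#' @return A list with `pass`, and per-well `table` of GM-channel positives.
#' @export
crosstalk_check <- function(wells, platform, gm_target = "gm",
                            max_positive_fraction = 0.005) {
  assert_columns(wells, c("well_id", "role", "target", "n_total",
                          "n_positive"), "`wells`")
  gm <- wells[wells$target == gm_target & wells$role != "ntc", , drop = FALSE]
  if (!nrow(gm)) {
    stop_dpcr("invalid_argument",
              "no eligible wells: need sample wells with a '%s' channel", gm_target)
  }
  if (any(gm$n_positive / gm$n_total > max_positive_fraction)) {
    stop_dpcr("invalid_argument",
              "GM channel signal too strong for a cross-talk layout: input contains GM-positive sample(s)")
  }
  tab <- data.frame(well_id = gm$well_id, n_total = gm$n_total,
                    n_positive = gm$n_positive,
                    pass = gm$n_positive <= platform$ntc_max_positive,
                    stringsAsFactors = FALSE)
  list(pass = all(tab$pass), table = tab)
}

#' Quantify every well x channel of a partition-count table
#'
#' Runs [estimate_lambda()] and [concentration()] on each row of a long
#' per-channel partition-count table and joins the per-well QC verdict.
#' Saturated channels are flagged (`saturated = TRUE`, concentrations `NA`)
#' rather than raising, so one bad well cannot abort a batch.
#'
#' @param wells Long per-channel table (see [read_partition_csv()]).
#' @param platform A [platform_profile()].
#' @return A `data.frame` with the input keys plus `lambda`, `copies_per_ul`,
#'   `copies_per_reaction`, `ci_low`, `ci_high`, `saturated`, `qc_pass`,
#'   `qc_reasons`.
#' @examples
#' d <- simulation_design(levels = c(1, 10), replicates_per_level = 2,
#'                        runs = 1, seed = 4)
#' head(quantify_wells(simulate_experiment(d), platform_profile("qx200")))
#' @export
quantify_wells <- function(wells, platform) {
  assert_columns(wells, c("run_id", "well_id", "role", "target",
                          "n_total", "n_positive"), "`wells`")
  qc <- well_qc(wells, platform)
  n <- nrow(wells)
  lambda <- copies_ul <- copies_rxn <- ci_lo <- ci_hi <- rep(NA_real_, n)
  saturated <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (wells$n_positive[i] >= wells$n_total[i]) {
      saturated[i] <- TRUE
      next
    }
    q <- concentration(estimate_lambda(wells$n_positive[i], wells$n_total[i]),
                       platform)
    lambda[i] <- q$lambda
    copies_ul[i] <- q$copies_per_ul
    copies_rxn[i] <- q$copies_per_reaction
    ci_lo[i] <- q$ci_low
    ci_hi[i] <- q$ci_high
  }
  out <- cbind(wells,
               data.frame(lambda = lambda, copies_per_ul = copies_ul,
                          copies_per_reaction = copies_rxn,
                          ci_low = ci_lo, ci_high = ci_hi,
                          saturated = saturated))
  idx <- match(interaction(out$run_id, out$well_id),
               interaction(qc$run_id, qc$well_id))
  out$qc_pass <- qc$pass[idx]
  out$qc_reasons <- qc$reasons[idx]
  rownames(out) <- NULL
  out
}
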