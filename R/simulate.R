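#' Design of a synthetic validation experiment
#'
#' Describes the layout and noise structure of a simulated in-house validation
#' study: the nominal GM mass-fraction levels, the number of replicates per
#' level and runs, the reference-gene loading, and the nuisance components the
#' generator emulates (rain, NTC contamination, pipetting/mixture noise).
#'
#' Defaults mirror a typical in-house validation design: six replicates per GM
#' level over five runs, seven levels spanning 0.05-100 % m/m, a reference-gene
#' loading of 100,000 lectin copies per reaction (so the lowest level still
#' yields tens of GM copies per reaction), 1 % rain, an expected 0.2
#' contaminating positives per NTC channel, 10 % multiplicative noise on the
#' GM/lectin copy ratio and 5 % on the total DNA input.
#'
#' @param levels Nominal GM levels in % (m/m), each in `[0, 100]`.
#' @param replicates_per_level Replicate wells per level per run.
#' @param runs Number of PCR runs (one per day by default).
#' @param lec_copies_per_reaction Lectin (reference gene) copies loaded per
#'   reaction.
#' @param rain_fraction Fraction of partitions per well placed in the
#'   intermediate rain band, in `[0, 1)`.
#' @param ntc_contamination_rate Expected spurious positive partitions per NTC
#'   channel (Poisson rate).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on the GM/lectin copy ratio (mixture heterogeneity + pipetting).
#' @param dna_cv Coefficient of variation of the common total-DNA loading
#'   factor (affects both channels, cancels in the ratio).
#' @param seed Integer seed recorded with the design; `NULL` leaves the
#'   current RNG stream in charge.
#' @return An object of class `simulation_design`.
#' @examples
#' simulation_design(levels = c(0.05, 0.1, 0.5, 1, 2, 10, 100), seed = 1)
#' @export
simulation_design <- function(levels = c(0.05, 0.1, 0.5, 1, 2, 10, 100),
                              replicates_per_level = 6L,
                              runs = 5L,
                              lec_copies_per_reaction = 1e5,
                              rain_fraction = 0.01,
                              ntc_contamination_rate = 0.2,
                              noise_cv = 0.10,
                              dna_cv = 0.05,
                              seed = NULL) {
  if (!is.numeric(levels) || !length(levels) ||
      any(levels < 0 | levels > 100)) {
    stop_dpcr("invalid_argument", "`levels` must be GM %% values in [0, 100]")
  }
  assert_count(replicates_per_level, "replicates_per_level", min = 1L)
  assert_count(runs, "runs", min = 1L)
  assert_scalar_number(lec_copies_per_reaction, "lec_copies_per_reaction",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(rain_fraction, "rain_fraction", min = 0)
  if (rain_fraction >= 1) {
    stop_dpcr("invalid_argument", "`rain_fraction` must be < 1")
  }
  assert_scalar_number(ntc_contamination_rate, "ntc_contamination_rate", min = 0)
  assert_scalar_number(noise_cv, "noise_cv", min = 0)
  assert_scalar_number(dna_cv, "dna_cv", min = 0)
  if (!is.null(seed)) assert_count(seed, "seed")
  structure(list(levels = as.numeric(levels),
                 replicates_per_level = as.integer(replicates_per_level),
                 runs = as.integer(runs),
                 lec_copies_per_reaction = lec_copies_per_reaction,
                 rain_fraction = rain_fraction,
                 ntc_contamination_rate = ntc_contamination_rate,
                 noise_cv = noise_cv,
                 dna_cv = dna_cv,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_design")
}

#' Simulate partition occupancy for one channel of one well
#'
#' Under Poisson loading with mean `lambda_per_partition` copies per
#' partition, each partition is positive with probability
#' `1 - exp(-lambda)`; the number of positive partitions is therefore
#' binomial.
#'
#' @param lambda_per_partition Mean target copies per partition (>= 0).
#' @param n_partitions Number of analysable partitions (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `n_total` and `n_positive`.
#' @examples
#' simulate_partitions(log(2), 10000, seed = 1)
#' @export
simulate_partitions <- function(lambda_per_partition, n_partitions,
                                seed = NULL) {
  assert_scalar_number(lambda_per_partition, "lambda_per_partition", min = 0)
  assert_count(n_partitions, "n_partitions", min = 1L)
  p <- 1 - exp(-lambda_per_partition)
  n_positive <- with_seed(seed, stats::rbinom(1L, n_partitions, p))
  list(n_total = as.integer(n_partitions), n_positive = as.integer(n_positive))
}

#' Simulate per-partition fluorescence amplitudes
#'
#' Generates the end-point amplitude of every partition in a well:
#' `round(rain_fraction * n_total)` partitions fall uniformly in the rain
#' band, `n_positive` are drawn from the positive Gaussian, and the remainder
#' from the negative Gaussian. Rain partitions are carved out of the negative
#' pool, consistent with the downstream rule that rain counts as negative for
#' quantification.
#'
#' @param n_total Total partitions.
#' @param n_positive Positive partitions (excluding rain).
#' @param model An [amplitude_model()].
#' @param rain_fraction Fraction of partitions in the rain band, `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_total` amplitudes in random order.
#' @examples
#' amp <- simulate_amplitudes(10000, 500, amplitude_model(), 0.03, seed = 1)
#' @export
simulate_amplitudes <- function(n_total, n_positive, model = amplitude_model(),
                                rain_fraction = 0, seed = NULL) {
  n_total <- assert_count(n_total, "n_total", min = 1L)
  n_positive <- assert_count(n_positive, "n_positive", min = 0L)
  if (!inherits(model, "amplitude_model")) {
    stop_dpcr("invalid_argument", "`model` must be an amplitude_model")
  }
  assert_scalar_number(rain_fraction, "rain_fraction", min = 0)
  if (rain_fraction >= 1) {
    stop_dpcr("invalid_argument", "`rain_fraction` must be < 1")
  }
  n_rain <- as.integer(round(rain_fraction * n_total))
  if (n_positive > n_total || n_positive + n_rain > n_total) {
    stop_dpcr("invalid_argument",
              "requested %d positive + %d rain partitions exceed %d total",
              n_positive, n_rain, n_total)
  }
  n_neg <- n_total - n_positive - n_rain
  with_seed(seed, {
    amp <- c(
      stats::rnorm(n_neg, model$neg_mean, model$neg_sd),
      stats::runif(n_rain, model$rain_low, model$rain_high),
      stats::rnorm(n_positive, model$pos_mean, model$pos_sd)
    )
    sample(amp)
  })
}

#' Simulate a full duplex validation experiment
#'
#' Emits one classified duplex well per (level, replicate, run) plus one NTC
#' well per run, in the long per-channel layout used throughout the package
#' (one row per well x target). The lectin channel is loaded at the design's
#' `lec_copies_per_reaction` (scaled by a common lognormal DNA factor); the GM
#' channel at `nominal %% x conversion_factor / 100` of the lectin copies,
#' scaled additionally by the ratio-noise factor. GM and lectin occupancy are
#' independent Poisson loadings (no partition-level competition). Accepted
#' partition counts per well are drawn from a Gaussian around the platform
#' nominal (CV 5 %), floored at the platform's minimum accepted partitions.
#'
#' @param design A [simulation_design()].
#' @param platform A [platform_profile()].
#' @param conversion_factor Event-specific conversion factor relating the
#'   GM/lectin copy ratio to the mass fraction.
#' @return A `data.frame` with columns `run_id`, `day`, `well_id`,
#'   `sample_id`, `role`, `nominal_level`, `target`, `n_total`, `n_positive`,
#'   `n_rain`.
#' @examples
#' d <- simulation_design(levels = c(1, 10), replicates_per_level = 2,
#'                        runs = 2, seed = 7)
#' wells <- simulate_experiment(d, platform_profile("qx200"))
#' head(wells)
#' @export
simulate_experiment <- function(design, platform = platform_profile("qx200"),
                                conversion_factor = 1) {
  if (!inherits(design, "simulation_design")) {
    stop_dpcr("invalid_argument", "`design` must be a simulation_design")
  }
  if (!inherits(platform, "platform_profile")) {
    stop_dpcr("invalid_argument", "`platform` must be a platform_profile")
  }
  assert_scalar_number(conversion_factor, "conversion_factor",
                       min = 0, strict_min = TRUE)
  # copies/reaction -> mean copies per partition
  lambda_of <- function(copies_per_reaction) {
    copies_per_reaction / platform$reaction_volume_ul *
      platform$partition_volume_nl / 1000
  }
  draw_n_total <- function() {
    n <- round(stats::rnorm(1, platform$n_partitions_nominal,
                            0.05 * platform$n_partitions_nominal))
    max(as.integer(n), platform$min_accepted_partitions)
  }
  with_seed(design$seed, {
    rows <- vector("list",
                   design$runs * (length(design$levels) *
                                    design$replicates_per_level + 1L) * 2L)
    k <- 0L
    for (run in seq_len(design$runs)) {
      for (li in seq_along(design$levels)) {
        level <- design$levels[li]
        for (rep in seq_len(design$replicates_per_level)) {
          n_total <- draw_n_total()
          f_dna <- rlnorm_cv(1, design$dna_cv)
          f_ratio <- rlnorm_cv(1, design$noise_cv)
          cp_lec <- design$lec_copies_per_reaction * f_dna
          cp_gm <- cp_lec * level * conversion_factor / 100 * f_ratio
          n_rain <- as.integer(round(design$rain_fraction * n_total))
          well_id <- sprintf("r%02d_L%s_rep%d", run, format(level), rep)
          for (tg in c("gm", "lec")) {
            lam <- lambda_of(if (tg == "gm") cp_gm else cp_lec)
            npos <- stats::rbinom(1L, n_total, 1 - exp(-lam))
            k <- k + 1L
            rows[[k]] <- data.frame(
              run_id = sprintf("run%02d", run), day = sprintf("day%02d", run),
              well_id = well_id,
              sample_id = sprintf("L%s", format(level)),
              role = "sample", nominal_level = level, target = tg,
              n_total = n_total, n_positive = as.integer(npos),
              n_rain = n_rain, stringsAsFactors = FALSE)
          }
        }
      }
      n_total <- draw_n_total()
      for (tg in c("gm", "lec")) {
        npos <- min(stats::rpois(1L, design$ntc_contamination_rate), n_total)
        k <- k + 1L
        rows[[k]] <- data.frame(
          run_id = sprintf("run%02d", run), day = sprintf("day%02d", run),
          well_id = sprintf("r%02d_NTC", run), sample_id = "NTC",
          role = "ntc", nominal_level = NA_real_, target = tg,
          n_total = n_total, n_positive = as.integer(npos), n_rain = 0L,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows[seq_len(k)])
    rownames(out) <- NULL
    class(out) <- c("well_data", "data.frame")
    out
  })
}

#' Simulate an inhibition-test dilution series
#'
#' Emulates the serial-dilution inhibition test used to check DNA extract
#' quality: the stock is measured undiluted and at each further dilution in
#' duplicate (or more). `inhibition_strength` multiplicatively suppresses the
#' recovery of the undiluted level only (1 = no inhibition), mimicking
#' inhibitors that are diluted out.
#'
#' @param stock_copies_per_reaction True copies per reaction in the undiluted
#'   extract.
#' @param dilution_factors Strictly increasing factors, first element 1.
#' @param inhibition_strength Recovery multiplier applied at dilution factor 1.
#' @param seed Optional integer seed.
#' @param n_replicates Measurements per dilution level (>= 2).
#' @param cv Measurement coefficient of variation.
#' @return A `data.frame` with columns `dilution_factor`, `replicate`,
#'   `copies_per_reaction`.
#' @examples
#' simulate_dilution_series(60000, c(1, 4, 16), inhibition_strength = 0.6,
#'                          seed = 3)
#' @export
simulate_dilution_series <- function(stock_copies_per_reaction,
                                     dilution_factors = c(1, 4, 16),
                                     inhibition_strength = 1,
                                     seed = NULL, n_replicates = 2L,
                                     cv = 0.02) {
  assert_scalar_number(stock_copies_per_reaction, "stock_copies_per_reaction",
                       min = 0)
  if (!length(dilution_factors)) {
    stop_dpcr("invalid_argument", "`dilution_factors` must not be empty")
  }
  if (dilution_factors[1] != 1 ||
      any(diff(dilution_factors) <= 0)) {
    stop_dpcr("invalid_argument",
              "`dilution_factors` must be strictly increasing and start at 1")
  }
  assert_scalar_number(inhibition_strength, "inhibition_strength", min = 0)
  assert_count(n_replicates, "n_replicates", min = 2L)
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        dilution_factor = dilution_factors)
    recovery <- ifelse(grid$dilution_factor == 1, inhibition_strength, 1)
    measured <- stock_copies_per_reaction / grid$dilution_factor * recovery *
      rlnorm_cv(nrow(grid), cv)
    data.frame(dilution_factor = grid$dilution_factor,
               replicate = grid$replicate,
               copies_per_reaction = measured)
  })
}

#' Simulate GM-content measurements at the result level
#'
#' A measurement-level generator for exercising the validation battery
#' directly: each replicate's measured GM % is the true level times a
#' unit-mean lognormal factor with coefficient of variation `cv`. Use this
#' when the quantity under test is the validation statistics themselves
#' (bias, RSDr, linearity, LOQ) rather than the partition-level machinery.
#'
#' @param levels Nominal GM levels in % (m/m).
#' @param cv Multiplicative noise CV of a single measurement.
#' @param replicates_per_level Replicates per level per run.
#' @param runs Number of runs.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `nominal_level`, `run_id`,
#'   `replicate`, `gm_percent`.
#' @examples
#' m <- simulate_gm_measurements(c(0.1, 1, 10), cv = 0.1, seed = 1)
#' aggregate(gm_percent ~ nominal_level, m, mean)
#' @export
simulate_gm_measurements <- function(levels, cv = 0.10,
                                     replicates_per_level = 6L, runs = 5L,
                                     seed = NULL) {
  if (!is.numeric(levels) || !length(levels) || any(levels < 0)) {
    stop_dpcr("invalid_argument", "`levels` must be non-negative GM %% values")
  }
  assert_scalar_number(cv, "cv", min = 0)
  assert_count(replicates_per_level, "replicates_per_level", min = 1L)
  assert_count(runs, "runs", min = 1L)
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates_per_level),
                        run = seq_len(runs), nominal_level = levels)
    data.frame(nominal_level = grid$nominal_level,
               run_id = sprintf("run%02d", grid$run),
               replicate = grid$replicate,
               gm_percent = grid$nominal_level * rlnorm_cv(nrow(grid), cv))
  })
}
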