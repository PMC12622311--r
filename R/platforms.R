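#' Digital PCR platform profile
#'
#' A platform profile bundles the physical and quality-control constants of a
#' dPCR system regime: partition volume, reaction volume, nominal partition
#' count, the minimum number of accepted partitions for a well to be usable,
#' and the maximum number of positive partitions tolerated in a no-template
#' control (NTC).
#'
#' Two presets are provided. `"qx200"` emulates a droplet system
#' (~20,000 droplets of 0.85 nl in a 20 ul reaction, wells accepted above
#' 10,000 droplets, NTC at most 2 positives). `"qiacuity26k"` emulates a
#' 26,000-partition nanoplate (0.91 nl partitions, 40 ul reaction, same
#' acceptance rules). Partition volumes are vendor-nominal figures and are
#' configuration, not constants: override any field.
#'
#' @param name Either a preset name (`"qx200"`, `"qiacuity26k"`) or a label
#'   for a fully custom profile.
#' @param n_partitions_nominal Nominal partitions generated per well.
#' @param partition_volume_nl Partition volume in nanolitres.
#' @param reaction_volume_ul Reaction volume in microlitres.
#' @param min_accepted_partitions Minimum accepted partitions for well QC.
#' @param ntc_max_positive Maximum positive partitions allowed in an NTC well
#'   (and per channel in a cross-talk check).
#'
#' @return An object of class `platform_profile` (a named list).
#' @examples
#' platform_profile("qx200")
#' platform_profile("qiacuity26k", ntc_max_positive = 1)
#' @export
platform_profile <- function(name = "qx200",
                             n_partitions_nominal = NULL,
                             partition_volume_nl = NULL,
                             reaction_volume_ul = NULL,
                             min_accepted_partitions = NULL,
                             ntc_max_positive = NULL) {
  presets <- list(
    qx200 = list(n_partitions_nominal = 20000L, partition_volume_nl = 0.85,
                 reaction_volume_ul = 20, min_accepted_partitions = 10000L,
                 ntc_max_positive = 2L),
    qiacuity26k = list(n_partitions_nominal = 26000L, partition_volume_nl = 0.91,
                       reaction_volume_ul = 40, min_accepted_partitions = 10000L,
                       ntc_max_positive = 2L)
  )
  base <- presets[[name]]
  if (is.null(base)) {
    base <- list(n_partitions_nominal = NULL, partition_volume_nl = NULL,
                 reaction_volume_ul = NULL, min_accepted_partitions = NULL,
                 ntc_max_positive = NULL)
  }
  take <- function(override, preset, field) {
    val <- if (!is.null(override)) override else preset
    if (is.null(val)) {
      stop_dpcr("invalid_argument",
                "custom platform '%s' requires `%s`", name, field)
    }
    val
  }
  p <- list(
    name = name,
    n_partitions_nominal =
      assert_count(take(n_partitions_nominal, base$n_partitions_nominal,
                        "n_partitions_nominal"), "n_partitions_nominal", min = 1L),
    partition_volume_nl =
      assert_scalar_number(take(partition_volume_nl, base$partition_volume_nl,
                                "partition_volume_nl"), "partition_volume_nl",
                           min = 0, strict_min = TRUE),
    reaction_volume_ul =
      assert_scalar_number(take(reaction_volume_ul, base$reaction_volume_ul,
                                "reaction_volume_ul"), "reaction_volume_ul",
                           min = 0, strict_min = TRUE),
    min_accepted_partitions =
      assert_count(take(min_accepted_partitions, base$min_accepted_partitions,
                        "min_accepted_partitions"), "min_accepted_partitions",
                   min = 1L),
    ntc_max_positive =
      assert_count(take(ntc_max_positive, base$ntc_max_positive,
                        "ntc_max_positive"), "ntc_max_positive", min = 0L)
  )
  if (p$min_accepted_partitions > p$n_partitions_nominal) {
    stop_dpcr("invalid_argument",
              "min_accepted_partitions exceeds n_partitions_nominal")
  }
  # the partitioned volume cannot exceed the loaded reaction volume
  if (p$n_partitions_nominal * p$partition_volume_nl >
      p$reaction_volume_ul * 1000) {
    stop_dpcr("invalid_argument",
              "partitioned volume (%g nl) exceeds reaction volume (%g nl)",
              p$n_partitions_nominal * p$partition_volume_nl,
              p$reaction_volume_ul * 1000)
  }
  structure(p, class = "platform_profile")
}

#' @export
print.platform_profile <- function(x, ...) {
  cat(sprintf(
    "<platform_profile '%s'>\n  %d partitions x %.2f nl in %.0f ul reaction\n  QC: >= %d accepted partitions, NTC <= %d positives\n",
    x$name, x$n_partitions_nominal, x$partition_volume_nl,
    x$reaction_volume_ul, x$min_accepted_partitions, x$ntc_max_positive))
  invisible(x)
}

#' Three-population fluorescence amplitude model
#'
#' Parameterises the end-point fluorescence distribution of a dPCR channel as
#' a negative Gaussian population, a positive Gaussian population, and an
#' intermediate uniform band of "rain" — partitions whose fluorescence does
#' not clearly belong to either population. The populations must be separable
#' by construction: the rain band has to sit strictly between the 3-sigma
#' fences of the two Gaussians.
#'
#' @param neg_mean,neg_sd Centre and spread of the negative population.
#' @param pos_mean,pos_sd Centre and spread of the positive population.
#' @param rain_low,rain_high Bounds of the intermediate rain band.
#'   All values are in arbitrary fluorescence units.
#' @return An object of class `amplitude_model`.
#' @examples
#' amplitude_model()
#' @export
amplitude_model <- function(neg_mean = 1000, neg_sd = 100,
                            pos_mean = 8000, pos_sd = 300,
                            rain_low = 2500, rain_high = 6000) {
  for (nm in c("neg_sd", "pos_sd")) {
    assert_scalar_number(get(nm), nm, min = 0, strict_min = TRUE)
  }
  if (!(neg_mean + 3 * neg_sd < rain_low && rain_low <= rain_high &&
        rain_high < pos_mean - 3 * pos_sd)) {
    stop_dpcr("invalid_argument",
              "amplitude populations are not separable: need neg_mean + 3*neg_sd < rain_low <= rain_high < pos_mean - 3*pos_sd")
  }
  structure(list(neg_mean = neg_mean, neg_sd = neg_sd,
                 pos_mean = pos_mean, pos_sd = pos_sd,
                 rain_low = rain_low, rain_high = rain_high),
            class = "amplitude_model")
}
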