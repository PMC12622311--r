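#' GM mass fraction from paired copy numbers
#'
#' The GM content in % (m/m) of a sample is the ratio of event-specific
#' copies to taxon-specific reference-gene (lectin) copies, divided by the
#' event's conversion factor and expressed as a percentage:
#' `GM% = (cp_gm / cp_lec) * (1 / CF) * 100`. The conversion factor relates
#' the copy ratio of a certified reference material to its certified mass
#' fraction and is published per event/CRM.
#'
#' Values above 100% are returned as computed (measurement noise can exceed
#' the certified value); they are not truncated.
#'
#' @param cp_gm GM event copies per reaction (>= 0).
#' @param cp_lec Reference-gene copies per reaction (> 0).
#' @param conversion_factor Event-specific conversion factor (> 0).
#' @return GM content in % (m/m).
#' @examples
#' gm_content(500, 100000, conversion_factor = 0.5)  # 1%
#' @export
gm_content <- function(cp_gm, cp_lec, conversion_factor = 1) {
  if (!is.numeric(cp_gm) || !is.numeric(cp_lec) ||
      anyNA(cp_gm) || anyNA(cp_lec)) {
    stop_dpcr("invalid_argument", "copy numbers must be numeric and non-missing")
  }
  if (any(cp_gm < 0)) {
    stop_dpcr("invalid_argument", "`cp_gm` must be >= 0")
  }
  if (any(cp_lec == 0)) {
    stop_dpcr("undefined_ratio", "`cp_lec` is zero: GM ratio undefined")
  }
  if (any(cp_lec < 0)) {
    stop_dpcr("invalid_argument", "`cp_lec` must be > 0")
  }
  assert_scalar_number(conversion_factor, "conversion_factor",
                       min = 0, strict_min = TRUE)
  (cp_gm / cp_lec) / conversion_factor * 100
}

#' Serial-dilution inhibition test
#'
#' Checks a DNA extract for PCR inhibition: the mean measured copies per
#' reaction at each diluted level, multiplied by its dilution factor, must not
#' differ by more than `tolerance` (default 25%) from the mean measured at
#' the highest concentration (lowest dilution factor). The comparison is
#' two-sided.
#'
#' @param series A `data.frame` with columns `dilution_factor` and
#'   `copies_per_reaction` (at least two levels, at least two measurements
#'   per level), e.g. from [simulate_dilution_series()].
#' @param tolerance Maximum allowed relative difference (default 0.25).
#' @return A list with `pass`, `reference` (mean at the highest
#'   concentration), and a per-level `table` (`dilution_factor`, `n`,
#'   `mean_measured`, `back_calculated`, `rel_diff`, `pass`).
#' @examples
#' s <- simulate_dilution_series(50000, c(1, 4, 16), seed = 1)
#' inhibition_test(s)
#' @export
inhibition_test <- function(series, tolerance = 0.25) {
  assert_columns(series, c("dilution_factor", "copies_per_reaction"),
                 "`series`")
  counts <- table(series$dilution_factor)
  if (length(counts) < 2L) {
    stop_dpcr("invalid_argument", "need at least two dilution levels")
  }
  if (any(counts < 2L)) {
    stop_dpcr("invalid_argument",
              "each dilution level needs duplicate measurements")
  }
  assert_scalar_number(tolerance, "tolerance", min = 0, strict_min = TRUE)
  agg <- aggregate(copies_per_reaction ~ dilution_factor, series, mean)
  agg <- agg[order(agg$dilution_factor), ]
  reference <- agg$copies_per_reaction[1]
  if (reference <= 0) {
    stop_dpcr("invalid_argument",
              "reference level has non-positive mean copies")
  }
  back <- agg$copies_per_reaction * agg$dilution_factor
  rel <- abs(back - reference) / reference
  tab <- data.frame(dilution_factor = agg$dilution_factor,
                    n = as.integer(counts[as.character(agg$dilution_factor)]),
                    mean_measured = agg$copies_per_reaction,
                    back_calculated = back,
                    rel_diff = rel,
                    pass = rel <= tolerance)
  tab$rel_diff[1] <- 0
  tab$pass[1] <- TRUE
  list(pass = all(tab$pass), reference = reference, table = tab)
}

#' Plan a gravimetric GM mixture by reference-gene copy balance
#'
#' Computes the mass fraction `w` of a GM stock (GM level `stock_level` %
#' m/m) to blend with non-GM material so the blend's copy-based GM level
#' equals `target_level`, weighting each component by its reference-gene
#' copies per unit mass. With equal copy yields this reduces to
#' `w = target_level / stock_level`; unequal yields shift `w` according to
#' the copy-weighted balance
#' `target = stock * w * a_gm / (w * a_gm + (1 - w) * a_wt)`.
#'
#' @param target_level Desired GM level of the blend, % (m/m), > 0.
#' @param stock_level GM level of the GM stock, % (m/m), >= target.
#' @param lec_copies_per_mass_gm Reference-gene copies per unit mass of the
#'   GM stock.
#' @param lec_copies_per_mass_wt Same for the non-GM material.
#' @return An object of class `mixture_plan`: `target_level`, `stock_level`,
#'   `w_stock`, `w_non_gm`, and the copy yields used.
#' @examples
#' mixture_plan(2, 10)              # w_stock = 0.2
#' mixture_plan(2, 10, 1e6, 5e5)    # non-GM yields half the copies
#' @export
mixture_plan <- function(target_level, stock_level,
                         lec_copies_per_mass_gm = 1,
                         lec_copies_per_mass_wt = lec_copies_per_mass_gm) {
  assert_scalar_number(target_level, "target_level", min = 0, strict_min = TRUE)
  assert_scalar_number(stock_level, "stock_level", min = 0, strict_min = TRUE,
                       max = 100)
  if (target_level > stock_level) {
    stop_dpcr("invalid_argument",
              "target_level (%g) exceeds stock_level (%g)",
              target_level, stock_level)
  }
  assert_scalar_number(lec_copies_per_mass_gm, "lec_copies_per_mass_gm",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(lec_copies_per_mass_wt, "lec_copies_per_mass_wt",
                       min = 0, strict_min = TRUE)
  a_g <- lec_copies_per_mass_gm
  a_w <- lec_copies_per_mass_wt
  # solve target = stock * w * a_g / (w * a_g + (1 - w) * a_w) for w
  w <- target_level * a_w /
    (a_g * (stock_level - target_level) + target_level * a_w)
  structure(list(target_level = target_level, stock_level = stock_level,
                 w_stock = w, w_non_gm = 1 - w,
                 lec_copies_per_mass_gm = a_g,
                 lec_copies_per_mass_wt = a_w),
            class = "mixture_plan")
}

#' @export
print.mixture_plan <- function(x, ...) {
  cat(sprintf(
    "<mixture_plan> %g%% from %g%% stock: %.4f stock + %.4f non-GM (by mass)\n",
    x$target_level, x$stock_level, x$w_stock, x$w_non_gm))
  invisible(x)
}

#' GM measurement from one quantified duplex well
#'
#' Joins the two channels of a quantified duplex well into a single GM
#' measurement: copies per reaction from each channel plus the resulting GM
#' % (m/m) via [gm_content()]. Refuses NTC wells and wells that failed QC
#' unless `qc_override = TRUE`.
#'
#' @param well Rows of a quantified table ([quantify_wells()]) belonging to
#'   one well: one `gm` and one `lec` row.
#' @param conversion_factor Event-specific conversion factor.
#' @param qc_override Set `TRUE` to quantify a QC-failed well anyway.
#' @return A one-row `data.frame`: `sample_id`, `run_id`, `well_id`,
#'   `nominal_level` (if present), `cp_gm`, `cp_lec`, `conversion_factor`,
#'   `gm_percent`.
#' @export
paired_measurement <- function(well, conversion_factor = 1,
                               qc_override = FALSE) {
  assert_columns(well, c("run_id", "well_id", "role", "target",
                         "copies_per_reaction", "qc_pass"), "`well`")
  if (length(unique(well$well_id)) != 1L) {
    stop_dpcr("invalid_argument", "`well` must contain a single well")
  }
  if (well$role[1] == "ntc") {
    stop_dpcr("invalid_argument", "well '%s' is an NTC, not a sample",
              well$well_id[1])
  }
  if (!all(well$qc_pass) && !qc_override) {
    stop_dpcr("qc_refusal",
              "well '%s' failed QC (%s); pass qc_override = TRUE to force",
              well$well_id[1],
              paste(unique(well$qc_reasons[well$qc_reasons != ""]),
                    collapse = ";"))
  }
  gm <- well[well$target == "gm", , drop = FALSE]
  lec <- well[well$target == "lec", , drop = FALSE]
  if (nrow(gm) != 1L || nrow(lec) != 1L) {
    stop_dpcr("invalid_argument",
              "well '%s' must have exactly one gm and one lec channel",
              well$well_id[1])
  }
  if (is.na(lec$copies_per_reaction) || lec$copies_per_reaction <= 0) {
    stop_dpcr("undefined_ratio",
              "well '%s': lec channel has no quantifiable signal",
              well$well_id[1])
  }
  cp_gm <- if (is.na(gm$copies_per_reaction)) NA_real_ else gm$copies_per_reaction
  data.frame(
    sample_id = if ("sample_id" %in% names(well)) well$sample_id[1] else NA,
    run_id = well$run_id[1], well_id = well$well_id[1],
    nominal_level = if ("nominal_level" %in% names(well))
      well$nominal_level[1] else NA_real_,
    cp_gm = cp_gm, cp_lec = lec$copies_per_reaction,
    conversion_factor = conversion_factor,
    gm_percent = if (is.na(cp_gm)) NA_real_ else
      gm_content(cp_gm, lec$copies_per_reaction, conversion_factor),
    stringsAsFactors = FALSE)
}

#' GM measurements for every sample well of a quantified table
#'
#' Vectorised wrapper around [paired_measurement()]: NTC wells are skipped,
#' QC-failed wells are skipped with a message (they are flagged upstream,
#' exclusion here is explicit and logged), and the remaining duplex wells are
#' converted to GM measurements.
#'
#' @param quantified Output of [quantify_wells()].
#' @param conversion_factor Event-specific conversion factor.
#' @param include_qc_failed Quantify QC-failed wells too (default `FALSE`).
#' @return A `data.frame` of GM measurements, one row per sample well.
#' @examples
#' d <- simulation_design(levels = c(1, 10), replicates_per_level = 2,
#'                        runs = 1, seed = 4)
#' q <- quantify_wells(simulate_experiment(d), platform_profile("qx200"))
#' gm_measurements(q)
#' @export
gm_measurements <- function(quantified, conversion_factor = 1,
                            include_qc_failed = FALSE) {
  if ("qc_reasons" %in% names(quantified)) {
    quantified$qc_reasons[is.na(quantified$qc_reasons)] <- ""
  }
  samples <- quantified[quantified$role != "ntc", , drop = FALSE]
  keys <- unique(samples[c("run_id", "well_id")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    w <- samples[samples$run_id == keys$run_id[i] &
                   samples$well_id == keys$well_id[i], , drop = FALSE]
    if (!all(w$qc_pass) && !include_qc_failed) {
      message(sprintf("excluding QC-failed well '%s' (%s)", keys$well_id[i],
                      paste(unique(w$qc_reasons[w$qc_reasons != ""]),
                            collapse = ";")))
      next
    }
    rows[[i]] <- paired_measurement(w, conversion_factor,
                                    qc_override = include_qc_failed)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
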