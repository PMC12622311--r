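# Shared fixture builders. All synthetic inputs are constructed in code.

# Deterministic vector with exact sample mean `mean` and exact sample
# CV `cv` (sd/mean, denominator n - 1). Used to engineer RSDr values.
vector_with_cv <- function(n, mean, cv, seed = 1) {
  z <- with_fixed_seed(seed, stats::rnorm(n))
  z <- (z - base::mean(z)) / stats::sd(z)      # exact mean 0, sd 1
  mean * (1 + cv * z)
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# One duplex well in the long per-channel layout.
make_well <- function(well_id = "A01", role = "sample",
                      n_total = 20000L, gm_pos = 100L, lec_pos = 15000L,
                      n_rain = 0L, run_id = "run01", nominal_level = NA_real_) {
  data.frame(
    run_id = run_id, day = "day01", well_id = well_id,
    sample_id = if (role == "ntc") "NTC" else "S1",
    role = role, nominal_level = nominal_level,
    target = c("gm", "lec"), n_total = n_total,
    n_positive = c(gm_pos, lec_pos), n_rain = n_rain,
    stringsAsFactors = FALSE)
}

qx <- dpcrval::platform_profile("qx200")
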