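test_that("lambda estimator matches the Poisson closed form", {
  expect_identical(estimate_lambda(0, 10000)$lambda, 0)
  expect_equal(estimate_lambda(5000, 10000)$lambda, log(2), tolerance = 1e-12)
  expect_equal(estimate_lambda(9999, 10000)$lambda, log(10000),
               tolerance = 1e-12)
  # delta-method variance
  e <- estimate_lambda(5000, 10000)
  expect_equal(e$var_lambda, (exp(log(2)) - 1) / 10000, tolerance = 1e-12)

  expect_error(estimate_lambda(10000, 10000), class = "saturation_error")
  expect_error(estimate_lambda(0, 0), class = "invalid_argument")
  expect_error(estimate_lambda(-1, 100), class = "invalid_argument")
})

test_that("lambda estimate is strictly monotone in positive count", {
  lam <- vapply(c(0, 1, 10, 100, 5000, 19000, 19999),
                function(p) estimate_lambda(p, 20000)$lambda, numeric(1))
  expect_true(all(diff(lam) > 0))
})

test_that("concentration converts lambda to copies with a 95% CI", {
  z <- concentration(0, qx)
  expect_identical(z$copies_per_ul, 0)
  expect_identical(z$ci_low, 0)

  # lambda = 0.6931 over 0.85 nl partitions -> 815.4 copies/ul
  q <- concentration(0.6931, qx)
  expect_equal(q$copies_per_ul, 0.6931 / 0.00085, tolerance = 1e-9)
  expect_equal(round(q$copies_per_ul, 1), 815.4)

  # 50 copies/ul in a 40 ul reaction -> 2000 copies/reaction
  qia <- platform_profile("qiacuity26k")
  q2 <- concentration(50 * qia$partition_volume_nl / 1000, qia)
  expect_equal(q2$copies_per_reaction, 2000, tolerance = 1e-9)

  # CI encloses the point estimate and respects the lambda-scale interval
  est <- estimate_lambda(5000, 10000)
  q3 <- concentration(est, qx)
  expect_lt(q3$ci_low, q3$copies_per_ul)
  expect_gt(q3$ci_high, q3$copies_per_ul)
  expect_equal(q3$ci_high - q3$ci_low,
               2 * 1.96 * sqrt(est$var_lambda) / 0.00085, tolerance = 1e-9)
})

test_that("confidence intervals achieve near-nominal coverage", {
  for (lam in c(0.1, 1)) {
    hits <- vapply(1:200, function(i) {
      r <- simulate_partitions(lam, 20000, seed = 5000 + i)
      q <- concentration(estimate_lambda(r$n_positive, r$n_total), qx)
      true_c <- lam / 0.00085
      q$ci_low <= true_c && true_c <= q$ci_high
    }, logical(1))
    expect_gte(mean(hits), 0.90)
    expect_lte(mean(hits), 0.99)
  }
})

test_that("partition classification separates the three populations", {
  # deterministic clusters with explicit fences
  amp <- c(rep(1000, 9700), rep(4000, 300), rep(8000, 5000))
  cl <- classify_partitions(amp, c(2000, 7000))
  expect_identical(cl$n_positive, 5000L)
  expect_identical(cl$n_rain, 300L)

  # none between the fences
  cl2 <- classify_partitions(c(rep(1000, 500), rep(8000, 500)), c(2000, 7000))
  expect_identical(cl2$n_rain, 0L)

  # single threshold above every amplitude -> nothing positive
  cl3 <- classify_partitions(c(rep(1000, 10), rep(8000, 10)), 9000)
  expect_identical(cl3$n_positive, 0L)

  # data-driven fences on well-separated simulated populations
  m <- amplitude_model()
  amp4 <- simulate_amplitudes(20000, 800, m, 0.015, seed = 13)
  cl4 <- classify_partitions(amp4)
  expect_equal(cl4$n_positive, 800L, tolerance = 0.02)
  expect_lt(abs(cl4$n_rain - 300) / 20000, 0.005)

  expect_error(classify_partitions(rep(5, 100)),
               class = "single_population_error")
  expect_error(classify_partitions(numeric(0)), class = "invalid_argument")
})

test_that("rain fraction applies the 2.5% acceptance rule", {
  r <- rain_fraction(300, 20000)
  expect_equal(r$fraction, 0.015)
  expect_true(r$pass)

  expect_true(rain_fraction(0, 20000)$pass)

  r2 <- rain_fraction(600, 20000)
  expect_equal(r2$fraction, 0.030)
  expect_false(r2$pass)

  # exactly at the threshold fails (rule is strictly less than)
  expect_false(rain_fraction(500, 20000)$pass)

  # accepts a classify_partitions result directly
  expect_true(rain_fraction(list(n_rain = 10, n_total = 20000))$pass)
})

test_that("well QC flags wells with reason codes and never drops them", {
  ok <- make_well("A01", gm_pos = 100, lec_pos = 15000)
  low <- make_well("A02", n_total = 9500L, gm_pos = 50, lec_pos = 7000)
  ntc_ok <- make_well("A03", role = "ntc", gm_pos = 2, lec_pos = 0)
  ntc_bad <- make_well("A04", role = "ntc", gm_pos = 3, lec_pos = 0)
  dead <- make_well("A05", gm_pos = 0, lec_pos = 1)
  verdict <- well_qc(rbind(ok, low, ntc_ok, ntc_bad, dead), qx)
  verdict <- verdict[order(verdict$well_id), ]

  expect_identical(nrow(verdict), 5L)  # all wells present
  expect_true(verdict$pass[verdict$well_id == "A01"])
  expect_false(verdict$pass[verdict$well_id == "A02"])
  expect_match(verdict$reasons[verdict$well_id == "A02"],
               "insufficient_partitions")
  expect_true(verdict$pass[verdict$well_id == "A03"])    # NTC at limit passes
  expect_false(verdict$pass[verdict$well_id == "A04"])   # one above fails
  expect_match(verdict$reasons[verdict$well_id == "A04"], "ntc_contamination")
  expect_match(verdict$reasons[verdict$well_id == "A05"], "no_amplification")
})

test_that("cross-talk check applies the NTC rule to the GM channel", {
  clean <- make_well("B01", gm_pos = 0, lec_pos = 15000)
  expect_true(crosstalk_check(clean, qx)$pass)

  leaky <- make_well("B02", gm_pos = 5, lec_pos = 15000)
  expect_false(crosstalk_check(leaky, qx)$pass)

  # genuinely GM-positive sample: not a cross-talk layout
  gm_pos <- make_well("B03", gm_pos = 500, lec_pos = 15000)
  expect_error(crosstalk_check(rbind(clean, gm_pos), qx),
               class = "invalid_argument")
  expect_error(crosstalk_check(clean[clean$target == "lec", ], qx),
               class = "invalid_argument")
})

test_that("count pooling is equivalent to estimating on the union", {
  # splitting a well's partitions in two and merging counts before
  # estimating equals estimating on the pooled counts directly
  h1 <- simulate_partitions(0.7, 9000, seed = 31)
  h2 <- simulate_partitions(0.7, 11000, seed = 32)
  merged <- estimate_lambda(h1$n_positive + h2$n_positive,
                            h1$n_total + h2$n_total)
  direct <- -log(1 - (h1$n_positive + h2$n_positive) / 20000)
  expect_equal(merged$lambda, direct, tolerance = 1e-12)
  expect_equal(concentration(merged, qx)$copies_per_ul, direct / 0.00085,
               tolerance = 1e-12)
})

test_that("quantify_wells flags saturated channels instead of aborting", {
  sat <- make_well("C01", gm_pos = 20000L, lec_pos = 15000)
  q <- quantify_wells(sat, qx)
  expect_true(q$saturated[q$target == "gm"])
  expect_true(is.na(q$copies_per_ul[q$target == "gm"]))
  expect_false(q$saturated[q$target == "lec"])
  expect_false(is.na(q$copies_per_ul[q$target == "lec"]))
})
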