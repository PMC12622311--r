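test_that("trueness reproduces printed validation-report arithmetic", {
  # 100% CRM rows: printed mean vs certified reference
  expect_equal(trueness(98.67, 99.6)$bias_abs_percent, 0.93, tolerance = 0.005)
  expect_equal(trueness(95.34, 99.6)$bias_abs_percent, 4.28, tolerance = 0.005)
  expect_equal(trueness(96.14, 98.5)$bias_abs_percent, 2.40, tolerance = 0.005)

  r <- trueness(c(1, 1, 1), 1)
  expect_equal(r$bias_percent, 0)
  expect_true(r$pass)
  expect_false(trueness(1.3, 1)$pass)  # 30% above

  expect_error(trueness(numeric(0), 1), class = "invalid_argument")
  expect_error(trueness(1, 0), class = "invalid_argument")
})

test_that("precision decomposes within- and between-run variance", {
  expect_equal(precision(c(1, 1, 1))$sr, 0)
  expect_equal(precision(c(1, 1, 1))$rsdr_percent, 0)

  p <- precision(c(0.9, 1.0, 1.1))
  expect_equal(p$mean, 1.0)
  expect_equal(p$sr, 0.1, tolerance = 1e-12)
  expect_equal(p$rsdr_percent, 10, tolerance = 1e-9)

  # identical replicates within runs, all spread between runs
  p2 <- precision(c(1, 1, 2, 2), run = c("a", "a", "b", "b"))
  expect_equal(p2$sr, 0, tolerance = 1e-12)
  expect_gt(p2$s_between, 0)
  expect_gt(p2$s_intermediate, p2$sr)

  # pooled within-run SD against direct arithmetic (independent oracle)
  x <- c(vector_with_cv(6, 10, 0.05, seed = 2),
         vector_with_cv(6, 10.5, 0.08, seed = 3))
  run <- rep(c("r1", "r2"), each = 6)
  pooled <- sqrt(sum(tapply(x, run, function(v) (length(v) - 1) * var(v))) /
                   (length(x) - 2))
  expect_equal(precision(x, run)$sr, pooled, tolerance = 1e-12)

  expect_error(precision(1), class = "undefined_sd")
})

test_that("trueness and precision ignore ordering and run labels", {
  x <- vector_with_cv(12, 2, 0.1, seed = 4)
  run <- rep(c("r1", "r2", "r3"), each = 4)
  perm <- with_fixed_seed(9, sample(12))
  expect_equal(trueness(x[perm], 2), trueness(x, 2))
  p1 <- precision(x, run)
  p2 <- precision(x[perm], run[perm])
  expect_equal(p1$sr, p2$sr, tolerance = 1e-12)
  p3 <- precision(x, paste0("renamed_", run))
  expect_equal(p1$sr, p3$sr, tolerance = 1e-12)
})

test_that("dynamic range is the widest contiguous passing span", {
  tab <- data.frame(level = c(0.05, 0.1, 0.5, 1, 2, 10, 100),
                    rsdr_percent = c(23, 14, 10, 6, 9, 2, 2),
                    bias_abs_percent = c(20, 21, 24, 23, 24, 20, 2.4))
  dr <- dynamic_range_assessment(tab)
  expect_true(dr$all_pass)
  expect_equal(dr$range, c(0.05, 100))

  tab$rsdr_percent[1] <- 30  # lowest level fails precision only
  dr2 <- dynamic_range_assessment(tab)
  expect_false(dr2$all_pass)
  expect_equal(dr2$range, c(0.1, 100))

  expect_error(dynamic_range_assessment(tab[1, ]), class = "invalid_argument")
})

test_that("linearity matches the closed-form OLS solution", {
  nominal <- c(0.1, 0.5, 1, 2, 10, 100)
  ident <- data.frame(nominal_level = nominal, gm_percent = nominal)
  l <- linearity(ident)
  expect_equal(l$per_run$slope, 1, tolerance = 1e-12)
  expect_equal(l$per_run$intercept, 0, tolerance = 1e-12)
  expect_equal(l$per_run$r_squared, 1, tolerance = 1e-12)

  # noiseless affine data reproduces slope/intercept to 1e-9 against the
  # closed-form least-squares solution
  aff <- data.frame(nominal_level = nominal,
                    gm_percent = 1.04 * nominal + 0.3)
  slope_cf <- sum((nominal - mean(nominal)) *
                    (aff$gm_percent - mean(aff$gm_percent))) /
    sum((nominal - mean(nominal))^2)
  l2 <- linearity(aff)
  expect_equal(l2$per_run$slope, slope_cf, tolerance = 1e-9)
  expect_equal(l2$per_run$slope, 1.04, tolerance = 1e-9)
  expect_equal(l2$per_run$intercept, 0.3, tolerance = 1e-9)
  expect_true(l2$pass)

  # slope outside 1 +/- 0.25 fails
  off <- data.frame(nominal_level = nominal, gm_percent = 1.30 * nominal)
  expect_false(linearity(off)$pass)

  expect_error(linearity(data.frame(nominal_level = c(1, 2),
                                    gm_percent = c(1, 2))),
               class = "invalid_argument")
})

test_that("asymmetric LOQ picks the lowest precision-passing level", {
  cand <- rbind(
    data.frame(nominal_level = 0.01,
               gm_percent = vector_with_cv(30, 0.01, 0.35, seed = 5),
               copies_per_reaction = vector_with_cv(30, 10, 0.02, seed = 6)),
    data.frame(nominal_level = 0.05,
               gm_percent = vector_with_cv(30, 0.05, 0.23, seed = 7),
               copies_per_reaction = vector_with_cv(30, 50, 0.02, seed = 8)),
    data.frame(nominal_level = 0.1,
               gm_percent = vector_with_cv(30, 0.1, 0.10, seed = 9),
               copies_per_reaction = vector_with_cv(30, 100, 0.02, seed = 10)))
  r <- loq_asym(cand, min_replicates = 30)
  expect_true(r$established)
  expect_equal(r$level, 0.05)  # 35% RSDr fails, 23% is the lowest pass
  expect_equal(r$loq_copies_per_reaction, 50, tolerance = 1e-9)

  # all candidates passing -> lowest level returned
  all_ok <- cand
  all_ok$gm_percent[all_ok$nominal_level == 0.01] <-
    vector_with_cv(30, 0.01, 0.2, seed = 11)
  expect_equal(loq_asym(all_ok, min_replicates = 30)$level, 0.01)

  # no candidate passing -> verdict, not an exception
  none <- cand[cand$nominal_level == 0.01, ]
  r2 <- loq_asym(none, min_replicates = 30)
  expect_false(r2$established)
  expect_true(is.na(r2$loq_copies_per_reaction))

  # replicate floor: levels below min_replicates cannot establish the LOQ
  thin <- cand[cand$nominal_level == 0.05, ][1:10, ]
  expect_false(loq_asym(thin, min_replicates = 30)$established)
})

test_that("robustness design is a full factorial in standard order", {
  d4 <- robustness_design(c("mastermix_-10pct", "annealing_+1C",
                            "ramp_+0.5C_s", "oligo_-10pct"))
  expect_identical(nrow(d4), 16L)
  d3 <- robustness_design(c("mastermix_-10pct", "annealing_+1C",
                            "oligo_-10pct"))
  expect_identical(nrow(d3), 8L)
  expect_identical(nrow(robustness_design()), 1L)

  # rows unique; each factor at each level in exactly half the rows
  expect_identical(anyDuplicated(d4[-1]), 0L)
  for (f in names(d4)[-1]) {
    expect_identical(sum(d4[[f]] == "changed"), 8L)
  }
  # deterministic standard order: first factor alternates fastest
  expect_identical(d4[[2]][1:4], rep(c("baseline", "changed"), 2))

  expect_error(robustness_design(as.list(1:7)), class = "invalid_argument")
})

test_that("robustness evaluation enforces the 30% rule per condition", {
  lvl <- 0.05
  good <- do.call(rbind, lapply(1:16, function(k) {
    data.frame(condition = k,
               gm_percent = vector_with_cv(4, lvl * 1.05, 0.29, seed = k))
  }))
  r <- robustness_evaluate(good, lvl)
  expect_true(r$pass)
  expect_lt(max(r$table$rsdr_percent), 30)

  # one condition biased 35% -> overall fail
  bad <- good
  bad$gm_percent[bad$condition == 7] <-
    vector_with_cv(4, lvl * 1.35, 0.1, seed = 99)
  r2 <- robustness_evaluate(bad, lvl)
  expect_false(r2$pass)
  expect_false(r2$table$pass[r2$table$condition == 7])

  # exact nominal everywhere: zero bias, pass
  flat <- data.frame(condition = rep(1:4, each = 2), gm_percent = lvl)
  r3 <- robustness_evaluate(flat, lvl)
  expect_true(r3$pass)
  expect_true(all(r3$table$bias_percent == 0))

  # a condition with a single replicate is incomplete, not silently passed
  thin <- rbind(flat, data.frame(condition = 5, gm_percent = lvl))
  r4 <- robustness_evaluate(thin, lvl)
  expect_false(r4$complete)
  expect_false(r4$pass)
})

test_that("measurement uncertainty combines components in quadrature", {
  expect_equal(measurement_uncertainty(1, 0, 10, 0, 0)$expanded_u, 0)

  # RSDr 10%, n = 25, no bias: u_c = 0.02, U = 0.04 x mean
  mu <- measurement_uncertainty(2, 10, 25, 0, 0)
  expect_equal(mu$u_c_relative, 0.02, tolerance = 1e-12)
  expect_equal(mu$expanded_u, 0.04 * 2, tolerance = 1e-12)

  # monotone non-decreasing in |bias|, RSDr, u_ref
  base <- measurement_uncertainty(1, 10, 25, 5, 0.01)$expanded_u
  expect_gt(measurement_uncertainty(1, 20, 25, 5, 0.01)$expanded_u, base)
  expect_gt(measurement_uncertainty(1, 10, 25, 10, 0.01)$expanded_u, base)
  expect_gt(measurement_uncertainty(1, 10, 25, 5, 0.05)$expanded_u, base)
  expect_equal(measurement_uncertainty(1, 10, 25, -5, 0.01)$expanded_u, base)

  expect_error(measurement_uncertainty(1, 10, 1, 0), class = "invalid_argument")
})

test_that("the battery recovers generator parameters on synthetic data", {
  # bias -> 0 and RSDr -> 100c within 15% relative, averaged over simulations
  c_true <- 0.1
  stats <- vapply(1:200, function(i) {
    m <- simulate_gm_measurements(2, cv = c_true, replicates_per_level = 6,
                                  runs = 5, seed = 3000 + i)
    c(trueness(m$gm_percent, 2)$bias_percent,
      precision(m$gm_percent, m$run_id)$rsdr_percent)
  }, numeric(2))
  expect_lt(abs(mean(stats[1, ])), 1)             # bias near zero (percent)
  expect_lt(abs(mean(stats[2, ]) - 100 * c_true) / (100 * c_true), 0.15)
})
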