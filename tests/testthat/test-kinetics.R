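test_that("exponential rate MLE equals 1/mean with chi-square CI", {
  r <- estimate_rate(c(1, 2, 3, 4))
  expect_equal(r$rate_per_s, 0.4)
  expect_lt(r$ci[1], 0.4)
  expect_gt(r$ci[2], 0.4)
  # single dwell: 1/d with a wide interval
  r1 <- estimate_rate(5)
  expect_equal(r1$rate_per_s, 0.2)
  expect_gt(r1$ci[2] / r1$ci[1], 50)
  expect_error(estimate_rate(numeric(0)), "at least one")
  expect_error(estimate_rate(c(1, -1)), "> 0")
  # recovery: 1000 simulated dwells at 2/s
  set.seed(9)
  d <- rexp(1000, 2)
  est <- estimate_rate(d)
  expect_lt(abs(est$rate_per_s - 2), 2 * 2 / sqrt(1000))
})

test_that("equilibrium force by linear ln K root and by median rupture", {
  rates <- data.frame(force_pN = c(3, 5),
                      k_fold_per_s = c(exp(1), exp(-1)),
                      k_unfold_per_s = c(1, 1))
  expect_equal(equilibrium_force(rates, "rates"), 4.0)
  expect_equal(equilibrium_force(c(3.0, 3.5, 4.0, 4.5, 5.0)), 4.0)
  expect_warning(
    equilibrium_force(data.frame(force_pN = c(3, 5),
                                 k_fold_per_s = c(10, 5),
                                 k_unfold_per_s = c(1, 1)), "rates"),
    "extrapolation")
  # a Bell-model rate pair recovers its own equilibrium force
  kBT <- env25$thermal_energy_pNnm
  f <- seq(2, 6, by = 0.5)
  feq_true <- 4.2
  k_unf <- 0.1 * exp((f - feq_true) * 1.5 / kBT)
  k_fold <- 0.1 * exp(-(f - feq_true) * 1.2 / kBT)
  rates <- data.frame(force_pN = f, k_fold_per_s = k_fold,
                      k_unfold_per_s = k_unf)
  feq_hat <- equilibrium_force(rates, "rates")
  expect_lt(abs(feq_hat - feq_true), 0.1)
  # consistency: the rate free energy vanishes at the fitted Feq
  ku <- 0.1 * exp((feq_hat - feq_true) * 1.5 / kBT)
  kf <- 0.1 * exp(-(feq_hat - feq_true) * 1.2 / kBT)
  expect_lt(abs(delta_g_from_rates(kf, ku, env25)), 0.01)
})

test_that("state-counting Kd follows the count ratio times concentration", {
  expect_equal(estimate_kd(300, 700, 83), 300 / 700 * 83)
  expect_equal(estimate_kd(0, 50, 83), 0)
  expect_equal(estimate_kd(50, 50, 83), 83)
  expect_error(estimate_kd(10, 0, 83), "unbounded")
})

test_that("Kd bootstrap recovers the generating constant with honest spread", {
  cyc <- simulate_force_jump_binding(16.3, 83, 1000, "unmodified", seed = 4)
  est <- kd_uncertainty(cyc, 83, n_boot = 2000, seed = 4)
  expect_s3_class(est, "kd_estimate")
  # binomial delta method gives SE ~1.4 nM at n = 1000
  expect_lt(abs(est$kd_nM - 16.3), 3)
  expect_true(est$ci_95[1] <= 16.3 && 16.3 <= est$ci_95[2])
  expect_gt(est$se_nM, 0.5)
  expect_lt(est$se_nM, 3)
  expect_error(kd_uncertainty(cyc[1:5, ], 83), "at least 10")
})

test_that("bootstrap CI covers the truth at near-nominal rate", {
  hits <- vapply(1:60, function(s) {
    cyc <- simulate_force_jump_binding(16.3, 83, 300, "unmodified", seed = s)
    est <- kd_uncertainty(cyc, 83, n_boot = 400, seed = s)
    est$ci_95[1] <= 16.3 && 16.3 <= est$ci_95[2]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("condition comparison separates different Kd and not identical data", {
  a <- simulate_force_jump_binding(16.3, 83, 1000, "unmodified", seed = 6)
  b <- simulate_force_jump_binding(8.0, 83, 1000, "ubh2b", seed = 7)
  cmp <- compare_conditions(a, b, 83, seed = 6)
  expect_lt(cmp$p_value, 0.01)
  expect_lt(cmp$p_value_proportion, 0.01)
  expect_gt(cmp$difference_nM, 0)
  same <- compare_conditions(a, a, 83, seed = 8)
  expect_gt(same$p_value, 0.5)
})

test_that("box-plot summary applies the 1.5 IQR fence with type-7 quartiles", {
  s <- summarize_distribution(c(1, 2, 3, 4, 100))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$outliers, 100)
  expect_equal(s$whisker_high, 4)
  const <- summarize_distribution(rep(7, 10))
  expect_equal(const$median, 7)
  expect_equal(const$q1, const$q3)
  expect_length(const$outliers, 0)
  sym <- summarize_distribution(seq(-5, 5, by = 0.5))
  expect_equal(sym$median, mean(seq(-5, 5, by = 0.5)))
  expect_error(summarize_distribution(numeric(0)), "non-empty")
})

test_that("distribution summary is permutation-invariant and affine-monotone", {
  set.seed(13)
  x <- rnorm(50)
  a <- summarize_distribution(x)
  b <- summarize_distribution(sample(x))
  expect_equal(a, b)
  shifted <- summarize_distribution(2 * x + 3)
  expect_equal(shifted$median, 2 * a$median + 3)
  expect_equal(shifted$q1, 2 * a$q1 + 3)
  expect_equal(shifted$q3, 2 * a$q3 + 3)
})

test_that("assembly fractions aggregate batches as mean and SD in percent", {
  af <- assembly_fraction(list(rep(c(TRUE, FALSE), c(8, 2)),
                               rep(c(TRUE, FALSE), c(7, 3)),
                               rep(c(TRUE, FALSE), c(9, 1))))
  expect_equal(af$mean_percent, 80)
  expect_equal(af$sd_percent, 10)
  all_in <- assembly_fraction(list(rep(TRUE, 5)))
  expect_equal(all_in$mean_percent, 100)
  expect_equal(all_in$sd_percent, 0)
  expect_warning(assembly_fraction(list(logical(0), c(TRUE, FALSE))),
                 "skipped")
  # simulated batches at the observed assembly probability
  set.seed(5)
  batches <- replicate(30, runif(25) < 0.791, simplify = FALSE)
  af2 <- assembly_fraction(batches)
  se <- 100 * sqrt(0.791 * 0.209 / (30 * 25))
  expect_lt(abs(af2$mean_percent - 79.1), 3 * se)
})

test_that("Kd recovery composes with the simulator over a range of constants", {
  for (kd in c(5, 16.3, 40)) {
    cyc <- simulate_force_jump_binding(kd, 83, 800, "unmodified",
                                       seed = 100 + kd)
    est <- kd_uncertainty(cyc, 83, n_boot = 500, seed = 1)
    expect_lt(abs(est$kd_nM - kd), 2.5 * est$se_nM + 1e-9)
  }
})
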