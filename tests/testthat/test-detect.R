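test_that("a smooth WLC ramp with no transitions yields no rupture events", {
  tr <- programmed_ramp(numeric(0), 99, noise_sd = 0)
  expect_equal(nrow(detect_ruptures(tr)), 0L)
  expect_error(detect_ruptures(data.frame(time_s = 1:3)), "missing required")
})

test_that("a programmed rupture is recovered in force and contour gain", {
  tr <- programmed_ramp(4.0, c(99, 119), noise_sd = 2, seed = 11)
  ev <- detect_ruptures(tr, window_samples = 40)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$force_pN - 4.0), 0.1)
  expect_lt(abs(ev$contour_gain_nm - 20), 1)
})

test_that("two programmed transitions are detected in ramp order", {
  tr <- programmed_ramp(c(4, 23), c(99, 119, 146), noise_sd = 2, seed = 12)
  ev <- detect_ruptures(tr, window_samples = 40)
  expect_equal(nrow(ev), 2L)
  expect_true(all(diff(ev$time_s) > 0))
  expect_lt(abs(ev$force_pN[1] - 4), 0.1)
  expect_lt(abs(ev$force_pN[2] - 23), 0.1)
  expect_lt(max(abs(ev$contour_gain_nm - c(20, 27))), 1)
})

test_that("noiseless detected contour gains equal the configured gains", {
  tr <- programmed_ramp(c(4, 23), c(99, 119, 146), noise_sd = 0)
  ev <- detect_ruptures(tr)
  # the residual offset is the WLC growth across the detection window
  expect_equal(ev$contour_gain_nm, c(20, 27), tolerance = 2e-3)
})

test_that("rupture classification follows the order and boundary rules", {
  ev <- data.frame(cycle = 1L, time_s = c(10, 50), force_pN = c(4, 23),
                   extension_jump_nm = c(18, 25), contour_gain_nm = c(20, 27),
                   wrap_class = "unclassified", stringsAsFactors = FALSE)
  got <- classify_ruptures(ev, "nucleosome")
  expect_equal(got$wrap_class, c("outer", "inner"))
  # lone event above / below the 12 pN boundary
  lone <- ev[1, ]
  lone$force_pN <- 16
  expect_equal(classify_ruptures(lone, "nucleosome")$wrap_class, "inner")
  lone$force_pN <- 5
  expect_equal(classify_ruptures(lone, "nucleosome")$wrap_class, "outer")
  # tetrasome mode: everything is the inner wrap
  expect_equal(classify_ruptures(lone, "tetrasome")$wrap_class, "inner")
  # extras beyond two are flagged
  ev3 <- rbind(ev, transform(ev[2, ], time_s = 60))
  expect_equal(classify_ruptures(ev3, "nucleosome")$wrap_class,
               c("outer", "inner", "unclassified"))
  # empty in, empty out
  empty <- ev[0, ]
  expect_equal(nrow(classify_ruptures(empty, "nucleosome")), 0L)
})

test_that("reversibility calls distinguish recurring from one-shot patterns", {
  two_step <- function(cyc) {
    data.frame(cycle = cyc, time_s = cyc * 100 + c(1, 2),
               force_pN = c(4, 23), extension_jump_nm = 20,
               contour_gain_nm = 22, wrap_class = "unclassified",
               stringsAsFactors = FALSE)
  }
  all_cycles <- do.call(rbind, lapply(1:5, two_step))
  expect_true(assess_reversibility(all_cycles, 5, "nucleosome")$reversible)
  only_first <- two_step(1)
  expect_false(assess_reversibility(only_first, 5, "nucleosome")$reversible)
  expect_true(is.na(assess_reversibility(only_first, 1, "nucleosome")$reversible))
  # tetrasome mode needs only one step per cycle
  one_step <- do.call(rbind, lapply(1:4, function(c) two_step(c)[1, ]))
  expect_true(assess_reversibility(one_step, 4, "tetrasome")$reversible)
  expect_false(assess_reversibility(one_step, 4, "nucleosome")$reversible)
})

test_that("dwell extraction is exact on a noiseless square wave", {
  dt <- 0.01
  x <- rep(rep(c(0, 30), 8), times = rep(c(100, 200), 8))
  tr <- data.frame(time_s = seq_along(x) * dt, extension_nm = x,
                   force_pN = 3.5)
  dw <- extract_dwells(tr)
  expect_equal(dw$duration_s[dw$state == "folded"], rep(1, 7))
  expect_equal(dw$duration_s[dw$state == "unfolded"], rep(2, 7))
  # first and last dwells are censored and dropped
  expect_equal(nrow(dw), 14L)
})

test_that("constant and indistinguishable traces are handled explicitly", {
  flat <- data.frame(time_s = 1:100 / 10, extension_nm = rep(5, 100))
  expect_equal(nrow(extract_dwells(flat)), 0L)
  set.seed(3)
  noisy <- data.frame(time_s = 1:2000 / 100,
                      extension_nm = rnorm(2000, 0, 3) +
                        rep(c(0, 1), each = 1000))
  expect_error(extract_dwells(noisy), "indistinguishable")
})

test_that("dwell counts on simulated hopping are close to truth", {
  tr <- simulate_constant_force_hopping(3.5, 0.5, 0.5, 500,
                                        noise = noise_model(0.01, 2), seed = 2)
  dw <- extract_dwells(tr)
  n_truth <- sum(tr$truth_state[-1] != tr$truth_state[-nrow(tr)]) - 1L
  expect_lt(abs(nrow(dw) - n_truth) / n_truth, 0.1)
  rate <- estimate_rate(dw$duration_s[dw$state == "folded"])
  expect_gt(rate$ci[1], 0.3)
  expect_lt(rate$ci[2], 0.8)
})

test_that("step detection is exact without noise and silent on flat traces", {
  flat <- data.frame(time_s = 1:200 / 10, extension_nm = rep(3, 200))
  expect_equal(nrow(detect_steps(flat)), 0L)
  x <- c(rep(100, 300), rep(110, 400), rep(120, 300))
  tr <- data.frame(time_s = seq_along(x) / 100, extension_nm = x)
  st <- detect_steps(tr)
  expect_equal(nrow(st), 2L)
  expect_equal(st$size_nm, c(10, 10))
})

test_that("steps survive realistic noise", {
  tr <- simulate_deposition_trace(c(10, 10), mean_wait_s = 10,
                                  noise = noise_model(0.01, 2), seed = 3)
  st <- detect_steps(tr)
  expect_equal(nrow(st), 2L)
  expect_true(all(abs(st$size_nm - 10) < 1))
})

test_that("binding-cycle classification maps disruption by condition", {
  expect_equal(classify_binding_cycle(TRUE, "unmodified"), "complex")
  expect_equal(classify_binding_cycle(FALSE, "unmodified"), "nucleosome")
  expect_equal(classify_binding_cycle(TRUE, "ubh2b"), "nucleosome")
  expect_equal(classify_binding_cycle(FALSE, "ubh2b"), "complex")
  expect_error(classify_binding_cycle(TRUE, "other"), "unknown condition")
  cyc <- simulate_force_jump_binding(16.3, 83, 200, "unmodified", seed = 4)
  out <- classify_binding_cycle(cyc)
  expect_identical(out$outcome == "complex", cyc$truth_bound)
  cyc2 <- simulate_force_jump_binding(16.3, 83, 200, "ubh2b", seed = 4)
  out2 <- classify_binding_cycle(cyc2)
  expect_identical(out2$outcome == "complex", cyc2$truth_bound)
})
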