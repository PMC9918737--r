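fast_prot <- function(n_cycles = 1L, sample_rate_Hz = 25) {
  ramp_protocol(sample_rate_Hz = sample_rate_Hz, n_cycles = n_cycles)
}

test_that("simulators are byte-reproducible for identical (config, seed)", {
  a <- simulate_stretch_cycles("h2b", fast_prot(2), noise_model(0.01, 2), seed = 9)
  b <- simulate_stretch_cycles("h2b", fast_prot(2), noise_model(0.01, 2), seed = 9)
  expect_identical(a, b)
  c1 <- simulate_force_jump_binding(16.3, 83, 50, "unmodified", seed = 3)
  c2 <- simulate_force_jump_binding(16.3, 83, 50, "unmodified", seed = 3)
  expect_identical(c1, c2)
  expect_false(identical(
    a$extension_nm,
    simulate_stretch_cycles("h2b", fast_prot(2), noise_model(0.01, 2),
                            seed = 10)$extension_nm
  ))
})

test_that("noiseless ramp traces lie exactly on the labelled state's WLC curve", {
  tr <- simulate_stretch_cycles("h2b", fast_prot(), noise_model(0, 0), seed = 1)
  cond <- nucleosome_condition("h2b")
  L <- cond$states$tether_contour_nm[match(tr$truth_state, cond$states$name)]
  z <- tr$extension_nm / L
  expect_equal(wlc_force(z, polymer_state("s", 1, 50), env25), tr$force_pN,
               tolerance = 1e-6)
  # force follows the law along the magnet schedule
  expect_equal(predict(fast_prot()$force_law, tr$magnet_pos_um / 1e3),
               tr$force_pN)
  expect_true(all(diff(tr$time_s) > 0))
})

test_that("near-instantaneous transitions at threshold forces rupture at the thresholds", {
  cond <- nucleosome_condition("h2b")
  kBT <- env25$thermal_energy_pNnm
  law <- default_force_law()
  # a huge barrier distance makes the Bell rate a near-step function of force;
  # k0 is set so the cumulative hazard reaches ln 2 right at the threshold:
  # k(F_th) = ln2 * x * dF/dt / kBT for an exponential hazard under a ramp
  ramp_rate <- function(f) {
    z <- uniroot(function(z) predict(law, z) - f, c(1e-6, 50), tol = 1e-12)$root
    0.01 * (law$a1_pN / law$d1_mm * exp(-z / law$d1_mm) +
              law$a2_pN / law$d2_mm * exp(-z / law$d2_mm))
  }
  k0_at <- function(f_th, x) log(2) * x * ramp_rate(f_th) / kBT * exp(-x * f_th / kBT)
  cond$transitions <- data.frame(
    from = c("intact", "outer_open"),
    to = c("outer_open", "fully_unfolded"),
    k0_per_s = c(k0_at(4, 400), k0_at(23, 60)),
    x_dagger_nm = c(400, 60),
    stringsAsFactors = FALSE
  )
  tr <- simulate_stretch_cycles(cond, fast_prot(), noise_model(0, 0), seed = 5)
  tru <- truth_transitions(tr)
  expect_equal(nrow(tru), 2L)
  expect_lt(abs(tru$force_pN[1] - 4), 0.1)
  expect_lt(abs(tru$force_pN[2] - 23), 0.25)
})

test_that("without reassembly, cycles after full unfolding stay unfolded", {
  tr <- simulate_stretch_cycles("h2b", fast_prot(3), noise_model(0, 0), seed = 2)
  later <- tr[tr$cycle > 1, ]
  expect_true(all(later$truth_state == "fully_unfolded"))
  # with the chaperone present the molecule refolds each cycle
  tr2 <- simulate_stretch_cycles("ubh2b_fact", fast_prot(3), noise_model(0, 0),
                                 seed = 2)
  expect_true(all(tapply(tr2$truth_state == "intact", tr2$cycle, any)))
})

test_that("state contour lengths must increase along the unfolding order", {
  cond <- nucleosome_condition("h2b")
  cond$states$tether_contour_nm <- c(119, 99, 146)
  expect_error(simulate_stretch_cycles(cond, fast_prot(), seed = 1),
               "strictly increase")
})

test_that("constant-force hopping has correct occupancy and dwell statistics", {
  tr <- simulate_constant_force_hopping(3.5, 1, 1, 1000,
                                        noise = noise_model(0, 0), seed = 7)
  occ <- mean(tr$truth_state == "unfolded")
  # stationary occupancy 1/2 within 3 binomial-style SE on ~1000 dwells
  n_dwell <- sum(tr$truth_state[-1] != tr$truth_state[-nrow(tr)])
  expect_gt(n_dwell, 200)
  expect_lt(abs(occ - 0.5), 3 * 0.5 / sqrt(n_dwell))
  # mean dwell duration within 2 SE of 1/k per state
  s <- tr$truth_state
  r <- rle(s)
  dt <- tr$time_s[2] - tr$time_s[1]
  for (state in c("folded", "unfolded")) {
    d <- r$lengths[r$values == state] * dt
    d <- d[-c(1, length(d))]
    expect_lt(abs(mean(d) - 1), 2 * 1 / sqrt(length(d)))
  }
  # dwell times are exponential with the generating rate (KS test on the
  # continuous switch times, free of grid quantisation)
  durations <- diff(c(0, attr(tr, "switch_times_s")))
  expect_gt(length(durations), 500)
  expect_gt(stats::ks.test(durations, "pexp", 1)$p.value, 0.01)
})

test_that("a zero unfolding rate pins the hopping trace in the folded state", {
  tr <- simulate_constant_force_hopping(3.5, 1, 0, 50,
                                        noise = noise_model(0, 0), seed = 1)
  expect_true(all(tr$truth_state == "folded"))
  expect_error(
    simulate_constant_force_hopping(3.5, 1, 1, -5, seed = 1), "> 0")
})

test_that("hopping extension levels sit on the two WLC curves", {
  tr <- simulate_constant_force_hopping(3.5, 0.5, 0.5, 100,
                                        noise = noise_model(0, 0), seed = 4)
  lev <- sort(unique(round(tr$extension_nm, 9)))
  expect_equal(lev, c(wlc_extension(3.5, ncp99, env25),
                      wlc_extension(3.5, dna119, env25)),
               tolerance = 1e-6)
})

test_that("force-jump binding cycles are Bernoulli with the occupancy probability", {
  # kd = conc: occupancy 1/2
  cyc <- simulate_force_jump_binding(83, 83, 10000, "unmodified", seed = 11)
  expect_lt(abs(mean(cyc$truth_bound) - 0.5), 3 * 0.005)
  # kd = 0: all bound
  cyc0 <- simulate_force_jump_binding(0, 83, 100, "unmodified", seed = 1)
  expect_true(all(cyc0$truth_bound))
  # expected occupancy 83 / (83 + 16.3)
  cyc2 <- simulate_force_jump_binding(16.3, 83, 20000, "ubh2b", seed = 12)
  expect_lt(abs(mean(cyc2$truth_bound) - 83 / 99.3), 3 * 0.0035)
  # probe-force rule per condition
  expect_equal(unique(cyc$probe_force_pN), 11)
  expect_equal(unique(cyc2$probe_force_pN), 6)
  expect_identical(cyc$disruption_at_probe, cyc$truth_bound)
  expect_identical(cyc2$disruption_at_probe, !cyc2$truth_bound)
  expect_error(simulate_force_jump_binding(-1, 83, 10, seed = 1), ">= 0")
})

test_that("deposition traces step by the configured sizes", {
  tr <- simulate_deposition_trace(c(10, 10), mean_wait_s = 5,
                                  noise = noise_model(0, 0), seed = 3)
  lev <- unique(tr$extension_nm)
  expect_length(lev, 3L)
  expect_equal(diff(lev), c(10, 10))
  # empty step list gives a flat trace
  flat <- simulate_deposition_trace(numeric(0), mean_wait_s = 5,
                                    noise = noise_model(0, 0), seed = 3)
  expect_equal(length(unique(flat$extension_nm)), 1L)
})

test_that("bead fluctuations have equipartition variance and OU autocorrelation", {
  b <- simulate_bead_fluctuations(10, 3000, duration_s = 300, seed = 5)
  expect_equal(attr(b, "stationary_sd_nm")^2, 1234.9, tolerance = 1e-4)
  expect_equal(attr(b, "corner_frequency_Hz"), 22.59, tolerance = 1e-3)
  expect_lt(abs(var(b$y_nm) / 1234.9 - 1), 0.1)
  # autocorrelation time gamma * l / F
  tau <- attr(b, "relaxation_s")
  a1 <- acf(b$y_nm, lag.max = 10, plot = FALSE)$acf[, 1, 1]
  expect_equal(a1[2], exp(-(1 / 500) / tau), tolerance = 0.05)
  # variance decreases with force
  v <- vapply(c(1, 5, 20), function(f) {
    attr(simulate_bead_fluctuations(f, 3000, duration_s = 1, seed = 1),
         "stationary_sd_nm")^2
  }, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_error(simulate_bead_fluctuations(-1, 3000, duration_s = 1, seed = 1),
               "> 0")
})
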