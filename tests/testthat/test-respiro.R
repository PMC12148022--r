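test_that("flow correction to STP follows the ideal-gas and dilution factors", {
  expect_equal(flow_to_stp(100, 0, 101.3, 0), 100)
  expect_equal(flow_to_stp(100, 25, 101.3, 0), 100 * 273.15 / 298.15)
  expect_equal(flow_to_stp(100, 0, 101.3, 0.02), 98)
  expect_equal(flow_to_stp(100, 25, 90, 0.01),
               100 * (273.15 / 298.15) * (90 / 101.3) * 0.99)
  expect_error(flow_to_stp(100, 25, 101.3, 1), "f_h2o")
  expect_error(flow_to_stp(100, 25, 0), "pressure_amb")
})

test_that("baseline drift fit is the least-squares line through pre+post", {
  # pre mean 10 ppm centred at t = 0, post mean 12 ppm centred at t = 3240
  bl <- baseline_pair(
    pre = data.frame(time_s = -30:30, co2_ppm = 10),
    post = data.frame(time_s = 3210:3270, co2_ppm = 12))
  drift <- fit_baseline_drift(bl)
  expect_equal(drift$fi_of(1620), 11e-6)
  # constant baselines: zero slope
  bl0 <- baseline_pair(
    pre = data.frame(time_s = 0:60, co2_ppm = 7),
    post = data.frame(time_s = 1000:1060, co2_ppm = 7))
  d0 <- fit_baseline_drift(bl0)
  expect_equal(d0$slope, 0)
  expect_equal(d0$fi_of(c(0, 500, 1e4)), rep(7e-6, 3))
})

test_that("simulated analyser drift is recovered by the baseline fit", {
  for (slope_ppm_min in c(-0.1, 0.05, 0.2)) {
    sim <- simulate_trace(quick_trace_params(drift_slope = slope_ppm_min))
    drift <- fit_baseline_drift(sim$baselines)
    expect_equal(drift$slope, slope_ppm_min / 60, tolerance = 1e-8)
  }
})

test_that("settling trim keeps the interior window with original timestamps", {
  sim <- simulate_trace(trace_sim_params())
  tr <- trim_settling(sim$trace, 600, 600)
  expect_equal(diff(range(tr$time)), 3600 - 1200 - 1)
  expect_true(all(tr$time %in% sim$trace$time))
  expect_identical(trim_settling(sim$trace, 0, 0), sim$trace)
  short <- resp_trace(0:899, rep(10, 900), 100)
  expect_error(trim_settling(short), "settl")
})

test_that("burst starts on noiseless traces match simulator truth within 2 samples", {
  sim <- simulate_trace(quick_trace_params())
  tr <- trim_settling(sim$trace, 120, 120)
  drift <- fit_baseline_drift(sim$baselines)
  cs <- detect_cycles(tr, drift, quick_opts())
  expect_gt(nrow(cs$bursts), 7)
  truth <- sim$truth$burst_starts
  for (i in seq_len(nrow(cs$bursts))) {
    nearest <- min(abs(truth - cs$bursts$start_s[i]))
    expect_lte(nearest, 2)
  }
  expect_identical(cs$qc_flags, character())
})

test_that("a flat trace yields no cycles and a no-DGC flag, not an error", {
  sim <- simulate_trace(trace_sim_params(true_vco2 = 0, noise_sd = 0,
                                         drift_slope = 0.05))
  tr <- trim_settling(sim$trace)
  drift <- fit_baseline_drift(sim$baselines)
  cs <- detect_cycles(tr, drift)
  expect_identical(cs$n_complete, 0L)
  expect_true("no DGC" %in% cs$qc_flags)
})

test_that("cycle counting is robust to measurement noise", {
  hits <- 0L
  for (s in 1:10) {
    sim <- simulate_trace(trace_sim_params(noise_sd = 3.3, seed = s))
    drift <- fit_baseline_drift(sim$baselines)
    cs <- detect_cycles(trim_settling(sim$trace), drift)
    hits <- hits + (cs$n_complete == 18L)  # truth for the default design
  }
  expect_gte(hits, 9L)
})

test_that("V̇CO2 equals the closed form on constant signals", {
  ct <- constant_trace(fe_ppm = 50, fi_ppm = 10)
  expected <- 100 * (50e-6 - 10e-6) / (1 - 50e-6)
  expect_equal(compute_vco2(ct$trace, ct$drift), expected,
               tolerance = 1e-12)
  expect_equal(expected, 4.0002e-3, tolerance = 1e-4)
  # Fe == Fi -> exactly zero
  ct0 <- constant_trace(fe_ppm = 10, fi_ppm = 10)
  expect_equal(compute_vco2(ct0$trace, ct0$drift), 0)
})

test_that("V̇CO2 recovery on whole cycles is window-start invariant", {
  sim <- simulate_trace(trace_sim_params(noise_sd = 0))
  drift <- fit_baseline_drift(sim$baselines)
  cs <- detect_cycles(trim_settling(sim$trace), drift)
  starts <- cs$cycles$cycle_start_s
  for (j in c(1, 3, 5)) {
    w <- c(starts[j], starts[j + 7])  # seven whole cycles from cycle j
    v <- compute_vco2(sim$trace, drift, w)
    expect_lt(abs(v / 0.002 - 1), 0.005,
              label = sprintf("relative error starting at cycle %d", j))
  }
})

test_that("a shared linear ramp on baseline and signal cancels out", {
  sim <- simulate_trace(trace_sim_params(noise_sd = 0, drift_slope = 0))
  sim_r <- simulate_trace(trace_sim_params(noise_sd = 0, drift_slope = 0.3))
  v <- compute_vco2(sim$trace, fit_baseline_drift(sim$baselines))
  v_r <- compute_vco2(sim_r$trace, fit_baseline_drift(sim_r$baselines))
  expect_lt(abs(v_r / v - 1), 0.001)
})

test_that("gas-exchange frequency is k over the measured span", {
  bursts <- data.frame(start_s = seq(0, 960, by = 120),
                       end_s = seq(0, 960, by = 120) + 36)
  cs <- structure(list(bursts = bursts,
                       cycles = data.frame(
                         cycle_start_s = bursts$start_s[-nrow(bursts)],
                         cycle_end_s = bursts$start_s[-1]),
                       n_complete = nrow(bursts) - 1L,
                       threshold_ppm = 5, qc_flags = character()),
                  class = "cycle_set")
  expect_equal(as.numeric(compute_fge(cs, k = 7)), 0.5)
  expect_equal(as.numeric(compute_fge(cs, k = 1)), 60 / 120)
  # strict span mode omits the final interburst: 6x120 + 36 s for k = 7
  expect_equal(as.numeric(compute_fge(cs, k = 7, fge_mode = "span")),
               7 / ((6 * 120 + 36) / 60))
  # exactly k bursts still supports the strict span; k+1 needed beyond that
  expect_equal(as.numeric(compute_fge(cs, k = 9)),
               9 / ((8 * 120 + 36) / 60))
  expect_warning(f <- compute_fge(cs, k = 10), "insufficient")
  expect_true(is.na(f))
})

test_that("end-to-end measurement recovers truth on a simulated bee", {
  sim <- simulate_trace(trace_sim_params(noise_sd = 0, seed = 21))
  rec <- measure_bee(sim$trace, sim$baselines, mass_mg = 2.1,
                     species = "H_fijiensis")
  expect_lt(abs(rec$vco2 / 0.002 - 1), 0.005)
  expect_equal(rec$fge, 0.5)
  expect_identical(rec$n_cycles_used, 7L)
  expect_identical(rec$species, "H_fijiensis")
  # detection matched truth, so FGE equals k / true span exactly
  expect_equal(rec$fge, 7 / (7 * 120 / 60))
})

test_that("records lacking the required cycles are excluded with a flag", {
  # only ~4 cycles fit in a short window
  sim <- simulate_trace(trace_sim_params(duration = 900, settle_in = 120,
                                         settle_out = 120,
                                         cycle_period = 150))
  rec <- measure_bee(sim$trace, sim$baselines, quick_opts())
  expect_true(is.na(rec$vco2))
  expect_match(rec$qc_flags, "insufficient-cycles")
  # opting in accepts >= accept_min cycles with a flag
  rec2 <- measure_bee(sim$trace, sim$baselines,
                      quick_opts(require_k = FALSE))
  expect_false(is.na(rec2$vco2))
  expect_match(rec2$qc_flags, "fewer-cycles")
  expect_lt(abs(rec2$vco2 / 0.002 - 1), 0.01)
})

test_that("batches of chambers produce one trait record per recording", {
  recs <- lapply(1:3, function(i) {
    sim <- simulate_trace(quick_trace_params(seed = i))
    c(sim[c("trace", "baselines")], list(species = "sp", site_id = "S01"))
  })
  out <- measure_batch(recs, quick_opts())
  expect_identical(nrow(out), 3L)
  expect_true(all(abs(out$vco2 / 0.002 - 1) < 0.005))
})

test_that("measurement is deterministic for identical inputs", {
  sim <- simulate_trace(trace_sim_params(noise_sd = 2, seed = 5))
  expect_identical(measure_bee(sim$trace, sim$baselines),
                   measure_bee(sim$trace, sim$baselines))
})
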