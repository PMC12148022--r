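# Shared fixtures: small, fast simulated recordings and trait tables.

# a short noiseless recording: 25-min measurement, 2-min settling margins,
# 120 s cycles -> 10+ complete cycles inside the analysis window
quick_trace_params <- function(...) {
  args <- utils::modifyList(
    list(duration = 1500, settle_in = 120, settle_out = 120,
         noise_sd = 0, drift_slope = 0.05),
    list(...))
  do.call(trace_sim_params, args)
}

quick_opts <- function(...) {
  resp_opts(settle_in = 120, settle_out = 120, ...)
}

# a constant-concentration trace with a known flat baseline, for
# closed-form checks of the respirometry arithmetic
constant_trace <- function(fe_ppm, fi_ppm, flow = 100, n = 600) {
  trace <- resp_trace(time = seq_len(n) - 1, co2 = rep(fe_ppm, n),
                      flow_rate_stp = flow)
  baselines <- baseline_pair(
    pre = data.frame(time_s = -120:-60, co2_ppm = fi_ppm),
    post = data.frame(time_s = (n + 60):(n + 120), co2_ppm = fi_ppm))
  list(trace = trace, baselines = baselines,
       drift = fit_baseline_drift(baselines))
}

# small but estimable trait table: 8 sites x 12 bees
quick_trait_params <- function(...) {
  trait_sim_params(n_sites = 8, n_dry = 5, n_per_site = 12, ...)
}
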