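#' Parameters for the respirometry trace simulator
#'
#' Bundles and validates the settings of [simulate_trace()]. Defaults
#' describe one bee in a 100 ml min^-1 flow-through system sampled at 1 Hz
#' for 60 min, emitting 0.002 ml CO2 min^-1 in discontinuous gas-exchange
#' cycles of 120 s (one burst per cycle, 30% duty cycle), with 2 min
#' empty-chamber baseline segments before and after the measurement.
#'
#' @param true_vco2 Ground-truth rate of CO2 production, ml CO2 min^-1.
#' @param cycle_period Gas-exchange cycle period, s.
#' @param burst_fraction Fraction of each cycle spent with spiracles open,
#'   in (0, 1).
#' @param flow_rate Flow rate through the chamber at STP, ml min^-1.
#' @param baseline_start_ppm Incurrent CO2 concentration at t = 0, ppm.
#' @param drift_slope Linear analyser drift, ppm min^-1.
#' @param noise_sd SD of additive Gaussian measurement noise, ppm.
#' @param washout_tau First-order chamber washout (mixing) constant, s.
#' @param duration Length of the animal measurement window, s.
#' @param settle_in,settle_out Settling periods at the start/end of the
#'   measurement window that downstream analysis discards, s.
#' @param sample_rate Sampling rate, Hz.
#' @param baseline_len Length of each empty-chamber baseline segment, s.
#' @param cycle_jitter_sd SD of Gaussian jitter on individual cycle
#'   periods, s (0 = perfectly periodic; realistic magnitude unknown).
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return An object of class `trace_sim_params` (a validated list).
#' @export
trace_sim_params <- function(true_vco2 = 0.002,
                             cycle_period = 120,
                             burst_fraction = 0.3,
                             flow_rate = 100,
                             baseline_start_ppm = 10,
                             drift_slope = 0.05,
                             noise_sd = 0,
                             washout_tau = 15,
                             duration = 3600,
                             settle_in = 600,
                             settle_out = 600,
                             sample_rate = 1,
                             baseline_len = 120,
                             cycle_jitter_sd = 0,
                             seed = NULL) {
  p <- list(true_vco2 = true_vco2, cycle_period = cycle_period,
            burst_fraction = burst_fraction, flow_rate = flow_rate,
            baseline_start_ppm = baseline_start_ppm,
            drift_slope = drift_slope, noise_sd = noise_sd,
            washout_tau = washout_tau, duration = duration,
            settle_in = settle_in, settle_out = settle_out,
            sample_rate = sample_rate, baseline_len = baseline_len,
            cycle_jitter_sd = cycle_jitter_sd, seed = seed)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(p$true_vco2) || p$true_vco2 < 0)
    stop_field("true_vco2", "must be a single number >= 0")
  if (!num1(p$cycle_period) || p$cycle_period <= 0)
    stop_field("cycle_period", "must be > 0")
  if (!num1(p$burst_fraction) || p$burst_fraction <= 0 ||
      p$burst_fraction >= 1)
    stop_field("burst_fraction", "must lie strictly between 0 and 1")
  if (!num1(p$flow_rate) || p$flow_rate <= 0)
    stop_field("flow_rate", "must be > 0")
  if (!num1(p$noise_sd) || p$noise_sd < 0)
    stop_field("noise_sd", "must be >= 0")
  if (!num1(p$washout_tau) || p$washout_tau <= 0)
    stop_field("washout_tau", "must be > 0")
  if (!num1(p$sample_rate) || p$sample_rate <= 0)
    stop_field("sample_rate", "must be > 0")
  if (!num1(p$duration) || p$duration <= p$settle_in + p$settle_out)
    stop_field("duration", "must exceed settle_in + settle_out")
  if (!num1(p$baseline_len) || p$baseline_len < 30)
    stop_field("baseline_len", "must be >= 30 s")
  if (!num1(p$cycle_jitter_sd) || p$cycle_jitter_sd < 0)
    stop_field("cycle_jitter_sd", "must be >= 0")
  structure(p, class = "trace_sim_params")
}

# Total burst-covered time in [0, t] for each t, given sorted
# non-overlapping burst intervals. Piecewise-linear exact coverage.
.burst_coverage <- function(t, starts, ends) {
  if (!length(starts)) return(numeric(length(t)))
  bounds <- as.vector(rbind(starts, ends))      # s1 e1 s2 e2 ...
  lens <- ends - starts
  cum_at_start <- c(0, cumsum(lens))[seq_along(starts)]
  cov_at_bound <- as.vector(rbind(cum_at_start, cum_at_start + lens))
  i <- findInterval(t, bounds)
  out <- numeric(length(t))
  pos <- i > 0
  out[pos] <- cov_at_bound[i[pos]]
  inside <- pos & (i %% 2 == 1)                 # between a start and its end
  out[inside] <- cum_at_start[(i[inside] + 1) / 2] +
    (t[inside] - bounds[i[inside]])
  out
}

#' Simulate a flow-through respirometry CO2 trace with known ground truth
#'
#' Generates a full recording: an empty-chamber baseline segment, a
#' measurement window during which a simulated bee emits CO2 in
#' square-wave spiracle-opening bursts smoothed by first-order chamber
#' washout, and a closing baseline segment. The incurrent (baseline) CO2
#' concentration drifts linearly; Gaussian noise is added last.
#'
#' Mass balance is built in: before noise, the excess CO2 above the
#' drifting baseline, integrated over the record and multiplied by the
#' flow rate, equals `true_vco2` times the elapsed measurement time
#' (washout only redistributes CO2 in time; a small tail, of order
#' `washout_tau` times the final excess fraction, leaves the record).
#'
#' @param params A [trace_sim_params()] object (or a list of arguments
#'   for it).
#' @return A list with components
#'   \describe{
#'     \item{trace}{[resp_trace()] covering the measurement window.}
#'     \item{baselines}{[baseline_pair()] with the pre/post segments.}
#'     \item{truth}{List: `true_vco2`, `true_cycle_period`, `true_fge`
#'       (cycles min^-1), `burst_starts`, `burst_ends` (s, on the
#'       recording clock), and the parameters used.}
#'   }
#' @examples
#' sim <- simulate_trace(trace_sim_params(duration = 1500, seed = 1))
#' sim$truth$true_fge
#' @export
simulate_trace <- function(params = trace_sim_params()) {
  if (!inherits(params, "trace_sim_params")) {
    params <- do.call(trace_sim_params, as.list(params))
  }
  with_seed(params$seed, {
    p <- params
    dt <- 1 / p$sample_rate
    n_base <- round(p$baseline_len * p$sample_rate)
    n_meas <- round(p$duration * p$sample_rate)
    n_tot <- 2L * n_base + n_meas
    time <- (seq_len(n_tot) - 1L) * dt
    meas_start <- n_base * dt
    meas_end <- meas_start + n_meas * dt

    # burst schedule on the recording clock; bursts confined to measurement
    n_cycles_max <- ceiling(p$duration / p$cycle_period) + 1L
    periods <- rep(p$cycle_period, n_cycles_max)
    if (p$cycle_jitter_sd > 0) {
      periods <- pmax(periods + rnorm(n_cycles_max, 0, p$cycle_jitter_sd),
                      p$cycle_period * 0.2)
    }
    starts <- meas_start + cumsum(c(0, periods[-n_cycles_max]))
    ends <- starts + p$burst_fraction * periods
    keep <- starts < meas_end
    starts <- starts[keep]
    ends <- pmin(ends[keep], meas_end)

    # emission as a fractional concentration source; exact first-order
    # washout update with the burst occupancy of each sampling interval
    u_burst <- if (p$true_vco2 > 0) {
      (p$true_vco2 / p$burst_fraction) / p$flow_rate
    } else 0
    cov_t <- .burst_coverage(c(time, n_tot * dt), starts, ends)
    occupancy <- diff(cov_t) / dt               # in [0, 1] per interval
    u <- u_burst * occupancy
    a <- exp(-dt / p$washout_tau)
    x <- stats::filter((1 - a) * u, filter = a, method = "recursive")
    x <- c(0, as.numeric(x)[-n_tot])            # x[k] = state at time[k]
    x[time >= meas_end] <- 0                    # bee removed for post baseline

    baseline_ppm <- p$baseline_start_ppm + p$drift_slope * time / 60
    co2 <- baseline_ppm + x * 1e6
    if (p$noise_sd > 0) co2 <- co2 + rnorm(n_tot, 0, p$noise_sd)

    pre_idx <- time < meas_start
    post_idx <- time >= meas_end
    meas_idx <- !pre_idx & !post_idx

    trace <- resp_trace(time = time[meas_idx], co2 = co2[meas_idx],
                        flow_rate_stp = p$flow_rate)
    baselines <- baseline_pair(
      pre = data.frame(time_s = time[pre_idx], co2_ppm = co2[pre_idx]),
      post = data.frame(time_s = time[post_idx], co2_ppm = co2[post_idx]))
    mean_period <- mean(diff(starts))
    if (!is.finite(mean_period)) mean_period <- p$cycle_period
    truth <- list(true_vco2 = p$true_vco2,
                  true_cycle_period = mean_period,
                  true_fge = 60 / mean_period,
                  burst_starts = starts,
                  burst_ends = ends,
                  params = p)
    list(trace = trace, baselines = baselines, truth = truth)
  })
}
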