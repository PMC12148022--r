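#' Respirometry trace object
#'
#' One chamber's recording: a strictly increasing time base (nominally
#' 1 Hz) and the excurrent CO2 concentration in ppm, together with the
#' STP-corrected flow rate and identifiers used as random-effect levels
#' downstream.
#'
#' @param time Sample times, s; strictly increasing.
#' @param co2 CO2 concentration of the excurrent air, ppm; finite.
#' @param flow_rate_stp Flow rate corrected to STP, ml min^-1 (> 0); see
#'   [flow_to_stp()].
#' @param chamber_id,block_id,channel_id Optional identifiers.
#' @param qc_flags Character vector of quality-control flags.
#' @return An object of class `resp_trace`.
#' @export
resp_trace <- function(time, co2, flow_rate_stp, chamber_id = NA,
                       block_id = NA, channel_id = NA,
                       qc_flags = character()) {
  if (length(time) != length(co2))
    stop_field("co2", "must have the same length as 'time'")
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    bad <- which(!is.finite(time) | c(FALSE, diff(time) <= 0))[1]
    stop(sprintf("time must be finite and strictly increasing; first offending row: %d",
                 bad), call. = FALSE)
  }
  if (any(!is.finite(co2))) stop_field("co2", "must be finite")
  if (!is.numeric(flow_rate_stp) || length(flow_rate_stp) != 1L ||
      !is.finite(flow_rate_stp) || flow_rate_stp <= 0)
    stop_field("flow_rate_stp", "must be a single number > 0")
  structure(list(time = as.numeric(time), co2 = as.numeric(co2),
                 flow_rate_stp = flow_rate_stp, chamber_id = chamber_id,
                 block_id = block_id, channel_id = channel_id,
                 qc_flags = qc_flags),
            class = "resp_trace")
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace> %d samples, %.1f-%.1f s, FR(STP) %.4g ml/min",
              length(x$time), min(x$time), max(x$time), x$flow_rate_stp))
  if (length(x$qc_flags)) cat("  [", paste(x$qc_flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Pre/post empty-chamber baseline segments
#'
#' The incurrent CO2 concentration is recorded with an empty chamber
#' before and after each animal measurement; these two segments anchor
#' the linear drift correction of [fit_baseline_drift()].
#'
#' @param pre,post Data frames with columns `time_s` and `co2_ppm`; each
#'   must span at least 30 s and `post` must start after `pre` ends.
#' @return An object of class `baseline_pair`.
#' @export
baseline_pair <- function(pre, post) {
  chk <- function(seg, nm) {
    if (!is.data.frame(seg) || !all(c("time_s", "co2_ppm") %in% names(seg)))
      stop_field(nm, "must be a data frame with columns time_s, co2_ppm")
    if (nrow(seg) < 2L || diff(range(seg$time_s)) < 30)
      stop_field(nm, "must span at least 30 s of samples")
  }
  chk(pre, "pre"); chk(post, "post")
  if (min(post$time_s) <= max(pre$time_s))
    stop_field("post", "must start after 'pre' ends")
  structure(list(pre = pre, post = post), class = "baseline_pair")
}

#' Correct a volumetric flow rate to STP with water-vapour dilution
#'
#' Converts a flow measured at ambient temperature and pressure to
#' standard temperature and pressure (0 degC, 101.3 kPa), discounting the
#' fraction of the stream that is water vapour:
#' \deqn{FR_{STP} = FR \cdot \frac{273.15}{273.15 + T} \cdot
#'   \frac{P}{101.3} \cdot (1 - f_{H_2O})}
#'
#' @param flow_measured Measured volumetric flow, ml min^-1.
#' @param temp_amb Ambient temperature, degC.
#' @param pressure_amb Ambient barometric pressure, kPa.
#' @param f_h2o Fractional water-vapour content of the stream, in [0, 1).
#' @return Flow rate at STP, ml min^-1.
#' @examples
#' flow_to_stp(100, 25, 101.3, 0)  # ~91.61
#' @export
flow_to_stp <- function(flow_measured, temp_amb = 0, pressure_amb = 101.3,
                        f_h2o = 0) {
  if (any(pressure_amb <= 0)) stop_field("pressure_amb", "must be > 0")
  if (any(temp_amb <= -273.15)) stop_field("temp_amb", "must exceed -273.15")
  if (any(f_h2o < 0 | f_h2o >= 1))
    stop_field("f_h2o", "must lie in [0, 1)")
  flow_measured * (273.15 / (273.15 + temp_amb)) *
    (pressure_amb / 101.3) * (1 - f_h2o)
}

#' Fit the linear analyser-drift model to the baseline segments
#'
#' Ordinary least squares of CO2 (ppm) on time (s) through the pooled
#' pre + post empty-chamber samples. The fitted line estimates the
#' incurrent CO2 concentration Fi(t) at any time during the recording.
#'
#' @param baselines A [baseline_pair()].
#' @return An object of class `drift_model` with fields `intercept` (ppm),
#'   `slope` (ppm s^-1) and `fi_of(t)`, a function returning the
#'   *fractional* incurrent concentration (ppm x 1e-6) at time `t`.
#' @export
fit_baseline_drift <- function(baselines) {
  if (!inherits(baselines, "baseline_pair"))
    stop_field("baselines", "must be a baseline_pair")
  dat <- rbind(baselines$pre, baselines$post)
  if (length(unique(dat$time_s)) < 2L)
    stop("singular drift fit: baseline samples share a single time",
         call. = FALSE)
  fit <- lm(co2_ppm ~ time_s, data = dat)
  b <- coef(fit)
  intercept <- unname(b[1]); slope <- unname(b[2])
  structure(list(intercept = intercept, slope = slope,
                 fi_of = function(t) (intercept + slope * t) * 1e-6),
            class = "drift_model")
}

#' Discard the settling-in/out periods of a measurement window
#'
#' The animal disturbs the trace while settling after chamber loading and
#' before removal; those margins are cut, preserving original timestamps.
#'
#' @param trace A [resp_trace()].
#' @param settle_in,settle_out Margins to discard at the start/end, s.
#' @return The interior `resp_trace`.
#' @export
trim_settling <- function(trace, settle_in = 600, settle_out = 600) {
  if (!inherits(trace, "resp_trace")) stop_field("trace", "must be a resp_trace")
  span <- diff(range(trace$time))
  if (span <= settle_in + settle_out)
    stop(sprintf("trace spans %.1f s; cannot trim %g + %g s of settling",
                 span, settle_in, settle_out), call. = FALSE)
  lo <- min(trace$time) + settle_in
  hi <- max(trace$time) - settle_out
  keep <- trace$time >= lo & trace$time <= hi
  out <- trace
  out$time <- trace$time[keep]
  out$co2 <- trace$co2[keep]
  out
}

#' Options for cycle detection and trait derivation
#'
#' All detection constants in one place. The burst threshold is
#' `max(mad_mult x MAD of interburst residuals, excess_frac x 95th
#' percentile of the baseline-subtracted smoothed signal)`; a burst ends
#' when the signal falls below half the entry threshold (hysteresis).
#'
#' @param smooth_s Width of the centred moving-mean smoother, s.
#' @param min_burst_s Minimum burst duration, s.
#' @param min_interburst_s Bursts separated by less than this are merged, s.
#' @param mad_mult Multiplier on the MAD of interburst residuals.
#' @param excess_frac Fraction of the 95th-percentile excess used as the
#'   alternative threshold floor.
#' @param min_amplitude_ppm Smallest 95th-percentile excess (ppm) treated
#'   as a real gas-exchange signal; traces below it are classed as
#'   showing no discontinuous gas exchange. Default 1 ppm, on the order
#'   of an infrared CO2 analyser's noise floor.
#' @param k Number of complete gas-exchange cycles to measure over.
#' @param require_k If `TRUE` (default) records with fewer than `k`
#'   complete cycles are excluded (flagged); if `FALSE`, records with at
#'   least `accept_min` cycles are retained with a qc flag.
#' @param accept_min Minimum cycles accepted when `require_k = FALSE`.
#' @param settle_in,settle_out Settling margins passed to [trim_settling()], s.
#' @param fge_mode `"period"` (default) measures the frequency span from
#'   the start of burst 1 to the start of burst `k + 1` when one exists
#'   (an unbiased cycle period), falling back to `"span"`; `"span"`
#'   always uses start of burst 1 to end of burst `k` (the strict
#'   first-breath-to-end-of-seventh-breath reading).
#' @return A list of class `resp_opts`.
#' @export
resp_opts <- function(smooth_s = 5, min_burst_s = 5, min_interburst_s = 10,
                      mad_mult = 3, excess_frac = 0.10,
                      min_amplitude_ppm = 1, k = 7,
                      require_k = TRUE, accept_min = 3,
                      settle_in = 600, settle_out = 600,
                      fge_mode = c("period", "span")) {
  structure(list(smooth_s = smooth_s, min_burst_s = min_burst_s,
                 min_interburst_s = min_interburst_s, mad_mult = mad_mult,
                 excess_frac = excess_frac,
                 min_amplitude_ppm = min_amplitude_ppm, k = k,
                 require_k = require_k,
                 accept_min = accept_min, settle_in = settle_in,
                 settle_out = settle_out,
                 fge_mode = match.arg(fge_mode)),
            class = "resp_opts")
}

.moving_mean <- function(x, width) {
  if (width <= 1L) return(x)
  w <- rep(1 / width, width)
  sm <- stats::filter(x, w, sides = 2)
  sm <- as.numeric(sm)
  # shrink the window at the edges instead of returning NA
  half <- (width - 1L) %/% 2L
  n <- length(x)
  for (i in which(is.na(sm))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] <- mean(x[lo:hi])
  }
  sm
}

#' Detect discontinuous gas-exchange cycles in a trimmed trace
#'
#' Subtracts the drifting baseline, smooths with a centred moving mean,
#' and marks bursts as maximal runs above a robust threshold (with
#' hysteresis exit at half the entry threshold). Cycles run from each
#' burst start to the next burst start; `n_complete` counts cycles whose
#' full extent lies inside the analysis window.
#'
#' @param trace A trimmed [resp_trace()].
#' @param drift A [fit_baseline_drift()] model.
#' @param opts A [resp_opts()] list.
#' @return An object of class `cycle_set`: `bursts` (data frame
#'   `start_s`/`end_s`), `cycles` (data frame `cycle_start_s`/
#'   `cycle_end_s`), `n_complete`, `threshold_ppm` and `qc_flags`
#'   (contains `"no DGC"` when nothing was detected -- not an error, so
#'   callers can exclude the record).
#' @export
detect_cycles <- function(trace, drift, opts = resp_opts()) {
  if (!inherits(trace, "resp_trace")) stop_field("trace", "must be a resp_trace")
  if (!inherits(drift, "drift_model")) stop_field("drift", "must be a drift_model")
  t <- trace$time
  dt <- median(diff(t))
  excess <- trace$co2 - drift$fi_of(t) * 1e6
  width <- max(1L, round(opts$smooth_s / dt))
  if (width %% 2L == 0L) width <- width + 1L
  sm <- .moving_mean(excess, width)

  p95 <- as.numeric(quantile(sm, 0.95, names = FALSE))
  thr0 <- opts$excess_frac * p95
  no_dgc <- function() {
    structure(list(bursts = data.frame(start_s = numeric(), end_s = numeric()),
                   cycles = data.frame(cycle_start_s = numeric(),
                                       cycle_end_s = numeric()),
                   n_complete = 0L, threshold_ppm = NA_real_,
                   qc_flags = "no DGC"),
              class = "cycle_set")
  }
  if (!is.finite(thr0) || p95 <= opts$min_amplitude_ppm) return(no_dgc())
  interburst <- sm < thr0
  mad_ib <- if (any(interburst)) mad(sm[interburst]) else 0
  thr <- max(opts$mad_mult * mad_ib, thr0)
  exit_thr <- thr / 2

  above_exit <- sm >= exit_thr
  r <- rle(above_exit)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- data.frame(start = starts_i[r$values], end = ends_i[r$values])
  if (nrow(runs)) {
    # keep only runs that actually cross the entry threshold
    hit <- vapply(seq_len(nrow(runs)), function(i)
      any(sm[runs$start[i]:runs$end[i]] >= thr), logical(1))
    runs <- runs[hit, , drop = FALSE]
  }
  if (!nrow(runs)) return(no_dgc())

  # merge bursts separated by less than min_interburst_s
  if (nrow(runs) > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- (t[runs$start[i]] - t[merged$end[nrow(merged)]])
      if (gap < opts$min_interburst_s) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  # minimum duration applies to time spent above the *entry* threshold,
  # so noise blips that merely graze it are rejected
  above_entry <- vapply(seq_len(nrow(runs)), function(i)
    sum(sm[runs$start[i]:runs$end[i]] >= thr) * dt, numeric(1))
  runs <- runs[above_entry >= opts$min_burst_s, , drop = FALSE]
  if (!nrow(runs)) return(no_dgc())

  bursts <- data.frame(start_s = t[runs$start], end_s = t[runs$end])
  # a burst already under way at the window edge is a partial breath:
  # its onset latency differs from interior bursts, so drop it
  if (nrow(bursts) && bursts$start_s[1] <= min(t) + opts$smooth_s) {
    bursts <- bursts[-1, , drop = FALSE]
  }
  if (!nrow(bursts)) return(no_dgc())
  nb <- nrow(bursts)
  cycles <- if (nb >= 2L) {
    data.frame(cycle_start_s = bursts$start_s[-nb],
               cycle_end_s = bursts$start_s[-1])
  } else {
    data.frame(cycle_start_s = numeric(), cycle_end_s = numeric())
  }
  lo <- min(t); hi <- max(t)
  n_complete <- sum(cycles$cycle_start_s >= lo & cycles$cycle_end_s <= hi)
  structure(list(bursts = bursts, cycles = cycles,
                 n_complete = as.integer(n_complete), threshold_ppm = thr,
                 qc_flags = character()),
            class = "cycle_set")
}

#' Rate of CO2 production over a window (flow-through respirometry)
#'
#' Pointwise \deqn{\dot V_{CO_2}(t) = FR \cdot
#'   \frac{Fe_{CO_2}(t) - Fi_{CO_2}(t)}{1 - Fe_{CO_2}(t)}}
#' with `Fe` the fractional excurrent concentration (trace ppm x 1e-6),
#' `Fi` the drift-model incurrent concentration and `FR` the STP flow
#' rate; the window average is returned. Negative instantaneous values
#' are retained (clipping would bias the mean upward); only a negative
#' window mean is flagged via a warning.
#'
#' @param trace A [resp_trace()].
#' @param drift A [fit_baseline_drift()] model.
#' @param window Numeric `c(start_s, end_s)` inside the trace.
#' @return Mean V̇CO2 over the window, ml CO2 min^-1.
#' @export
compute_vco2 <- function(trace, drift, window = range(trace$time)) {
  if (!inherits(trace, "resp_trace")) stop_field("trace", "must be a resp_trace")
  if (!inherits(drift, "drift_model")) stop_field("drift", "must be a drift_model")
  if (window[1] < min(trace$time) - 1e-9 || window[2] > max(trace$time) + 1e-9)
    stop_field("window", "must lie inside the trace")
  keep <- trace$time >= window[1] & trace$time <= window[2]
  fe <- trace$co2[keep] * 1e-6
  if (any(fe >= 1)) stop_field("co2", "fractional Fe must be < 1")
  fi <- drift$fi_of(trace$time[keep])
  v <- trace$flow_rate_stp * (fe - fi) / (1 - fe)
  out <- mean(v)
  if (out < 0) warning("negative mean V̇CO2 over window (qc: negative-MR)")
  out
}

#' Frequency of gas exchange from a detected cycle set
#'
#' `FGE = k / span` in cycles min^-1. With `fge_mode = "period"` the span
#' runs from the start of burst 1 to the start of burst `k + 1` when one
#' was detected (so the span is exactly `k` full cycle periods), falling
#' back to the start of burst 1 -> end of burst `k`; `"span"` always uses
#' the latter (the strict "first breath to end of the k-th breath"
#' definition, which omits the final interburst pause).
#'
#' @param cycles A [detect_cycles()] result.
#' @param k Number of cycles to measure over (default 7).
#' @param fge_mode `"period"` or `"span"`; see Details.
#' @return FGE in min^-1, with attribute `span_s` (the span used). `NA`
#'   with a warning when fewer than `k` complete cycles are available.
#' @export
compute_fge <- function(cycles, k = 7, fge_mode = c("period", "span")) {
  fge_mode <- match.arg(fge_mode)
  if (!inherits(cycles, "cycle_set")) stop_field("cycles", "must be a cycle_set")
  nb <- nrow(cycles$bursts)
  if (nb < k) {
    warning(sprintf("only %d bursts detected; need %d cycles (insufficient-cycles)",
                    nb, k))
    return(structure(NA_real_, span_s = NA_real_))
  }
  span <- if (fge_mode == "period" && nb >= k + 1) {
    cycles$bursts$start_s[k + 1] - cycles$bursts$start_s[1]
  } else {
    cycles$bursts$end_s[k] - cycles$bursts$start_s[1]
  }
  structure(k / (span / 60), span_s = span)
}

#' Derive one bee's trait record from its recording
#'
#' Composes the full trace pipeline: trim settling margins, fit the
#' baseline drift model, detect gas-exchange cycles, average V̇CO2 over
#' the first `k` complete cycles, and compute the frequency of gas
#' exchange over the same cycles. Stage problems the field protocol
#' tolerates become qc flags; structural problems raise errors.
#'
#' @param trace A [resp_trace()] covering the full measurement window.
#' @param baselines A [baseline_pair()].
#' @param opts A [resp_opts()] list.
#' @param mass_mg,species,sex,site_id Optional specimen metadata copied
#'   into the record.
#' @return A one-row data frame of class `trait_record`: `vco2`
#'   (ml CO2 min^-1), `fge` (min^-1), `span_used` (s), `n_cycles_used`,
#'   specimen metadata, ids, and `qc_flags` (semicolon-separated).
#' @export
measure_bee <- function(trace, baselines, opts = resp_opts(),
                        mass_mg = NA_real_, species = NA_character_,
                        sex = NA_character_, site_id = NA_character_) {
  trimmed <- trim_settling(trace, opts$settle_in, opts$settle_out)
  drift <- fit_baseline_drift(baselines)
  cs <- detect_cycles(trimmed, drift, opts)
  flags <- c(trace$qc_flags, cs$qc_flags)
  vco2 <- NA_real_; fge <- NA_real_; span <- NA_real_; n_used <- 0L

  k_eff <- opts$k
  if (cs$n_complete < opts$k) {
    if (!opts$require_k && cs$n_complete >= opts$accept_min) {
      k_eff <- cs$n_complete
      flags <- c(flags, sprintf("fewer-cycles:%d", k_eff))
    } else if (!"no DGC" %in% flags) {
      flags <- c(flags, "insufficient-cycles")
      k_eff <- 0L
    } else k_eff <- 0L
  }
  if (k_eff >= 1L) {
    w <- c(cs$cycles$cycle_start_s[1], cs$cycles$cycle_end_s[k_eff])
    vco2 <- withCallingHandlers(
      compute_vco2(trimmed, drift, w),
      warning = function(wrn) {
        flags <<- c(flags, "negative-MR")
        invokeRestart("muffleWarning")
      })
    fge <- suppressWarnings(compute_fge(cs, k_eff, opts$fge_mode))
    span <- attr(fge, "span_s")
    fge <- as.numeric(fge)
    n_used <- k_eff
  }
  out <- data.frame(vco2 = vco2, fge = fge, span_used = span,
                    n_cycles_used = as.integer(n_used), mass_mg = mass_mg,
                    species = species, sex = sex, site_id = site_id,
                    block_id = trace$block_id, channel_id = trace$channel_id,
                    qc_flags = paste(unique(flags), collapse = ";"),
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_record", class(out))
  out
}

#' Process a batch of recordings into a trait table
#'
#' @param recordings A list whose elements each contain `trace` and
#'   `baselines` (as returned by [simulate_trace()] or [load_trace()]),
#'   plus optional `mass_mg`, `species`, `sex`, `site_id`.
#' @param opts A [resp_opts()] list.
#' @return A data frame with one [measure_bee()] row per recording.
#' @export
measure_batch <- function(recordings, opts = resp_opts()) {
  rows <- lapply(recordings, function(r) {
    measure_bee(r$trace, r$baselines, opts,
                mass_mg = r$mass_mg %||% NA_real_,
                species = r$species %||% NA_character_,
                sex = r$sex %||% NA_character_,
                site_id = r$site_id %||% NA_character_)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
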