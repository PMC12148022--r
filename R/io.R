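#' Write a respirometry recording to CSV plus a YAML sidecar
#'
#' The full recording (pre-baseline, measurement, post-baseline) is
#' written as a two-column CSV (`time_s`, `co2_ppm`); flow rate, baseline
#' windows, identifiers and any simulation truth go to `<path>.yml`.
#'
#' @param trace A [resp_trace()] (the measurement window).
#' @param baselines A [baseline_pair()].
#' @param path CSV output path; the sidecar replaces the extension with
#'   `.yml`.
#' @param truth Optional list of ground-truth values (stored verbatim).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, baselines, path, truth = NULL) {
  full <- rbind(baselines$pre,
                data.frame(time_s = trace$time, co2_ppm = trace$co2),
                baselines$post)
  write.csv(full, path, row.names = FALSE)
  meta <- list(
    flow_rate_stp = trace$flow_rate_stp,
    baseline_pre = c(min(baselines$pre$time_s), max(baselines$pre$time_s)),
    baseline_post = c(min(baselines$post$time_s), max(baselines$post$time_s)),
    chamber_id = trace$chamber_id, block_id = trace$block_id,
    channel_id = trace$channel_id)
  if (!is.null(truth)) {
    meta$truth <- truth[setdiff(names(truth), "params")]
  }
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".yml", path)

#' Load a respirometry recording written by [write_trace()]
#'
#' Reads the two-column CSV and its YAML sidecar, splits the record into
#' the measurement-window trace and the pre/post baseline segments, and
#' applies basic quality control: non-monotone timestamps are an error
#' naming the first offending row; sampling gaps longer than `gap_s`
#' add a `"gap"` qc flag.
#'
#' @param path CSV path.
#' @param meta Optional metadata list (defaults to the YAML sidecar).
#' @param gap_s Gap threshold, s.
#' @return A list with `trace` ([resp_trace()]), `baselines`
#'   ([baseline_pair()]) and `truth` (list or `NULL`).
#' @export
load_trace <- function(path, meta = NULL, gap_s = 5) {
  if (!file.exists(path)) stop(sprintf("no such trace file: %s", path),
                               call. = FALSE)
  dat <- read.csv(path)
  if (!all(c("time_s", "co2_ppm") %in% names(dat)) ||
      !is.numeric(dat$time_s) || !is.numeric(dat$co2_ppm)) {
    stop(sprintf("format error: %s must have numeric columns time_s, co2_ppm",
                 path), call. = FALSE)
  }
  bad <- which(c(FALSE, diff(dat$time_s) <= 0))
  if (length(bad)) {
    stop(sprintf("non-monotone time in %s; first offending row: %d",
                 path, bad[1]), call. = FALSE)
  }
  if (is.null(meta)) {
    mp <- sidecar_path(path)
    if (!file.exists(mp)) stop(sprintf("missing metadata sidecar: %s", mp),
                               call. = FALSE)
    meta <- yaml::read_yaml(mp)
  }
  pre_w <- as.numeric(meta$baseline_pre)
  post_w <- as.numeric(meta$baseline_post)
  pre <- dat[dat$time_s >= pre_w[1] & dat$time_s <= pre_w[2], ]
  post <- dat[dat$time_s >= post_w[1] & dat$time_s <= post_w[2], ]
  if (!nrow(pre) || !nrow(post)) {
    stop("baseline error: empty baseline window(s)", call. = FALSE)
  }
  mid <- dat[dat$time_s > pre_w[2] & dat$time_s < post_w[1], ]
  flags <- character()
  if (any(diff(mid$time_s) > gap_s)) flags <- "gap"
  trace <- resp_trace(mid$time_s, mid$co2_ppm,
                      flow_rate_stp = meta$flow_rate_stp,
                      chamber_id = meta$chamber_id %||% NA,
                      block_id = meta$block_id %||% NA,
                      channel_id = meta$channel_id %||% NA,
                      qc_flags = flags)
  list(trace = trace, baselines = baseline_pair(pre, post),
       truth = meta$truth)
}

#' Import a tab-delimited multi-channel acquisition export
#'
#' Wide-format exports hold one time column plus one CO2 column per
#' analyser channel (`time_s`, `ch1` ... `chN`, ppm). Each channel
#' becomes its own recording; the caller supplies the flow rate and
#' baseline windows (shared by all channels).
#'
#' @param path Tab-delimited file path.
#' @param flow_rate_stp STP flow rate applied to every channel, ml min^-1.
#' @param baseline_pre,baseline_post Numeric `c(start_s, end_s)` windows.
#' @param block_id Optional block identifier shared by the channels.
#' @return Named list (one element per channel) of lists with `trace` and
#'   `baselines`, as [load_trace()] returns.
#' @export
read_multichannel <- function(path, flow_rate_stp, baseline_pre,
                              baseline_post, block_id = NA) {
  dat <- read.csv(path, sep = "\t")
  if (!"time_s" %in% names(dat)) {
    stop(sprintf("format error: %s lacks a time_s column", path),
         call. = FALSE)
  }
  chans <- setdiff(names(dat), "time_s")
  out <- lapply(seq_along(chans), function(i) {
    ch <- chans[i]
    seg <- function(w) data.frame(time_s = dat$time_s, co2_ppm = dat[[ch]])[
      dat$time_s >= w[1] & dat$time_s <= w[2], ]
    mid <- dat$time_s > baseline_pre[2] & dat$time_s < baseline_post[1]
    list(trace = resp_trace(dat$time_s[mid], dat[[ch]][mid],
                            flow_rate_stp = flow_rate_stp,
                            block_id = block_id, channel_id = i),
         baselines = baseline_pair(seg(baseline_pre), seg(baseline_post)))
  })
  names(out) <- chans
  out
}
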