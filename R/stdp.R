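#' EPSP onset time
#'
#' Onset is the first time after the stimulus where the voltage exceeds the
#' pre-stimulus baseline mean + 2 baseline SD and stays above that level for
#' at least `sustain_ms` (0.5 ms). Monosynaptic responses should have onset
#' latency below 4 ms; a warning is issued otherwise. No crossing within
#' `search_ms` (10 ms) raises a `no EPSP` error.
#'
#' @param sweep An [epsp_sweep()].
#' @param baseline_window Interval before the stimulus used for baseline
#'   statistics (s relative to `stim_time`; default 50 to 2 ms before).
#' @param sustain_ms Required supra-threshold duration (ms).
#' @param search_ms Search horizon after the stimulus (ms).
#' @return Onset time (s from sweep start).
#' @export
epsp_onset <- function(sweep, baseline_window = c(-0.05, -0.002),
                       sustain_ms = 0.5, search_ms = 10) {
  stopifnot(inherits(sweep, "epsp_sweep"))
  fs <- sweep$sampling_rate
  v <- sweep$voltage
  t <- (seq_along(v) - 1) / fs
  bl <- v[t >= sweep$stim_time + baseline_window[1] &
            t <= sweep$stim_time + baseline_window[2]]
  if (length(bl) < 5) stop("baseline window too short")
  thr <- mean(bl) + 2 * sd(bl)
  i0 <- seconds_to_index(sweep$stim_time, fs)
  i1 <- min(length(v), seconds_to_index(sweep$stim_time + search_ms / 1000, fs))
  k <- max(1L, as.integer(round(sustain_ms / 1000 * fs)))
  seg <- v[i0:i1] > thr
  # first index where the crossing is sustained for k samples
  cross <- NA_integer_
  for (j in which(seg)) {
    if (j + k - 1 <= length(seg) && all(seg[j:(j + k - 1)])) { cross <- j; break }
  }
  if (is.na(cross))
    stop_odplast("odplast_no_epsp", "no EPSP: no sustained threshold crossing within the search window")
  onset <- (i0 + cross - 2) / fs
  if ((onset - sweep$stim_time) * 1000 > 4)
    warning(sprintf("onset latency %.2f ms exceeds 4 ms; response may not be monosynaptic",
                    (onset - sweep$stim_time) * 1000))
  onset
}

#' EPSP initial slope
#'
#' Least-squares linear fit of voltage against time over the first 2 ms from
#' onset; the fitted slope (mV/ms) quantifies monosynaptic strength without
#' contamination by polysynaptic components.
#'
#' @param sweep An [epsp_sweep()].
#' @param onset Onset time (s), e.g. from [epsp_onset()].
#' @param fit_ms Fit window length (ms).
#' @return Initial slope (mV/ms).
#' @export
epsp_slope <- function(sweep, onset, fit_ms = 2) {
  stopifnot(inherits(sweep, "epsp_sweep"))
  fs <- sweep$sampling_rate
  i0 <- seconds_to_index(onset, fs)
  i1 <- seconds_to_index(onset + fit_ms / 1000, fs)
  if (i1 > length(sweep$voltage)) stop("slope window truncated by end of trace")
  tt <- ((i0:i1) - i0) / fs * 1000          # ms
  vv <- sweep$voltage[i0:i1]
  sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
}

#' Build a slope series from EPSP sweeps
#'
#' Applies [epsp_onset()] and [epsp_slope()] to each sweep and returns the
#' time course of initial slopes.
#'
#' @param sweeps List of [epsp_sweep()]s (e.g. from [gen_stdp_sweeps()]).
#' @param pathway Pathway label (`"P1"` or `"P2"`).
#' @return A `slope_series`: data.frame with `times` (min relative to
#'   pairing, strictly increasing) and `slopes` (mV/ms), attribute `pathway`.
#' @export
slope_series <- function(sweeps, pathway = "P1") {
  if (!is.null(sweeps$sweeps)) sweeps <- sweeps$sweeps
  times <- vapply(sweeps, function(s) s$acquisition_time, 0) / 60
  if (any(diff(times) <= 0))
    stop("acquisition times must be strictly increasing")
  slopes <- vapply(sweeps, function(s) epsp_slope(s, epsp_onset(s)), 0)
  structure(data.frame(times = times, slopes = slopes),
            pathway = pathway, class = c("slope_series", "data.frame"))
}

#' Mean baseline EPSP slope
#'
#' Arithmetic mean of the last `n` (default 30) consecutive slopes acquired
#' before the drug-application mark.
#'
#' @param series A `slope_series`.
#' @param n Number of baseline sweeps to average.
#' @param drug_mark Time of drug application (min relative to pairing).
#' @return Baseline slope (mV/ms).
#' @export
baseline_slope <- function(series, n = 30, drug_mark = 0) {
  pre <- series$slopes[series$times < drug_mark]
  if (length(pre) < n)
    stop(sprintf("need at least %d baseline sweeps before the drug mark, have %d",
                 n, length(pre)))
  mean(pre[(length(pre) - n + 1):length(pre)])
}

#' Final plasticity magnitude
#'
#' Expresses the late post-induction response as a percentage of baseline:
#' `100 * mean(slopes in endpoint_window) / baseline`. The default endpoint
#' window is 25-30 min after pairing.
#'
#' @param series A `slope_series`.
#' @param baseline Baseline slope (mV/ms), from [baseline_slope()].
#' @param endpoint_window `(start, end)` in minutes after pairing.
#' @param n_baseline Number of baseline sweeps used (recorded in the result).
#' @return A `plasticity_result`: `baseline_mean`, `final_percent`,
#'   `n_baseline`, `endpoint_window`, `n_endpoint`.
#' @export
plasticity_magnitude <- function(series, baseline, endpoint_window = c(25, 30),
                                 n_baseline = 30) {
  if (baseline <= 0) stop("baseline must be > 0")
  sel <- series$times >= endpoint_window[1] & series$times <= endpoint_window[2]
  if (sum(sel) < 3)
    stop("fewer than 3 sweeps inside the endpoint window")
  structure(list(baseline_mean = baseline,
                 final_percent = 100 * mean(series$slopes[sel]) / baseline,
                 n_baseline = n_baseline,
                 endpoint_window = endpoint_window,
                 n_endpoint = sum(sel)),
            class = "plasticity_result")
}

#' @export
print.plasticity_result <- function(x, ...) {
  cat(sprintf("<plasticity_result> %.1f%% of baseline (baseline %.3f mV/ms, endpoint %g-%g min, n=%d)\n",
              x$final_percent, x$baseline_mean, x$endpoint_window[1],
              x$endpoint_window[2], x$n_endpoint))
  invisible(x)
}

#' End-to-end STDP quantification from raw sweeps
#'
#' @param sweeps List of [epsp_sweep()]s or the list from [gen_stdp_sweeps()].
#' @param n_baseline Baseline sweeps to average.
#' @param endpoint_window `(start, end)` minutes after pairing.
#' @param pathway Pathway label.
#' @return A `plasticity_result`, with the computed `slope_series` attached
#'   as attribute `series`.
#' @export
analyze_stdp <- function(sweeps, n_baseline = 30, endpoint_window = c(25, 30),
                         pathway = "P1") {
  ser <- slope_series(sweeps, pathway)
  bl <- baseline_slope(ser, n = n_baseline)
  res <- plasticity_magnitude(ser, bl, endpoint_window, n_baseline)
  attr(res, "series") <- ser
  res
}
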