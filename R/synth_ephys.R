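#' Ground truth for synthetic Sr2+-desynchronized EPSC recordings
#'
#' Describes the voltage-clamp world the quantal analysis assumes: spontaneous
#' quantal events as a Poisson process over the whole 1500 ms sweep, extra
#' stimulation-evoked events at `evoked_rate` inside the 750-1150 ms evoked
#' window, difference-of-exponentials inward-current kinetics, and Gaussian
#' baseline noise. Event amplitudes are lognormal with the given means and a
#' common coefficient of variation.
#'
#' Defaults are the reference cell used throughout the test suite: 12 pA
#' spontaneous events at 1 Hz, 18 pA evoked events raising the post-window
#' rate to 8 events/s, 2 pA RMS noise, 1 ms (10-90%) rise and 6 ms decay tau.
#'
#' @param spont_rate Spontaneous event rate (events/s, whole sweep).
#' @param evoked_rate Additional evoked event rate within the evoked window
#'   (events/s); the post-window total rate is `spont_rate + evoked_rate`.
#' @param spont_amp_mean,evoked_amp_mean Mean event amplitudes (pA, positive
#'   magnitude of the inward deflection).
#' @param amp_cv Coefficient of variation of event amplitudes.
#' @param rise_ms 10-90% rise time of the event kernel (ms).
#' @param decay_ms Decay time constant of the event kernel (ms).
#' @param noise_rms Baseline Gaussian noise RMS (pA).
#' @param seed Integer seed.
#' @return An `ephys_truth` object.
#' @export
ephys_truth <- function(spont_rate = 1, evoked_rate = 7,
                        spont_amp_mean = 12, evoked_amp_mean = 18,
                        amp_cv = 0.25, rise_ms = 1, decay_ms = 6,
                        noise_rms = 2, seed = 1L) {
  if (spont_rate < 0 || evoked_rate < 0) stop("rates must be >= 0")
  if (spont_amp_mean <= 0 || evoked_amp_mean <= 0) stop("amplitudes must be > 0")
  if (amp_cv < 0 || noise_rms < 0) stop("amp_cv and noise_rms must be >= 0")
  if (rise_ms <= 0 || decay_ms <= rise_ms) stop("need 0 < rise_ms < decay_ms")
  structure(list(spont_rate = spont_rate, evoked_rate = evoked_rate,
                 spont_amp_mean = spont_amp_mean,
                 evoked_amp_mean = evoked_amp_mean, amp_cv = amp_cv,
                 rise_ms = rise_ms, decay_ms = decay_ms,
                 noise_rms = noise_rms, seed = as.integer(seed)),
            class = "ephys_truth")
}

# Difference-of-exponentials conductance shape, unit peak:
#   g(t) = (exp(-t/tau_d) - exp(-t/tau_r)) / gmax, t >= 0.
# tau_r is solved so the 10-90% rise time matches `rise_ms`.
doe_shape <- function(rise_ms, decay_ms) {
  rise_of_taur <- function(tau_r) {
    tpk <- tau_r * decay_ms / (decay_ms - tau_r) * log(decay_ms / tau_r)
    g <- function(t) (exp(-t / decay_ms) - exp(-t / tau_r))
    gmax <- g(tpk)
    t10 <- uniroot(function(t) g(t) - 0.1 * gmax, c(1e-9, tpk))$root
    t90 <- uniroot(function(t) g(t) - 0.9 * gmax, c(t10, tpk))$root
    t90 - t10
  }
  tau_r <- uniroot(function(x) rise_of_taur(x) - rise_ms,
                   c(rise_ms / 20, decay_ms * 0.99))$root
  tpk <- tau_r * decay_ms / (decay_ms - tau_r) * log(decay_ms / tau_r)
  gmax <- exp(-tpk / decay_ms) - exp(-tpk / tau_r)
  list(tau_r = tau_r, tau_d = decay_ms, gmax = gmax, t_peak = tpk)
}

#' Unit-amplitude EPSC kernel sampled at a given rate
#'
#' Difference-of-exponentials inward current, normalized to analytic peak -1,
#' evaluated at sample times `0, 1/fs, ...` for `10 * decay_ms`.
#'
#' @param sampling_rate Sampling rate (Hz).
#' @param rise_ms 10-90% rise time (ms).
#' @param decay_ms Decay time constant (ms).
#' @return Numeric vector of kernel samples (<= 0, min ~ -1).
#' @export
epsc_kernel <- function(sampling_rate, rise_ms = 1, decay_ms = 6) {
  sh <- doe_shape(rise_ms, decay_ms)
  t_ms <- seq(0, 10 * decay_ms, by = 1000 / sampling_rate)
  -(exp(-t_ms / sh$tau_d) - exp(-t_ms / sh$tau_r)) / sh$gmax
}

#' Container for voltage-clamp current sweeps
#'
#' @param sweeps Numeric matrix, sweeps x samples (pA, inward negative).
#' @param sampling_rate Sampling rate (Hz), >= 5 kHz.
#' @param stim_onset Stimulation time from sweep start (s).
#' @param sweep_duration Sweep length (s).
#' @param test_pulse_window `(start, end)` of the seal test pulse (s),
#'   excluded from all analysis.
#' @return A `sweep_set` object.
#' @export
sweep_set <- function(sweeps, sampling_rate, stim_onset = 0.7,
                      sweep_duration = 1.5,
                      test_pulse_window = c(0.01, 0.11)) {
  if (is.vector(sweeps)) sweeps <- matrix(sweeps, nrow = 1)
  stopifnot(is.matrix(sweeps))
  if (sampling_rate < 5000)
    stop("sampling_rate must be >= 5 kHz to resolve ~1 ms rise times")
  if (stim_onset >= sweep_duration) stop("stim_onset must precede sweep end")
  if (test_pulse_window[2] <= test_pulse_window[1] ||
      test_pulse_window[2] > sweep_duration)
    stop("invalid test_pulse_window")
  if (abs(ncol(sweeps) - sampling_rate * sweep_duration) > 1)
    stop("sweep length inconsistent with sampling_rate * sweep_duration")
  structure(list(sweeps = sweeps, sampling_rate = sampling_rate,
                 stim_onset = stim_onset, sweep_duration = sweep_duration,
                 test_pulse_window = test_pulse_window),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples @ %g kHz, stim at %g ms\n",
              nrow(x$sweeps), ncol(x$sweeps), x$sampling_rate / 1000,
              1000 * x$stim_onset))
  invisible(x)
}

#' Generate Sr2+-desynchronized EPSC sweeps with known event log
#'
#' Each 1500 ms sweep carries: Poisson spontaneous events over the whole sweep
#' at `truth$spont_rate`; additional evoked events at `truth$evoked_rate`
#' inside `evoked_window` (default 750-1150 ms, mirroring the analysis
#' post-stimulation window of 400 ms after a 50 ms delay from the 700 ms
#' stimulus); a square seal-test-pulse response in `test_pulse_window`; and
#' Gaussian baseline noise. Event amplitudes are lognormal; all events share
#' the truth kinetics unless a `rise_ms` column is supplied via `events`.
#'
#' @param truth An [ephys_truth()].
#' @param n_sweeps Number of sweeps.
#' @param sampling_rate Sampling rate (Hz), >= 5 kHz.
#' @param stim_onset Stimulus time (s).
#' @param sweep_duration Sweep length (s).
#' @param evoked_window `(start, end)` of the evoked-event window (s).
#' @param test_pulse_window `(start, end)` of the test pulse (s).
#' @param test_pulse_pA Amplitude of the square test-pulse response (pA).
#' @param events Optional data.frame (`sweep`, `time`, `amplitude`, optional
#'   `rise_ms`) of deterministic events to inject instead of drawing the
#'   Poisson processes (rates are ignored when supplied); used for
#'   ground-truth detector tests.
#' @return List with `sweeps` (a [sweep_set()]), `event_log` (data.frame:
#'   `sweep`, `time`, `amplitude`, `rise_time`, `type`), and `truth`.
#' @export
gen_sr_sweeps <- function(truth, n_sweeps = 60, sampling_rate = 10000,
                          stim_onset = 0.7, sweep_duration = 1.5,
                          evoked_window = c(0.75, 1.15),
                          test_pulse_window = c(0.01, 0.11),
                          test_pulse_pA = -50, events = NULL) {
  stopifnot(inherits(truth, "ephys_truth"))
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  if (sampling_rate < 5000) stop("sampling_rate must be >= 5 kHz")
  if (evoked_window[2] > sweep_duration || evoked_window[1] < 0 ||
      evoked_window[2] <= evoked_window[1])
    stop("evoked window must lie within the sweep")

  ns <- as.integer(round(sampling_rate * sweep_duration))
  kern <- epsc_kernel(sampling_rate, truth$rise_ms, truth$decay_ms)
  sdlog <- sqrt(log(1 + truth$amp_cv^2))

  draw_events <- function() {
    logs <- vector("list", n_sweeps)
    for (i in seq_len(n_sweeps)) {
      n_sp <- rpois(1, truth$spont_rate * sweep_duration)
      n_ev <- rpois(1, truth$evoked_rate * diff(evoked_window))
      t_sp <- runif(n_sp, 0, sweep_duration)
      t_ev <- runif(n_ev, evoked_window[1], evoked_window[2])
      a_sp <- rlnorm(n_sp, log(truth$spont_amp_mean) - sdlog^2 / 2, sdlog)
      a_ev <- rlnorm(n_ev, log(truth$evoked_amp_mean) - sdlog^2 / 2, sdlog)
      logs[[i]] <- data.frame(
        sweep = rep(i, n_sp + n_ev),
        time = c(t_sp, t_ev),
        amplitude = c(a_sp, a_ev),
        type = rep(c("spont", "evoked"), c(n_sp, n_ev))
      )
    }
    do.call(rbind, logs)
  }

  build <- function(ev_log) {
    m <- matrix(0, n_sweeps, ns)
    tp <- 1 + round(test_pulse_window * sampling_rate)
    m[, tp[1]:tp[2]] <- test_pulse_pA
    if (nrow(ev_log)) {
      for (r in seq_len(nrow(ev_log))) {
        k <- if (!is.null(ev_log$rise_ms) && !is.na(ev_log$rise_ms[r]) &&
                 ev_log$rise_ms[r] != truth$rise_ms)
          epsc_kernel(sampling_rate, ev_log$rise_ms[r], truth$decay_ms)
        else kern
        i0 <- min(ns, 1 + floor(ev_log$time[r] * sampling_rate))
        idx <- i0:min(ns, i0 + length(k) - 1)
        m[ev_log$sweep[r], idx] <- m[ev_log$sweep[r], idx] +
          ev_log$amplitude[r] * k[seq_along(idx)]
      }
    }
    if (truth$noise_rms > 0)
      m <- m + matrix(rnorm(length(m), 0, truth$noise_rms), nrow(m), ncol(m))
    m
  }

  res <- with_local_seed(derive_seed(truth$seed, "sr"), {
    ev_log <- if (is.null(events)) draw_events() else {
      stopifnot(all(c("sweep", "time", "amplitude") %in% names(events)))
      ev <- events
      if (is.null(ev$type)) ev$type <- "injected"
      ev
    }
    if (nrow(ev_log)) {
      if (any(ev_log$time < 0 | ev_log$time >= sweep_duration))
        stop("event times must lie within the sweep")
      ev_log <- ev_log[order(ev_log$sweep, ev_log$time), , drop = FALSE]
      rownames(ev_log) <- NULL
    }
    list(m = build(ev_log), ev = ev_log)
  })
  rt <- if (nrow(res$ev)) {
    if (!is.null(res$ev$rise_ms)) ifelse(is.na(res$ev$rise_ms), truth$rise_ms,
                                         res$ev$rise_ms)
    else rep(truth$rise_ms, nrow(res$ev))
  } else numeric(0)
  ev_log <- res$ev
  ev_log$rise_time <- rt
  ev_log$rise_ms <- NULL

  list(sweeps = sweep_set(res$m, sampling_rate, stim_onset, sweep_duration,
                          test_pulse_window),
       event_log = ev_log, truth = truth)
}

#' One current-clamp EPSP sweep
#'
#' @param voltage Membrane-potential trace (mV).
#' @param sampling_rate Sampling rate (Hz), >= 5 kHz.
#' @param stim_time Extracellular stimulus time from sweep start (s).
#' @param acquisition_time Sweep time relative to the pairing/drug mark (s);
#'   negative values are baseline sweeps.
#' @return An `epsp_sweep` object.
#' @export
epsp_sweep <- function(voltage, sampling_rate, stim_time,
                       acquisition_time = 0) {
  if (sampling_rate < 5000) stop("sampling_rate must be >= 5 kHz")
  n <- length(voltage)
  if (stim_time < 0 || stim_time >= n / sampling_rate)
    stop("stim_time must lie within the trace")
  structure(list(voltage = as.numeric(voltage), sampling_rate = sampling_rate,
                 stim_time = stim_time, acquisition_time = acquisition_time),
            class = "epsp_sweep")
}

#' Generate a current-clamp EPSP sweep series around a plasticity induction
#'
#' Baseline sweeps are acquired every `interval_s` (20 s) before the pairing
#' mark at time 0, post-induction sweeps afterwards. Each EPSP rises linearly
#' at the target slope for `rise_ms` after a short monosynaptic onset latency
#' (< 4 ms), then decays exponentially. After the pairing the slope is scaled
#' by `post_ratio` (the induced plasticity). Per-sweep multiplicative slope
#' jitter (`slope_jitter_sd`, fraction of the slope) and additive trace noise
#' (`trace_noise_mv`) model biological and recording variability; set both to
#' 0 for noise-free series.
#'
#' @param baseline_slope True baseline initial slope (mV/ms); with the default
#'   3 ms rise this gives EPSP peaks in the 2-10 mV monosynaptic range.
#' @param post_ratio Post/baseline slope ratio (> 0).
#' @param n_baseline Number of baseline sweeps (>= 30).
#' @param n_post Number of post-induction sweeps (90 = 30 min at 20 s).
#' @param slope_jitter_sd Per-sweep slope jitter SD as a fraction of slope.
#' @param trace_noise_mv Additive Gaussian trace noise SD (mV).
#' @param sampling_rate,stim_time,latency_ms,rise_ms,decay_ms,interval_s
#'   Acquisition and EPSP shape parameters.
#' @param rest_mv Resting potential (mV).
#' @param seed Integer seed.
#' @return List with `sweeps` (list of [epsp_sweep()]s) and `truth`
#'   (the arguments, including the implied true final percent `100 * post_ratio`).
#' @export
gen_stdp_sweeps <- function(baseline_slope = 2, post_ratio = 1,
                            n_baseline = 30, n_post = 90,
                            slope_jitter_sd = 0.05, trace_noise_mv = 0.1,
                            sampling_rate = 10000, stim_time = 0.1,
                            latency_ms = 2, rise_ms = 3, decay_ms = 40,
                            interval_s = 20, rest_mv = -65, seed = 1L) {
  if (n_baseline < 30) stop("n_baseline must be >= 30")
  if (post_ratio <= 0) stop("post_ratio must be > 0")
  if (baseline_slope <= 0) stop("baseline_slope must be > 0")
  if (latency_ms >= 4) stop("monosynaptic onset latency must be < 4 ms")

  dur <- 0.5
  ns <- as.integer(sampling_rate * dur)
  tms <- (seq_len(ns) - 1) / sampling_rate * 1000   # ms from sweep start
  onset_ms <- stim_time * 1000 + latency_ms
  rise_seg <- tms >= onset_ms & tms < onset_ms + rise_ms
  decay_seg <- tms >= onset_ms + rise_ms
  shape <- numeric(ns)                              # unit-slope EPSP (mV per mV/ms)
  shape[rise_seg] <- tms[rise_seg] - onset_ms
  shape[decay_seg] <- rise_ms * exp(-(tms[decay_seg] - onset_ms - rise_ms) / decay_ms)

  times <- c(-(n_baseline:1), seq_len(n_post)) * interval_s
  ratio <- c(rep(1, n_baseline), rep(post_ratio, n_post))
  sweeps <- with_local_seed(derive_seed(seed, "stdp"), {
    lapply(seq_along(times), function(i) {
      sl <- baseline_slope * ratio[i] *
        (1 + if (slope_jitter_sd > 0) rnorm(1, 0, slope_jitter_sd) else 0)
      v <- rest_mv + sl * shape
      if (trace_noise_mv > 0) v <- v + rnorm(ns, 0, trace_noise_mv)
      epsp_sweep(v, sampling_rate, stim_time, acquisition_time = times[i])
    })
  })
  list(sweeps = sweeps,
       truth = list(baseline_slope = baseline_slope, post_ratio = post_ratio,
                    true_final_percent = 100 * post_ratio,
                    latency_ms = latency_ms, rise_ms = rise_ms,
                    slope_jitter_sd = slope_jitter_sd,
                    trace_noise_mv = trace_noise_mv, seed = as.integer(seed)))
}
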