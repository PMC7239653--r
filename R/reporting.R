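#' Compare before/after imaging sessions
#'
#' Computes the before-to-after change in ODI and per-eye ROI amplitudes.
#' The two sessions must have been analyzed with identical settings (ROI
#' threshold fraction, smoothing sigma, histogram bins); the ROI itself is
#' derived independently per session, since sessions are imaged on separate
#' days and aligned only approximately.
#'
#' @param before,after `odi_result`s (or `session_analysis` objects) from
#'   [compute_odi()] / [analyze_session()].
#' @param label Free-text condition label.
#' @return A `session_result`: `label`, `before`, `after`, `delta_odi`,
#'   `delta_amp_contra`, `delta_amp_ipsi`.
#' @export
compare_sessions <- function(before, after, label = "") {
  if (inherits(before, "session_analysis")) before <- before$odi
  if (inherits(after, "session_analysis")) after <- after$odi
  stopifnot(inherits(before, "odi_result"), inherits(after, "odi_result"))
  if (!identical(before$settings, after$settings))
    stop("before/after sessions were analyzed with different settings")
  structure(list(label = label, before = before, after = after,
                 delta_odi = after$odi - before$odi,
                 delta_amp_contra = after$amp_contra - before$amp_contra,
                 delta_amp_ipsi = after$amp_ipsi - before$amp_ipsi),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result%s> ODI %.3f -> %.3f (delta %+.3f); dC %+.3f, dI %+.3f (x1e4)\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$before$odi, x$after$odi, x$delta_odi,
              x$delta_amp_contra, x$delta_amp_ipsi))
  invisible(x)
}

#' Group summary of before/after sessions
#'
#' Means and standard errors per metric (ODI, contra amplitude, ipsi
#' amplitude; before and after), plus paired Wilcoxon signed-rank p-values
#' when `n >= 5`. The rank test is a routine statistic reported for
#' transparency only; it is labelled as such in the output.
#'
#' @param sessions List of `session_result`s.
#' @return A `group_summary`: `n`, `metrics` (data.frame with mean/sem before
#'   and after per metric), `p_values` (named list or `NULL` when `n < 5`),
#'   `p_value_note`.
#' @export
summarize_group <- function(sessions) {
  if (!length(sessions)) stop("no sessions to summarize")
  stopifnot(all(vapply(sessions, inherits, TRUE, "session_result")))
  n <- length(sessions)
  get <- function(f) vapply(sessions, f, 0)
  vals <- list(
    odi = cbind(before = get(function(s) s$before$odi),
                after = get(function(s) s$after$odi)),
    amp_contra = cbind(before = get(function(s) s$before$amp_contra),
                       after = get(function(s) s$after$amp_contra)),
    amp_ipsi = cbind(before = get(function(s) s$before$amp_ipsi),
                     after = get(function(s) s$after$amp_ipsi))
  )
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  metrics <- do.call(rbind, lapply(names(vals), function(k) {
    v <- vals[[k]]
    data.frame(metric = k,
               mean_before = mean(v[, "before"]), sem_before = sem(v[, "before"]),
               mean_after = mean(v[, "after"]), sem_after = sem(v[, "after"]))
  }))
  p_values <- NULL
  if (n >= 5) {
    p_values <- lapply(vals, function(v)
      suppressWarnings(wilcox.test(v[, "before"], v[, "after"],
                                   paired = TRUE)$p.value))
  }
  structure(list(n = n, metrics = metrics, p_values = p_values,
                 p_value_note = "routine paired Wilcoxon signed-rank test (wrapper; omitted for n < 5)"),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> n = %d sessions\n", x$n))
  print(x$metrics, row.names = FALSE)
  if (!is.null(x$p_values))
    cat("paired Wilcoxon p:",
        paste(sprintf("%s=%.4g", names(x$p_values), unlist(x$p_values)),
              collapse = ", "), "\n")
  invisible(x)
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    imaging = list(n_sessions = 2, height = 32, width = 32, duration = 50,
                   frame_rate = 10, stim_freq = 0.12, noise_sd = 1e-3,
                   odi_before = 0.30, odi_after = 0.10, amp_sum = 3.8e-4,
                   roi_fraction = 0.3, sigma = 1.0, n_bins = 50),
    quantal = list(n_cells = 3, n_sweeps = 30, sampling_rate = 10000,
                   spont_rate = 1, evoked_rate = 7, spont_amp_mean = 12,
                   evoked_amp_mean = 18, amp_cv = 0.25, noise_rms = 1.5,
                   rms_cutoff = 2, threshold_mult = 3),
    stdp = list(baseline_slope = 2, post_ratios = c(0.6, 1.0, 1.235),
                n_baseline = 30, n_post = 90, slope_jitter_sd = 0.05,
                trace_noise_mv = 0.1, endpoint_window = c(25, 30))
  )
}

merge_config <- function(defaults, cfg) {
  for (k in names(cfg)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(cfg[[k]]))
      merge_config(defaults[[k]], cfg[[k]]) else cfg[[k]]
  }
  defaults
}

#' Run the full simulated measurement pipeline and write report files
#'
#' Executes, with one top-level seed, the three simulated measurement arms:
#' imaging (generate before/after sessions at the configured true ODIs,
#' analyze each, compare, summarize across sessions), quantal EPSC analysis
#' (generate and analyze `n_cells` cells), and STDP (one series per
#' configured `post_ratio`). All outputs are plain CSV/JSON plus a parameter
#' log; reruns with the same config and seed are byte-identical.
#'
#' @param config A configuration list, or path to a JSON file with the same
#'   structure; missing fields take the documented defaults
#'   (see the shipped demo config,
#'   `system.file("extdata", "demo_config.json", package = "odplast")`).
#'   Sections (`imaging`, `quantal`, `stdp`) may be disabled with
#'   `"enabled": false`.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$seed` when non-NULL.
#' @return Invisibly, a list with the in-memory results and the paths written.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(pipeline_defaults(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  results <- list()
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wjson <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <<- c(paths, p)
  }

  enabled <- function(sec) !identical(sec$enabled, FALSE)

  if (enabled(cfg$imaging)) {
    im <- cfg$imaging
    rows <- list(); comps <- list()
    for (i in seq_len(im$n_sessions)) {
      res <- list()
      for (phase in c("before", "after")) {
        tr <- imaging_truth(im$height, im$width,
                            odi = if (phase == "before") im$odi_before else im$odi_after,
                            amp_sum = im$amp_sum, noise_sd = im$noise_sd,
                            seed = derive_seed(cfg$seed, "imaging", i, phase))
        st <- gen_session(tr, im$duration, im$frame_rate, im$stim_freq)
        res[[phase]] <- analyze_session(st, roi_fraction = im$roi_fraction,
                                        sigma = im$sigma, n_bins = im$n_bins)
      }
      comp <- compare_sessions(res$before, res$after,
                               label = sprintf("session_%02d", i))
      comps[[i]] <- comp
      rows[[i]] <- data.frame(
        session = i,
        odi_before = comp$before$odi, odi_after = comp$after$odi,
        delta_odi = comp$delta_odi,
        amp_contra_before = comp$before$amp_contra,
        amp_contra_after = comp$after$amp_contra,
        amp_ipsi_before = comp$before$amp_ipsi,
        amp_ipsi_after = comp$after$amp_ipsi,
        n_pixels_before = comp$before$n_pixels,
        n_pixels_after = comp$after$n_pixels,
        roi_fraction = im$roi_fraction
      )
    }
    wcsv(do.call(rbind, rows), "imaging_sessions.csv")
    grp <- summarize_group(comps)
    wjson(list(n = grp$n, metrics = grp$metrics, p_values = grp$p_values,
               p_value_note = grp$p_value_note), "imaging_group.json")
    results$imaging <- list(sessions = comps, group = grp)
  }

  if (enabled(cfg$quantal)) {
    qu <- cfg$quantal
    rows <- vector("list", qu$n_cells)
    for (i in seq_len(qu$n_cells)) {
      tr <- ephys_truth(spont_rate = qu$spont_rate, evoked_rate = qu$evoked_rate,
                        spont_amp_mean = qu$spont_amp_mean,
                        evoked_amp_mean = qu$evoked_amp_mean,
                        amp_cv = qu$amp_cv, noise_rms = qu$noise_rms,
                        seed = derive_seed(cfg$seed, "quantal", i))
      sim <- gen_sr_sweeps(tr, n_sweeps = qu$n_sweeps,
                           sampling_rate = qu$sampling_rate)
      est <- analyze_cell(sim$sweeps, rms_cutoff = qu$rms_cutoff,
                          threshold_mult = qu$threshold_mult)
      rows[[i]] <- data.frame(
        cell = i, rms = est$rms, included = est$included,
        exclusion_reason = est$exclusion_reason,
        pre_amp = est$pre_amp, pre_freq = est$pre_freq,
        post_amp = est$post_amp, post_freq = est$post_freq,
        evoked_amp = est$evoked_amp, n_events = est$n_events,
        true_evoked_amp = qu$evoked_amp_mean
      )
    }
    cells <- do.call(rbind, rows)
    wcsv(cells, "quantal_cells.csv")
    inc <- cells$included
    wjson(list(n_cells = nrow(cells), n_included = sum(inc),
               mean_evoked_amp = if (any(inc)) mean(cells$evoked_amp[inc]) else NULL,
               true_evoked_amp = qu$evoked_amp_mean),
          "quantal_summary.json")
    results$quantal <- cells
  }

  if (enabled(cfg$stdp)) {
    sp <- cfg$stdp
    rows <- list(); series_rows <- list()
    for (i in seq_along(sp$post_ratios)) {
      r <- sp$post_ratios[i]
      sim <- gen_stdp_sweeps(baseline_slope = sp$baseline_slope, post_ratio = r,
                             n_baseline = sp$n_baseline, n_post = sp$n_post,
                             slope_jitter_sd = sp$slope_jitter_sd,
                             trace_noise_mv = sp$trace_noise_mv,
                             seed = derive_seed(cfg$seed, "stdp", i))
      res <- analyze_stdp(sim$sweeps, n_baseline = sp$n_baseline,
                          endpoint_window = sp$endpoint_window)
      ser <- attr(res, "series")
      series_rows[[i]] <- data.frame(post_ratio = r, times = ser$times,
                                     slopes = ser$slopes)
      rows[[i]] <- data.frame(post_ratio = r,
                              baseline_slope = res$baseline_mean,
                              final_percent = res$final_percent,
                              true_final_percent = 100 * r)
    }
    wcsv(do.call(rbind, series_rows), "stdp_slopes.csv")
    wcsv(do.call(rbind, rows), "stdp_summary.csv")
    results$stdp <- do.call(rbind, rows)
  }

  log_lines <- c(
    sprintf("odplast version: %s", as.character(packageVersion("odplast"))),
    sprintf("seed: %d", cfg$seed),
    "config:",
    strsplit(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), "\n")[[1]]
  )
  log_path <- file.path(out_dir, "pipeline_log.txt")
  writeLines(log_lines, log_path)
  paths <- c(paths, log_path)
  invisible(list(results = results, paths = paths, config = cfg))
}
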