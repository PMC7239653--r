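# Plain-text I/O for the stack and sweep schemas. Widefield rigs typically
# deposit TIFF/HDF5; this environment has no R reader for either, so the same
# schemas (identical sidecar metadata fields) are carried as flat CSV matrices
# plus a JSON sidecar. Readers for binary formats can be slotted in behind the
# same functions without touching the analysis code.

#' Write / read an intrinsic stack as CSV + JSON sidecar
#'
#' The frame data are stored as a T x (H*W) CSV matrix (pixels column-major),
#' with acquisition metadata (`frame_rate_hz`, `stim_freq_hz`, `eye`,
#' `direction_deg`, `height`, `width`) in `<prefix>.json`.
#'
#' @param stack An [intrinsic_stack()].
#' @param prefix Path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return `write_intrinsic_stack` returns the paths invisibly;
#'   `read_intrinsic_stack` returns the [intrinsic_stack()].
#' @export
write_intrinsic_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "intrinsic_stack"))
  d <- dim(stack$frames)
  m <- stack$frames
  dim(m) <- c(d[1], d[2] * d[3])
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  utils::write.table(m, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(frame_rate_hz = stack$frame_rate,
                            stim_freq_hz = stack$stim_freq,
                            eye = stack$eye,
                            direction_deg = stack$direction,
                            height = d[2], width = d[3]),
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' @rdname write_intrinsic_stack
#' @export
read_intrinsic_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.csv(paste0(prefix, ".csv"), header = FALSE))
  dimnames(m) <- NULL
  frames <- array(m, dim = c(nrow(m), meta$height, meta$width))
  intrinsic_stack(frames, meta$frame_rate_hz, meta$stim_freq_hz,
                  meta$eye, as.numeric(meta$direction_deg))
}

#' Write / read a sweep set as CSV + JSON sidecar
#'
#' Sweeps are stored as a sweeps x samples CSV matrix; `sampling_rate_hz`,
#' `stim_onset_s`, `sweep_duration_s` and the test-pulse window go in the
#' JSON sidecar.
#'
#' @param sweeps A [sweep_set()].
#' @param prefix Path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return `write_sweep_set` returns the paths invisibly; `read_sweep_set`
#'   returns the [sweep_set()].
#' @export
write_sweep_set <- function(sweeps, prefix) {
  stopifnot(inherits(sweeps, "sweep_set"))
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  utils::write.table(sweeps$sweeps, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(sampling_rate_hz = sweeps$sampling_rate,
                            stim_onset_s = sweeps$stim_onset,
                            sweep_duration_s = sweeps$sweep_duration,
                            test_pulse_start_s = sweeps$test_pulse_window[1],
                            test_pulse_end_s = sweeps$test_pulse_window[2]),
                       json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- as.matrix(read.csv(paste0(prefix, ".csv"), header = FALSE))
  dimnames(m) <- NULL
  sweep_set(m, meta$sampling_rate_hz, meta$stim_onset_s,
            meta$sweep_duration_s,
            c(meta$test_pulse_start_s, meta$test_pulse_end_s))
}
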