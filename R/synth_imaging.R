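#' Ground truth for a synthetic intrinsic-signal imaging session
#'
#' Describes the "world" a simulated widefield acquisition is drawn from: a
#' binocular zone (elliptical by default) carrying a stimulus-locked
#' reflectance modulation of fractional amplitude ~1e-4 for each eye, zero
#' modulation outside the zone, and additive per-frame Gaussian noise.
#'
#' Amplitudes can be given directly (`amp_contra`/`amp_ipsi`, scalars applied
#' uniformly on the zone or full H x W maps) or via the (`odi`, `amp_sum`)
#' parameterization, where `amp_contra = amp_sum * (1 + odi) / 2` and
#' `amp_ipsi = amp_sum * (1 - odi) / 2`.
#'
#' Defaults mirror a naive adult mouse: contralateral 2.5e-4, ipsilateral
#' 1.3e-4 (ODI ~ 0.32), per-frame fractional noise SD 1e-3 (the shot-noise
#' scale of ~1e6 detected photons per pixel per frame).
#'
#' @param height,width Map geometry in pixels.
#' @param amp_contra,amp_ipsi True fractional modulation amplitude per eye;
#'   scalar (uniform on the zone) or full `height x width` map (>= 0, zero
#'   outside any bounded support you choose).
#' @param odi,amp_sum Alternative parameterization; when `odi` is non-NULL it
#'   overrides `amp_contra`/`amp_ipsi`.
#' @param zone_mask Logical `height x width` binocular-zone mask; default an
#'   ellipse with radii `0.22*height`, `0.28*width` centred on the map.
#' @param noise_sd Additive per-frame noise SD in reflectance units (baseline
#'   reflectance is 1).
#' @param hemo_phase Named numeric, response phase (radians) per drift
#'   direction (`"90"`, `"270"`); magnitudes are phase-invariant downstream.
#' @param seed Integer seed; sub-streams per stack are derived from it.
#' @return An `imaging_truth` object with fields `amp_contra_map`,
#'   `amp_ipsi_map`, `zone_mask`, `true_odi`, `noise_sd`, `hemo_phase`, `seed`.
#' @examples
#' tr <- imaging_truth(32, 32, odi = 0.3, seed = 1)
#' tr$true_odi
#' @export
imaging_truth <- function(height = 64, width = 64,
                          amp_contra = 2.5e-4, amp_ipsi = 1.3e-4,
                          odi = NULL, amp_sum = 3.8e-4,
                          zone_mask = NULL,
                          noise_sd = 1e-3,
                          hemo_phase = c(`90` = 0.8, `270` = 2.2),
                          seed = 1L) {
  if (height < 5 || width < 5) stop("geometry must be at least 5 x 5 pixels")
  if (is.null(zone_mask)) {
    zone_mask <- ellipse_mask(height, width,
                              ry = 0.22 * height, rx = 0.28 * width)
  }
  stopifnot(is.logical(zone_mask), all(dim(zone_mask) == c(height, width)))
  if (!any(zone_mask)) stop("zone_mask is empty")

  if (!is.null(odi)) {
    if (abs(odi) > 1) stop("odi must lie in [-1, 1]")
    amp_contra <- amp_sum * (1 + odi) / 2
    amp_ipsi <- amp_sum * (1 - odi) / 2
  }
  as_map <- function(a) {
    if (length(a) == 1) {
      m <- matrix(0, height, width)
      m[zone_mask] <- a
      m
    } else {
      stopifnot(all(dim(a) == c(height, width)))
      a
    }
  }
  cmap <- as_map(amp_contra)
  imap <- as_map(amp_ipsi)
  if (any(cmap < 0) || any(imap < 0)) stop("amplitude maps must be >= 0")
  s <- cmap[zone_mask] + imap[zone_mask]
  if (any(s <= 0)) stop("amp_contra + amp_ipsi must be > 0 on the zone")
  true_odi <- mean((cmap[zone_mask] - imap[zone_mask]) / s)

  structure(list(
    amp_contra_map = cmap, amp_ipsi_map = imap, zone_mask = zone_mask,
    true_odi = true_odi, noise_sd = noise_sd,
    hemo_phase = hemo_phase, seed = as.integer(seed)
  ), class = "imaging_truth")
}

ellipse_mask <- function(height, width, ry, rx,
                         cy = (height + 1) / 2, cx = (width + 1) / 2) {
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

#' Generate one intrinsic-signal acquisition (one eye, one drift direction)
#'
#' Simulates a widefield reflectance movie under continuous periodic bar-sweep
#' stimulation: per pixel,
#' `R(t) = R0 * (1 + a(x, y) * cos(2 * pi * stim_freq * t + phi)) + eps(t)`
#' with `a` the eye's true amplitude map, `phi` the direction's hemodynamic
#' phase, and `eps` Gaussian with SD `truth$noise_sd`. Baseline `R0 = 1`
#' (arbitrary units; only the fractional modulation matters downstream).
#'
#' The default 0.12 Hz sweep gives 36 integer stimulus cycles in the standard
#' 300 s acquisition, so the response lands exactly on a DFT bin.
#'
#' @param truth An [imaging_truth()] object.
#' @param eye `"contra"` or `"ipsi"`.
#' @param direction Drift direction in degrees, 90 (up) or 270 (down).
#' @param duration Acquisition length (s).
#' @param frame_rate Camera frame rate (Hz); must exceed `2 * stim_freq`.
#' @param stim_freq Bar-sweep temporal frequency (Hz).
#' @return An [intrinsic_stack()] object.
#' @export
gen_intrinsic_stack <- function(truth, eye = c("contra", "ipsi"),
                                direction = 90, duration = 300,
                                frame_rate = 30, stim_freq = 0.12) {
  eye <- match.arg(eye)
  stopifnot(inherits(truth, "imaging_truth"))
  if (duration <= 0 || frame_rate <= 0 || stim_freq <= 0)
    stop("duration, frame_rate and stim_freq must be positive")
  if (duration * stim_freq < 2)
    stop("need at least 2 stimulus cycles (duration * stim_freq >= 2)")
  if (frame_rate <= 2 * stim_freq)
    stop("frame_rate must exceed twice the stimulus frequency")
  if (!as.character(direction) %in% names(truth$hemo_phase))
    stop("no hemo_phase entry for direction ", direction)

  amp <- if (eye == "contra") truth$amp_contra_map else truth$amp_ipsi_map
  nt <- as.integer(round(duration * frame_rate))
  phase <- unname(truth$hemo_phase[as.character(direction)])
  sd_stream <- derive_seed(truth$seed, "stack", eye, direction)
  frames <- gen_stack_cpp(as.numeric(amp), nt, stim_freq / frame_rate,
                          phase, 1.0, truth$noise_sd, sd_stream)
  dim(frames) <- c(nt, nrow(amp), ncol(amp))
  intrinsic_stack(frames, frame_rate = frame_rate, stim_freq = stim_freq,
                  eye = eye, direction = direction)
}

#' Generate a complete four-stack imaging session
#'
#' One session = both eyes x both drift directions (90 and 270 degrees), all
#' sharing geometry, frame rate and stimulus frequency; amplitudes are
#' identical per eye across directions and the phase differs per direction.
#'
#' @inheritParams gen_intrinsic_stack
#' @return A list with elements `stacks` (list of four [intrinsic_stack()]
#'   objects) and `truth`.
#' @export
gen_session <- function(truth, duration = 300, frame_rate = 30,
                        stim_freq = 0.12) {
  grid <- expand.grid(eye = c("contra", "ipsi"), direction = c(90, 270),
                      stringsAsFactors = FALSE)
  stacks <- lapply(seq_len(nrow(grid)), function(i) {
    gen_intrinsic_stack(truth, grid$eye[i], grid$direction[i],
                        duration, frame_rate, stim_freq)
  })
  names(stacks) <- paste0(grid$eye, "_", grid$direction)
  list(stacks = stacks, truth = truth)
}
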