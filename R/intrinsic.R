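#' Intrinsic-signal image stack
#'
#' Container for one widefield acquisition: a T x H x W reflectance array plus
#' the acquisition metadata the Fourier analysis needs.
#'
#' @param frames Numeric T x H x W array, finite and positive.
#' @param frame_rate Camera frame rate (Hz).
#' @param stim_freq Periodic-stimulus frequency (Hz).
#' @param eye `"contra"` or `"ipsi"`.
#' @param direction Drift direction (degrees, 90 or 270).
#' @return An `intrinsic_stack` object.
#' @export
intrinsic_stack <- function(frames, frame_rate, stim_freq,
                            eye = c("contra", "ipsi"), direction = 90) {
  eye <- match.arg(eye)
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (frame_rate <= 0 || stim_freq <= 0)
    stop("frame_rate and stim_freq must be positive")
  nt <- dim(frames)[1]
  if (nt * stim_freq / frame_rate < 2)
    stop("stack spans fewer than 2 stimulus cycles")
  if (!direction %in% c(90, 270)) stop("direction must be 90 or 270")
  structure(list(frames = frames, frame_rate = frame_rate,
                 stim_freq = stim_freq, eye = eye, direction = direction),
            class = "intrinsic_stack")
}

#' @export
print.intrinsic_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<intrinsic_stack> %d frames @ %g Hz, %d x %d px, eye=%s, dir=%d deg, stim %g Hz\n",
              d[1], x$frame_rate, d[2], d[3], x$eye, x$direction, x$stim_freq))
  invisible(x)
}

new_response_map <- function(magnitude, phase, eye, direction = NA,
                             smoothed = FALSE, sigma = NA_real_) {
  structure(list(magnitude = magnitude, phase = phase, eye = eye,
                 direction = direction, smoothed = smoothed, sigma = sigma),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("<response_map> %d x %d px, eye=%s%s, peak %.3f (x1e4)\n",
              nrow(x$magnitude), ncol(x$magnitude), x$eye,
              if (isTRUE(x$smoothed)) ", smoothed" else "",
              max(x$magnitude)))
  invisible(x)
}

#' Per-pixel response magnitude and phase at the stimulus frequency
#'
#' Extracts the cortical response by Fourier analysis: for each pixel's time
#' series `x`, with DFT `X`, the response magnitude is
#' `2 * |X[k]| / X[0] * 1e4` at the DFT bin `k` nearest the stimulus
#' frequency — the fractional reflectance change x 1e4 (the grey-scale
#' convention of intrinsic-signal magnitude maps). A noise-free cosine of
#' fractional amplitude `a` spanning an integer number of cycles maps to
#' exactly `a * 1e4`. The phase map (argument of `X[k]`) is retained but
#' unused by the ocular-dominance pipeline.
#'
#' A warning is emitted when the stimulus frequency falls off-bin by more
#' than 1% of the bin spacing (spectral leakage).
#'
#' @param stack An [intrinsic_stack()].
#' @return A `response_map` with `magnitude` (H x W, >= 0, x 1e4 units),
#'   `phase` (radians), `eye`, `direction`, `smoothed = FALSE`.
#' @export
fourier_response_map <- function(stack) {
  stopifnot(inherits(stack, "intrinsic_stack"))
  d <- dim(stack$frames)
  nt <- d[1]
  if (stack$stim_freq >= stack$frame_rate / 2)
    stop("stimulus frequency at or above Nyquist")
  cycles <- nt * stack$stim_freq / stack$frame_rate
  if (cycles < 2) stop("fewer than 2 stimulus cycles in stack")
  k <- as.integer(round(cycles))         # 0-based DFT bin index
  if (k < 1) stop("stimulus frequency unresolvable at this duration")
  off <- abs(cycles - k)
  if (off > 0.01)
    warning(sprintf("stimulus frequency is %.1f%% off the nearest DFT bin; spectral leakage", 100 * off))

  pr <- dft_bin_cpp(stack$frames, nt, k)
  magnitude <- 2 * sqrt(pr$re^2 + pr$im^2) / pr$x0 * 1e4
  phase <- atan2(pr$im, pr$re)
  dim(magnitude) <- d[2:3]
  dim(phase) <- d[2:3]
  new_response_map(magnitude, phase, stack$eye, stack$direction)
}

#' Average the two drift-direction maps of one eye
#'
#' Pixelwise arithmetic mean of the 90- and 270-degree magnitude maps. The
#' phase maps are dropped: opposite drift directions have unrelated phases and
#' the ocular-dominance pipeline uses magnitudes only.
#'
#' @param map_up,map_down `response_map`s of the same eye and geometry with
#'   directions 90 and 270 (either order).
#' @return A direction-averaged `response_map` (phase `NULL`).
#' @export
average_directions <- function(map_up, map_down) {
  stopifnot(inherits(map_up, "response_map"), inherits(map_down, "response_map"))
  if (!identical(map_up$eye, map_down$eye))
    stop("direction averaging requires maps from the same eye")
  if (!identical(dim(map_up$magnitude), dim(map_down$magnitude)))
    stop("geometry mismatch between direction maps")
  dirs <- sort(c(map_up$direction, map_down$direction))
  if (!identical(as.numeric(dirs), c(90, 270)))
    stop("expected one 90-degree and one 270-degree map")
  new_response_map((map_up$magnitude + map_down$magnitude) / 2,
                   phase = NULL, eye = map_up$eye, direction = NA)
}

# Normalized 1-D Gaussian taps for a (2*half+1)-wide kernel.
gaussian_taps <- function(sigma, half = 2) {
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  w / sum(w)
}

# Separable convolution with half-sample symmetric (edge-repeating) padding;
# this boundary rule conserves the map sum for any symmetric kernel.
conv_sep_reflect <- function(m, taps) {
  half <- (length(taps) - 1) / 2
  n <- nrow(m); p <- ncol(m)
  ridx <- c(half:1, 1:n, n:(n - half + 1))
  cidx <- c(half:1, 1:p, p:(p - half + 1))
  pad <- m[ridx, cidx, drop = FALSE]
  # rows
  out <- matrix(0, n, p + 2 * half)
  for (i in seq_along(taps))
    out <- out + taps[i] * pad[(i - 1) + 1:n, , drop = FALSE]
  # cols
  res <- matrix(0, n, p)
  for (j in seq_along(taps))
    res <- res + taps[j] * out[, (j - 1) + 1:p, drop = FALSE]
  res
}

#' Smooth a response map with a 5 x 5 Gaussian low-pass kernel
#'
#' Convolves the magnitude map with a normalized 5 x 5 Gaussian
#' (`sigma` pixels, default 1), borders handled by reflection. Smoothing
#' precedes ROI definition and the pixelwise ODI computation.
#'
#' @param map A `response_map` of at least 5 x 5 pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @return The smoothed `response_map` (`smoothed = TRUE`).
#' @export
smooth_map <- function(map, sigma = 1.0) {
  stopifnot(inherits(map, "response_map"))
  if (nrow(map$magnitude) < 5 || ncol(map$magnitude) < 5)
    stop("map must be at least 5 x 5 pixels")
  if (sigma <= 0) stop("sigma must be positive")
  sm <- conv_sep_reflect(map$magnitude, gaussian_taps(sigma, 2))
  new_response_map(sm, phase = map$phase, eye = map$eye,
                   direction = map$direction, smoothed = TRUE, sigma = sigma)
}

#' Define the binocular region of interest
#'
#' The ROI is thresholded at a fraction (default 30%) of the peak response of
#' the smoothed ipsilateral-eye map. By default only the 8-connected component
#' of supra-threshold pixels containing the peak is kept, which excludes
#' disconnected noise blobs; set `connected = FALSE` to keep every
#' supra-threshold pixel.
#'
#' @param smoothed_ipsi Smoothed ipsilateral `response_map`.
#' @param threshold_fraction Fraction of the peak amplitude (default 0.3).
#' @param connected Keep only the peak's 8-connected component?
#' @return A `roi_mask` with `mask`, `threshold_fraction`, `peak_value`,
#'   `n_pixels`.
#' @export
define_binocular_roi <- function(smoothed_ipsi, threshold_fraction = 0.3,
                                 connected = TRUE) {
  stopifnot(inherits(smoothed_ipsi, "response_map"))
  if (!isTRUE(smoothed_ipsi$smoothed))
    stop("ROI must be defined on a smoothed map")
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must lie in (0, 1]")
  m <- smoothed_ipsi$magnitude
  peak <- max(m)
  if (peak <= 0) stop_odplast("odplast_no_roi", "map has no positive response; cannot define ROI")
  cand <- m >= threshold_fraction * peak
  mask <- if (connected) {
    seedpix <- which(m == peak)[1]
    connected_component(cand, seedpix)
  } else cand
  structure(list(mask = mask, threshold_fraction = threshold_fraction,
                 peak_value = peak, n_pixels = sum(mask)),
            class = "roi_mask")
}

# 8-connected component of `cand` containing linear index `seed`, grown by
# iterative dilation restricted to the candidate set.
connected_component <- function(cand, seed) {
  n <- nrow(cand); p <- ncol(cand)
  comp <- matrix(FALSE, n, p)
  comp[seed] <- TRUE
  repeat {
    g <- comp
    g[-1, ] <- g[-1, ] | comp[-n, ]
    g[-n, ] <- g[-n, ] | comp[-1, ]
    grown <- g
    grown[, -1] <- grown[, -1] | g[, -p]   # vertical merge first, then horiz+diag
    grown[, -p] <- grown[, -p] | g[, -1]
    grown <- grown & cand
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

#' Mean response amplitude over the ROI
#'
#' @param map A `response_map`.
#' @param roi A `roi_mask` with matching geometry.
#' @return Mean magnitude over ROI pixels (x 1e4 units).
#' @export
roi_amplitude <- function(map, roi) {
  stopifnot(inherits(map, "response_map"), inherits(roi, "roi_mask"))
  if (!identical(dim(map$magnitude), dim(roi$mask)))
    stop("geometry mismatch between map and ROI")
  if (roi$n_pixels == 0) stop("empty ROI")
  mean(map$magnitude[roi$mask])
}

#' Ocular dominance index over the binocular ROI
#'
#' For each ROI pixel, `odi_p = (C_p - I_p) / (C_p + I_p)` where `C` and `I`
#' are the smoothed contralateral- and ipsilateral-eye response magnitudes;
#' the ODI is the mean of `odi_p` over the ROI (the pixelwise definition, not
#' the ratio of ROI means). A pixel histogram over `[-1, 1]` is returned for
#' map-style summaries.
#'
#' @param contra,ipsi Smoothed `response_map`s for the two eyes.
#' @param roi A `roi_mask`.
#' @param n_bins Number of equal histogram bins over `[-1, 1]`.
#' @return An `odi_result` with `odi`, `amp_contra`, `amp_ipsi`, `histogram`
#'   (`bin_edges`, `counts`), `n_pixels`, and the settings used.
#' @export
compute_odi <- function(contra, ipsi, roi, n_bins = 50) {
  stopifnot(inherits(contra, "response_map"), inherits(ipsi, "response_map"),
            inherits(roi, "roi_mask"))
  if (!isTRUE(contra$smoothed) || !isTRUE(ipsi$smoothed))
    stop("ODI is computed on smoothed maps")
  if (!identical(dim(contra$magnitude), dim(ipsi$magnitude)) ||
      !identical(dim(contra$magnitude), dim(roi$mask)))
    stop("geometry mismatch")
  if (contra$eye != "contra" || ipsi$eye != "ipsi")
    stop("eye labels do not match the argument roles")
  C <- contra$magnitude[roi$mask]
  I <- ipsi$magnitude[roi$mask]
  s <- C + I
  if (any(s <= 0)) {
    bad <- which(roi$mask)[s <= 0]
    stop_odplast("odplast_degenerate_pixels",
                 paste0("C+I <= 0 at ROI pixel(s): ",
                        paste(utils::head(bad, 10), collapse = ", "),
                        if (length(bad) > 10) " ..." else ""),
                 pixels = bad)
  }
  odi_p <- (C - I) / s
  edges <- seq(-1, 1, length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(odi_p, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  structure(list(
    odi = mean(odi_p),
    amp_contra = roi_amplitude(contra, roi),
    amp_ipsi = roi_amplitude(ipsi, roi),
    histogram = list(bin_edges = edges, counts = counts),
    n_pixels = roi$n_pixels,
    settings = list(threshold_fraction = roi$threshold_fraction,
                    sigma = contra$sigma, n_bins = n_bins)
  ), class = "odi_result")
}

#' @export
print.odi_result <- function(x, ...) {
  cat(sprintf("<odi_result> ODI %.4f  (C %.3f, I %.3f x1e4; %d ROI px)\n",
              x$odi, x$amp_contra, x$amp_ipsi, x$n_pixels))
  invisible(x)
}

#' Run the full ocular-dominance analysis on one imaging session
#'
#' Orchestrates the four-step procedure in order: per-stack Fourier magnitude
#' maps, direction averaging per eye, 5 x 5 Gaussian smoothing, ROI at 30% of
#' the smoothed ipsilateral peak, then ROI amplitudes and the pixelwise ODI.
#' All stage outputs are retained for inspection.
#'
#' @param stacks List of four [intrinsic_stack()]s (both eyes x directions 90
#'   and 270), or the list returned by [gen_session()].
#' @param roi_fraction ROI threshold fraction of peak (default 0.3).
#' @param sigma Smoothing kernel SD in pixels.
#' @param n_bins ODI histogram bins.
#' @param connected Restrict the ROI to the peak's connected component?
#' @return A `session_analysis` with `odi` (an `odi_result`), `roi`, and
#'   per-eye raw/averaged/smoothed maps under `maps`.
#' @export
analyze_session <- function(stacks, roi_fraction = 0.3, sigma = 1.0,
                            n_bins = 50, connected = TRUE) {
  if (!is.null(stacks$stacks)) stacks <- stacks$stacks
  stopifnot(is.list(stacks), length(stacks) == 4)
  key <- vapply(stacks, function(s) paste0(s$eye, "_", s$direction), "")
  need <- c("contra_90", "contra_270", "ipsi_90", "ipsi_270")
  if (!setequal(key, need))
    stop("session must contain exactly: ", paste(need, collapse = ", "))
  names(stacks) <- key

  raw <- lapply(stacks, fourier_response_map)
  avg <- list(
    contra = average_directions(raw$contra_90, raw$contra_270),
    ipsi = average_directions(raw$ipsi_90, raw$ipsi_270)
  )
  sm <- lapply(avg, smooth_map, sigma = sigma)
  roi <- define_binocular_roi(sm$ipsi, roi_fraction, connected = connected)
  odi <- compute_odi(sm$contra, sm$ipsi, roi, n_bins = n_bins)
  structure(list(odi = odi, roi = roi,
                 maps = list(raw = raw, averaged = avg, smoothed = sm)),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  print(x$odi)
  invisible(x)
}
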