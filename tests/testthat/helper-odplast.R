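# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately use different algorithms than the implementation.

# Stack of pure cosines built directly from the closed form (bypasses the
# package generator) with per-pixel amplitudes `a` (H x W), integer bin k.
cosine_stack <- function(a, nt, frame_rate, k, phase = 0, eye = "contra",
                         direction = 90) {
  tt <- seq_len(nt) - 1
  co <- cos(2 * pi * k * tt / nt + phase)
  frames <- 1 + outer(co, as.numeric(a))
  dim(frames) <- c(nt, nrow(a), ncol(a))
  intrinsic_stack(frames, frame_rate = frame_rate,
                  stim_freq = k * frame_rate / nt, eye = eye,
                  direction = direction)
}

# Brute-force 2-D convolution with half-sample symmetric padding (direct
# nested loops; oracle for the separable implementation).
conv2_brute <- function(m, kern) {
  half <- (nrow(kern) - 1) / 2
  n <- nrow(m); p <- ncol(m)
  reflect <- function(i, n) {
    # half-sample symmetric: ..., 2, 1 | 1, ..., n | n, n-1, ...
    ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  }
  out <- matrix(0, n, p)
  for (i in 1:n) for (j in 1:p) {
    acc <- 0
    for (di in -half:half) for (dj in -half:half) {
      acc <- acc + kern[di + half + 1, dj + half + 1] *
        m[reflect(i + di, n), reflect(j + dj, p)]
    }
    out[i, j] <- acc
  }
  out
}

gauss_kernel_2d <- function(sigma = 1, half = 2) {
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(w, w)
  k / sum(k)
}

# Queue-based BFS connected components (8-connectivity) — independent oracle
# for the implementation's iterative-dilation component extraction.
roi_oracle <- function(m, threshold_fraction) {
  peak <- max(m)
  cand <- m >= threshold_fraction * peak
  n <- nrow(m); p <- ncol(m)
  seed <- which(m == peak)[1]
  comp <- matrix(FALSE, n, p)
  queue <- seed
  comp[seed] <- TRUE
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    i <- (idx - 1) %% n + 1
    j <- (idx - 1) %/% n + 1
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= p &&
          cand[ii, jj] && !comp[ii, jj]) {
        comp[ii, jj] <- TRUE
        queue <- c(queue, (jj - 1) * n + ii)
      }
    }
  }
  comp
}

# Random multi-blob magnitude map (sums of Gaussians) wrapped as a smoothed
# response map, for ROI tests.
random_blob_map <- function(n = 32, n_blobs = 3, eye = "ipsi") {
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  m <- matrix(0, n, n)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 4, n - 3); cx <- runif(1, 4, n - 3)
    s <- runif(1, 1.5, 4); h <- runif(1, 0.5, 3)
    m <- m + h * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * s^2))
  }
  structure(list(magnitude = m, phase = NULL, eye = eye, direction = NA,
                 smoothed = TRUE, sigma = 1.0),
            class = "response_map")
}

# Relabel the eyes of a generated session (contra <-> ipsi) keeping the data.
swap_session_eyes <- function(session) {
  stacks <- lapply(session$stacks, function(s) {
    s$eye <- if (s$eye == "contra") "ipsi" else "contra"
    s
  })
  names(stacks) <- vapply(stacks, function(s) paste0(s$eye, "_", s$direction), "")
  list(stacks = stacks, truth = session$truth)
}

# Fraction of true events (>= min_amp) matched by a detection in the same
# sweep within tol_s of the true onset. Events inside the (padded) test-pulse
# window are excluded from the denominator: the analysis discards that
# segment by design.
detection_recall <- function(detected, truth_log, min_amp = 10, tol_s = 0.003,
                             tp_window = c(0.01, 0.11)) {
  big <- truth_log[truth_log$amplitude >= min_amp &
                     !(truth_log$time >= tp_window[1] - 0.002 &
                         truth_log$time <= tp_window[2] + 0.010), ]
  if (!nrow(big)) return(NA_real_)
  hit <- mapply(function(sw, tt)
    any(detected$sweep_index == sw & abs(detected$time - tt) < tol_s),
    big$sweep, big$time)
  mean(hit)
}
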