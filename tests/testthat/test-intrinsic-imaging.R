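# Fourier response mapping, smoothing, ROI definition, and the ODI pipeline.

test_that("fourier_response_map recovers cosine amplitudes on exact bins", {
  # constant stack -> zero magnitude
  frames <- array(1, dim = c(100, 6, 6))
  st <- intrinsic_stack(frames, frame_rate = 10, stim_freq = 0.5, eye = "ipsi")
  m0 <- fourier_response_map(st)
  expect_equal(max(abs(m0$magnitude)), 0, tolerance = 1e-9)

  # single-pixel closed form: 1 + 3e-4 cos(2 pi 0.12 t), 300 s at 30 Hz
  a <- matrix(0, 6, 6); a[3, 4] <- 3e-4
  st1 <- cosine_stack(a, nt = 9000, frame_rate = 30, k = 36)
  m1 <- fourier_response_map(st1)
  expect_lt(abs(m1$magnitude[3, 4] - 3) / 3, 1e-6)

  # energy at 2x the stimulus frequency does not leak into the stimulus bin
  a2 <- matrix(2e-4, 6, 6)
  st2 <- cosine_stack(a2, nt = 1000, frame_rate = 10, k = 24)
  st2$stim_freq <- 12 * 10 / 1000      # analyze at half the modulated freq
  m2 <- fourier_response_map(st2)
  expect_equal(max(abs(m2$magnitude)), 0, tolerance = 1e-6)

  # errors: above-Nyquist and too-few-cycles
  stbad <- intrinsic_stack(array(1 + 1e-4 * rep(cos(1:100), 36), c(100, 6, 6)),
                           frame_rate = 10, stim_freq = 0.5, eye = "ipsi")
  stbad$stim_freq <- 6
  expect_error(fourier_response_map(stbad), "Nyquist")
})

test_that("average_directions is a validated pixelwise mean", {
  a <- matrix(2, 5, 5); b <- matrix(4, 5, 5)
  mu <- structure(list(magnitude = a, phase = NULL, eye = "contra",
                       direction = 90, smoothed = FALSE, sigma = NA),
                  class = "response_map")
  md <- structure(list(magnitude = b, phase = NULL, eye = "contra",
                       direction = 270, smoothed = FALSE, sigma = NA),
                  class = "response_map")
  expect_equal(average_directions(mu, md)$magnitude, matrix(3, 5, 5))
  expect_equal(average_directions(md, mu)$magnitude,
               average_directions(mu, md)$magnitude)
  mu270 <- mu; mu270$direction <- 270                  # same values, other sweep
  expect_equal(average_directions(mu, mu270)$magnitude, a)
  bad <- md; bad$eye <- "ipsi"
  expect_error(average_directions(mu, bad), "same eye")
  bad2 <- md; bad2$direction <- 90
  expect_error(average_directions(mu, bad2), "270")
})

test_that("smooth_map matches a brute-force convolution oracle", {
  mk <- function(m) structure(list(magnitude = m, phase = NULL, eye = "ipsi",
                                   direction = NA, smoothed = FALSE, sigma = NA),
                              class = "response_map")
  # constant preserved (kernel normalization)
  cm <- smooth_map(mk(matrix(2.38, 7, 7)))
  expect_equal(cm$magnitude, matrix(2.38, 7, 7), tolerance = 1e-12)
  expect_true(cm$smoothed)

  # impulse: center equals the kernel center weight, total sum preserved
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  sm <- smooth_map(mk(imp))
  kern <- gauss_kernel_2d(1, 2)
  expect_equal(sm$magnitude[6, 6], kern[3, 3], tolerance = 1e-12)
  expect_equal(sum(sm$magnitude), 1, tolerance = 1e-12)

  # random maps: implementation == brute-force oracle; mean preserved;
  # smoothing twice == one pass with the self-convolved kernel
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(runif(9 * 12), 9, 12)
    sm1 <- smooth_map(mk(m))$magnitude
    expect_equal(sm1, conv2_brute(m, kern), tolerance = 1e-12)
    expect_equal(mean(sm1), mean(m), tolerance = 1e-12)
  }
})

test_that("define_binocular_roi agrees with threshold + connected-component logic", {
  # uniform positive map: every pixel is at peak
  uni <- random_blob_map(10)
  uni$magnitude <- matrix(1.7, 10, 10)
  roi <- define_binocular_roi(uni)
  expect_true(all(roi$mask))
  expect_equal(roi$n_pixels, 100)

  # a strong blob and a distant sub-threshold blob: second blob excluded
  m <- matrix(0, 21, 21)
  yy <- matrix(1:21, 21, 21); xx <- t(yy)
  m <- 10 * exp(-((yy - 6)^2 + (xx - 6)^2) / 4) +
       2.5 * exp(-((yy - 17)^2 + (xx - 17)^2) / 4)
  blob <- uni; blob$magnitude <- m
  roi2 <- define_binocular_roi(blob, 0.3)
  expect_false(roi2$mask[17, 17])
  expect_true(roi2$mask[6, 6])
  expect_equal(roi2$mask, roi_oracle(m, 0.3))

  # threshold_fraction = 1: exactly the argmax pixels connected to the peak
  roi3 <- define_binocular_roi(blob, 1.0)
  expect_equal(which(roi3$mask), which(m == max(m)))

  # all-zero map is an error; unsmoothed map is rejected
  z <- uni; z$magnitude <- matrix(0, 10, 10)
  expect_error(define_binocular_roi(z), class = "odplast_no_roi")
  raw <- uni; raw$smoothed <- FALSE
  expect_error(define_binocular_roi(raw), "smoothed")
})

test_that("roi_amplitude averages inside the mask only", {
  mk <- function(m) structure(list(magnitude = m, phase = NULL, eye = "contra",
                                   direction = NA, smoothed = TRUE, sigma = 1),
                              class = "response_map")
  m <- matrix(2.38, 6, 6)
  roi <- structure(list(mask = matrix(TRUE, 6, 6), threshold_fraction = 0.3,
                        peak_value = 2.38, n_pixels = 36), class = "roi_mask")
  expect_equal(roi_amplitude(mk(m), roi), 2.38)

  mask2 <- matrix(FALSE, 6, 6); mask2[1, 1] <- TRUE; mask2[2, 2] <- TRUE
  roi2 <- structure(list(mask = mask2, threshold_fraction = 0.3,
                         peak_value = 3, n_pixels = 2), class = "roi_mask")
  m2 <- matrix(99, 6, 6); m2[1, 1] <- 1; m2[2, 2] <- 3
  expect_equal(roi_amplitude(mk(m2), roi2), 2)
  m3 <- m2; m3[!mask2] <- -1000   # outside-mask values are irrelevant
  expect_equal(roi_amplitude(mk(m3), roi2), 2)
})

test_that("compute_odi implements the pixelwise definition", {
  mk <- function(m, eye) structure(list(magnitude = m, phase = NULL, eye = eye,
                                        direction = NA, smoothed = TRUE,
                                        sigma = 1), class = "response_map")
  roi_all <- structure(list(mask = matrix(TRUE, 5, 5), threshold_fraction = 0.3,
                            peak_value = 1, n_pixels = 25), class = "roi_mask")
  # C = I -> 0
  r0 <- compute_odi(mk(matrix(2, 5, 5), "contra"), mk(matrix(2, 5, 5), "ipsi"),
                    roi_all)
  expect_equal(r0$odi, 0)
  # uniform C = 3, I = 1 -> 0.5
  r1 <- compute_odi(mk(matrix(3, 5, 5), "contra"), mk(matrix(1, 5, 5), "ipsi"),
                    roi_all)
  expect_equal(r1$odi, 0.5)
  expect_equal(sum(r1$histogram$counts), r1$n_pixels)

  # two-pixel ROI, C = (1, 3), I = (1, 1): pixelwise mean 0.25, not the
  # ratio-of-means 1/3
  mask <- matrix(FALSE, 5, 5); mask[1, 1] <- TRUE; mask[2, 1] <- TRUE
  roi2 <- structure(list(mask = mask, threshold_fraction = 0.3, peak_value = 1,
                         n_pixels = 2), class = "roi_mask")
  C <- matrix(0, 5, 5); C[1, 1] <- 1; C[2, 1] <- 3
  I <- matrix(0, 5, 5); I[1, 1] <- 1; I[2, 1] <- 1
  r2 <- compute_odi(mk(C, "contra"), mk(I, "ipsi"), roi2)
  expect_equal(r2$odi, 0.25)
  ratio_of_means <- (mean(C[mask]) - mean(I[mask])) / (mean(C[mask]) + mean(I[mask]))
  expect_equal(ratio_of_means, 1 / 3, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r2$odi, ratio_of_means)))

  # degenerate pixel (C + I = 0 inside ROI) raises a classed error
  Cz <- C; Cz[1, 1] <- 0
  Iz <- I; Iz[1, 1] <- 0
  expect_error(compute_odi(mk(Cz, "contra"), mk(Iz, "ipsi"), roi2),
               class = "odplast_degenerate_pixels")
})

test_that("analyze_session recovers the noise-free ODI and is deterministic", {
  tr <- imaging_truth(24, 24, amp_contra = 2.5e-4, amp_ipsi = 1.3e-4,
                      noise_sd = 0, seed = 2)
  ses <- gen_session(tr, duration = 50, frame_rate = 10)
  res <- analyze_session(ses)
  expect_equal(res$odi$odi, (2.5 - 1.3) / (2.5 + 1.3), tolerance = 1e-3)
  res2 <- analyze_session(ses)
  expect_identical(res$odi, res2$odi)

  # eye swap negates the ODI exactly
  swapped <- analyze_session(swap_session_eyes(ses))
  expect_equal(swapped$odi$odi, -res$odi$odi, tolerance = 1e-12)

  # scaling both eyes' modulation amplitudes leaves the ODI unchanged
  tr2 <- imaging_truth(24, 24, amp_contra = 3 * 2.5e-4, amp_ipsi = 3 * 1.3e-4,
                       noise_sd = 0, seed = 2)
  res3 <- analyze_session(gen_session(tr2, duration = 50, frame_rate = 10))
  expect_equal(res3$odi$odi, res$odi$odi, tolerance = 1e-12)
})

test_that("noisy sessions recover ODI and amplitudes (reduced-scale check)", {
  # reduced geometry/duration relative to the acceptance-scale run in
  # test-acceptance.R (full version: 100 sessions, 64 x 64, 300 s at 30 Hz);
  # noise is scaled by sqrt(T_reduced / T_full) so the per-pixel amplitude
  # uncertainty after Fourier integration matches the full-scale setting
  set.seed(7)
  odis <- runif(12, -0.1, 0.5)
  noise_sd <- 1e-3 * sqrt(3000 / 9000)
  err_odi <- amp_rel_err <- numeric(length(odis))
  for (i in seq_along(odis)) {
    tr <- imaging_truth(48, 48, odi = odis[i], noise_sd = noise_sd,
                        seed = 700 + i)
    ses <- gen_session(tr, duration = 150, frame_rate = 20, stim_freq = 0.12)
    res <- analyze_session(ses)
    err_odi[i] <- res$odi$odi - odis[i]
    # amplitude truth: smoothed true map averaged over the recovered ROI
    kern <- gauss_kernel_2d(1, 2)
    truth_sm <- conv2_brute(tr$amp_contra_map, kern) * 1e4
    amp_rel_err[i] <- res$odi$amp_contra / mean(truth_sm[res$roi$mask]) - 1
  }
  expect_lt(mean(abs(err_odi)), 0.02)
  expect_lt(max(abs(amp_rel_err)), 0.05)
})
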