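test_that("moving average computes exact window means", {
  arr <- array(rep(1:20, each = 4), c(2, 2, 20))   # frame i constant = i
  st <- frame_stack(arr, fps = 10)
  avg <- moving_average(st, 5)
  expect_identical(dim(avg$frames)[3], 16L)
  expect_equal(avg$frames[1, 1, 1], 3.0)
  expect_equal(avg$frames[2, 2, 16], 18.0)
  # constant stack stays constant for any window
  cst <- frame_stack(array(7, c(3, 3, 12)), fps = 1)
  expect_true(all(moving_average(cst, 10)$frames == 7))
  expect_error(moving_average(cst, 13), "shorter")
})

test_that("differential stack is the adjacent difference and shortens by one", {
  arr <- array(rnorm(3 * 3 * 6), c(3, 3, 6))
  st <- frame_stack(arr, fps = 5)
  d <- differential_stack(st)
  expect_identical(dim(d$frames)[3], 5L)
  expect_equal(d$frames[, , 2], arr[, , 3] - arr[, , 2])
  # static scene -> all-zero differentials
  expect_true(all(differential_stack(frame_stack(array(2, c(2, 2, 4)),
                                                 fps = 1))$frames == 0))
  expect_error(differential_stack(frame_stack(array(0, c(2, 2, 1)), fps = 1)),
               "two frames")
})

test_that("differential of a monotone-brightening static pattern is proportional to it", {
  pattern <- make_airy_psf(9, 2)
  frames <- lapply(1:12, function(i) pattern * i)
  st <- frame_stack(frames, fps = 1)
  d <- differential_stack(moving_average(st, 4))
  for (i in seq_len(dim(d$frames)[3]))
    expect_equal(d$frames[, , i], pattern, tolerance = 1e-12)
})

test_that("build_psf recovers a kernel from integer-shifted copies", {
  base <- matrix(0, 21, 21)
  base[8:14, 8:14] <- make_airy_psf(7, 2)
  imgs <- withr::with_seed(1, lapply(1:30, function(i) {
    dr <- sample(-3:3, 1); dc <- sample(-3:3, 1)
    m <- matrix(0, 21, 21)
    m[(8:14) + dr, (8:14) + dc] <- make_airy_psf(7, 2)
    m
  }))
  rec <- build_psf(imgs)
  expect_lt(max(abs(rec - base / max(base))), 1e-12)
  # identical inputs return the normalized input
  two <- build_psf(list(base, base))
  expect_equal(two, base / max(base))
  expect_error(build_psf(list(base)), "at least 2")
})

test_that("k-space deconvolution is the identity for a delta kernel", {
  img <- matrix(rnorm(32 * 32), 32, 32)
  delta <- matrix(0, 5, 5); delta[3, 3] <- 1
  out <- deconvolve_kspace(img, delta, eps_rel = 1e-9)
  expect_lt(max(abs(out - img)) / max(abs(img)), 1e-6)
  expect_error(deconvolve_kspace(img, matrix(0, 3, 3)), "zero")
})

test_that("convolve-deconvolve round trip restores peak position and amplitude", {
  psf <- make_airy_psf(15, 3)
  for (shift in list(c(20, 20), c(11, 47), c(50, 9))) {
    spot <- matrix(0, 64, 64)
    idx <- seq(-4, 4)
    spot[shift[1] + idx, shift[2] + idx] <-
      5 * exp(-(outer(idx^2, idx^2, "+")) / (2 * 2^2))
    blurred <- evpsubtype:::convolve_psf(spot, psf)
    dec <- deconvolve_kspace(blurred, psf, eps_rel = 1e-8)
    pk <- which(dec == max(dec), arr.ind = TRUE)[1, ]
    expect_equal(unname(pk), shift, ignore_attr = TRUE)
    expect_lt(abs(max(dec) - max(spot)) / max(spot), 0.05)
  }
})

test_that("infinite regularization drives the deconvolved image to zero", {
  img <- matrix(rnorm(16 * 16), 16, 16)
  psf <- make_airy_psf(5, 2)
  out <- deconvolve_kspace(img, psf, eps = 1e12)
  expect_lt(max(abs(out)), 1e-6)
})

test_that("particle intensity averages the 3x3 neighbourhood", {
  img <- matrix(0, 7, 7)
  img[3:5, 3:5] <- matrix(1:9, 3, 3)
  expect_equal(particle_intensity(img, c(4, 4)), 5.0)
  uni <- matrix(4.2, 5, 5)
  expect_equal(particle_intensity(uni, c(3, 3)), 4.2)
  expect_error(particle_intensity(img, c(1, 1)), "border")
  expect_error(particle_intensity(img, c(7, 4)), "border")
})

test_that("detection finds injected landings with exact frames and positions", {
  fx <- render_detection_fixture(n_events = 12, snr = 10, frame = 200, seed = 21)
  det <- detect_landings(differential_stack(moving_average(fx$stack, fx$n_avg)),
                         threshold_sigma = 5, min_separation_px = 8,
                         n_avg = fx$n_avg)
  expect_identical(nrow(det), 12L)
  hit <- vapply(seq_len(12), function(i)
    any(det$frame == fx$landing_frames[i] &
        abs(det$x_px - fx$events$x_px[i]) <= 2 &
        abs(det$y_px - fx$events$y_px[i]) <= 2), logical(1))
  expect_true(all(hit))
  # event times are frame / fps and non-decreasing in emission order
  expect_equal(det$time_s, det$frame / fx$stack$fps)
  expect_true(all(diff(det$frame) >= 0))
})

test_that("empty stacks and pure noise yield empty detections", {
  noise <- frame_stack(array(rnorm(64 * 64 * 40), c(64, 64, 40)), fps = 10)
  det <- detect_landings(differential_stack(moving_average(noise, 10)),
                         threshold_sigma = 5, min_separation_px = 8)
  expect_identical(nrow(det), 0L)
  zero <- frame_stack(array(0, c(16, 16, 25)), fps = 10)
  expect_identical(nrow(detect_landings(differential_stack(
    moving_average(zero, 10)))), 0L)
  expect_error(detect_landings(differential_stack(moving_average(noise, 10)),
                               threshold_sigma = 0), "positive")
})

test_that("detection recall is non-decreasing in SNR", {
  recall_at <- function(snr) {
    fx <- render_detection_fixture(n_events = 12, snr = snr, frame = 200,
                                   seed = 33)
    det <- detect_landings(differential_stack(moving_average(fx$stack, 10)),
                           threshold_sigma = 5, min_separation_px = 8)
    mean(vapply(seq_len(12), function(i)
      any(abs(det$x_px - fx$events$x_px[i]) <= 2 &
          abs(det$y_px - fx$events$y_px[i]) <= 2), logical(1)))
  }
  r_low <- recall_at(2.5)
  r_high <- recall_at(10)
  expect_lte(r_low, r_high)
  expect_identical(r_high, 1)
})

test_that("frame stacks round-trip through multi-page TIFF", {
  arr <- array(runif(8 * 8 * 5), c(8, 8, 5))
  st <- frame_stack(arr, fps = 25)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path, fps = 25)
  expect_identical(dim(back$frames), dim(arr))
  # 16-bit quantization of the affinely mapped intensities
  rng <- max(arr) - min(arr)
  expect_lt(max(abs((back$frames * rng + min(arr)) - arr)), rng / 65535 * 2)
})
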