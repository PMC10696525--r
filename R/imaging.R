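#' Frame stack container
#'
#' An ordered stack of single-channel frames with acquisition metadata.
#'
#' @param frames 3-D numeric array `[rows, cols, frames]`, or a list of
#'   equally sized matrices.
#' @param fps Frame rate in frames per second (> 0).
#' @param pixel_size_nm Optional pixel size metadata in nm per pixel.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps, pixel_size_nm = NA_real_) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must share one shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    c(dims[[1L]], length(frames)))
  }
  if (length(dim(frames)) != 3L) stop("frames must be a [rows, cols, n] array")
  if (fps <= 0) stop("fps must be positive")
  structure(list(frames = frames, fps = fps, pixel_size_nm = pixel_size_nm),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Frame stack: %d frames of %dx%d px at %g fps\n",
              d[3L], d[1L], d[2L], x$fps))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3L]

#' Temporal moving average of a frame stack
#'
#' Output frame `i` is the mean of input frames `i, ..., i + n - 1`,
#' so a stack of length `L` becomes one of length `L - n + 1`.
#' Averaging over `n = 10` raw frames (the default) suppresses shot
#' noise by sqrt(10) before differential reconstruction.
#'
#' @param stack A [frame_stack()].
#' @param n Window length in frames (>= 1, <= stack length).
#' @return A [frame_stack()] of averaged frames (fps unchanged; frame
#'   `i` is stamped at the time of its first raw frame).
#' @export
moving_average <- function(stack, n = 10) {
  L <- n_frames(stack)
  if (n < 1) stop("n must be at least 1")
  if (L < n) stop("stack shorter than the averaging window")
  d <- dim(stack$frames)
  m <- matrix(stack$frames, d[1L] * d[2L], L)
  # running sums via cumulative sums along time
  cs <- matrix(0, nrow(m), L + 1L)
  for (i in seq_len(L)) cs[, i + 1L] <- cs[, i] + m[, i]
  out <- (cs[, (n + 1L):(L + 1L), drop = FALSE] -
          cs[, 1L:(L - n + 1L), drop = FALSE]) / n
  frame_stack(array(out, c(d[1L], d[2L], L - n + 1L)), fps = stack$fps,
              pixel_size_nm = stack$pixel_size_nm)
}

#' Differential image stack
#'
#' Differences between adjacent (averaged) frames: `D_i = A_{i+1} - A_i`.
#' A particle that lands and persists shows up as a transient positive
#' spot in the differentials, so each landing is counted once.
#'
#' @param avg A [frame_stack()] (typically the output of
#'   [moving_average()]), length >= 2.
#' @return A [frame_stack()] one frame shorter than the input.
#' @export
differential_stack <- function(avg) {
  L <- n_frames(avg)
  if (L < 2L) stop("need at least two frames to difference")
  arr <- avg$frames[, , -1L, drop = FALSE] - avg$frames[, , -L, drop = FALSE]
  frame_stack(arr, fps = avg$fps, pixel_size_nm = avg$pixel_size_nm)
}

#' Build a point-spread function from single-particle images
#'
#' Aligns each image so its maximum-intensity pixel sits at the common
#' centre (first occurrence in row-major order on ties), averages
#' pixel-wise over the images (ignoring pixels shifted out of view),
#' and renormalizes to unit peak.  The experimental recipe uses 30
#' individual images of 100 nm silica beads.
#'
#' @param bead_images List of >= 2 equally sized matrices.
#' @return A PSF kernel matrix with unit peak.
#' @export
build_psf <- function(bead_images) {
  if (length(bead_images) < 2L) stop("need at least 2 bead images")
  dims <- unique(lapply(bead_images, dim))
  if (length(dims) != 1L) stop("bead images must share one shape")
  nr <- dims[[1L]][1L]; nc <- dims[[1L]][2L]
  cr <- ceiling(nr / 2); cc <- ceiling(nc / 2)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (img in bead_images) {
    # row-major first occurrence of the maximum
    pos <- which(t(img) == max(img))[1L]
    pr <- (pos - 1L) %/% nc + 1L; pc <- (pos - 1L) %% nc + 1L
    dr <- cr - pr; dc <- cc - pc
    src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
    ok_r <- src_r >= 1L & src_r <= nr; ok_c <- src_c >= 1L & src_c <= nc
    acc[ok_r, ok_c] <- acc[ok_r, ok_c] + img[src_r[ok_r], src_c[ok_c]]
    cnt[ok_r, ok_c] <- cnt[ok_r, ok_c] + 1
  }
  psf <- acc / pmax(cnt, 1)
  psf[cnt == 0] <- 0
  psf / max(psf)
}

# pad a PSF to the image size with its peak at the (1,1) origin, so the
# Wiener filter introduces no translation
pad_psf_origin <- function(psf, nr, nc) {
  if (nrow(psf) > nr || ncol(psf) > nc) stop("psf larger than image")
  pr <- which(psf == max(psf), arr.ind = TRUE)[1L, ]
  big <- matrix(0, nr, nc)
  big[seq_len(nrow(psf)), seq_len(ncol(psf))] <- psf
  rsh <- (seq_len(nr) - 1L + (pr[1L] - 1L)) %% nr + 1L
  csh <- (seq_len(nc) - 1L + (pr[2L] - 1L)) %% nc + 1L
  big[rsh, csh]
}

#' Wiener deconvolution in k-space
#'
#' Inverse filtering in the Fourier domain:
#' `F^-1[ F(img) * conj(F(psf)) / (|F(psf)|^2 + eps) ]`.
#' The regularization `eps` bounds the gain where the PSF spectrum is
#' weak; its default is a fraction `eps_rel` of `max |F(psf)|^2`.
#'
#' @param image 2-D numeric matrix.
#' @param psf PSF kernel (unit peak, smaller than the image).
#' @param eps Absolute regularization; overrides `eps_rel` if given.
#' @param eps_rel Regularization relative to `max |F(psf)|^2`.
#' @return Deconvolved matrix of the same shape.
#' @export
deconvolve_kspace <- function(image, psf, eps = NULL, eps_rel = 1e-3) {
  if (all(psf == 0)) stop("psf is identically zero")
  H <- stats::fft(pad_psf_origin(psf, nrow(image), ncol(image)))
  P2 <- Mod(H)^2
  if (is.null(eps)) eps <- eps_rel * max(P2)
  if (eps <= 0) stop("regularization must be positive")
  G <- stats::fft(image) * Conj(H) / (P2 + eps)
  Re(stats::fft(G, inverse = TRUE)) / length(image)
}

# convolution with the same origin convention (used in tests/round trips)
convolve_psf <- function(image, psf) {
  H <- stats::fft(pad_psf_origin(psf, nrow(image), ncol(image)))
  Re(stats::fft(stats::fft(image) * H, inverse = TRUE)) / length(image)
}

#' Mean intensity of the 3x3 neighbourhood around a peak
#'
#' The per-particle intensity readout: the arithmetic mean of the 3 x 3
#' pixels centred on the brightest pixel of the particle image.
#'
#' @param image 2-D numeric matrix.
#' @param peak Integer `c(row, col)` (1-based), at least one pixel away
#'   from every border.
#' @return Scalar mean intensity.
#' @export
particle_intensity <- function(image, peak) {
  r <- peak[1L]; c <- peak[2L]
  if (r < 2L || c < 2L || r > nrow(image) - 1L || c > ncol(image) - 1L)
    stop("peak must lie at least 1 px inside the image border")
  mean(image[(r - 1L):(r + 1L), (c - 1L):(c + 1L)])
}

# robust per-frame background SD from the median absolute deviation
robust_sd <- function(x) stats::mad(x, center = stats::median(x))

# local maxima (8-neighbourhood, strict) of a matrix above a threshold
local_maxima <- function(img, thresh) {
  nr <- nrow(img); nc <- ncol(img)
  core <- img[2:(nr - 1L), 2:(nc - 1L)]
  ok <- core > thresh
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ok <- ok & core > img[2:(nr - 1L) + dr, 2:(nc - 1L) + dc]
  }
  w <- which(ok, arr.ind = TRUE)
  w + 1L   # back to full-image coordinates
}

#' Detect particle-landing events in a differential stack
#'
#' Per differential frame: optionally Wiener-deconvolve, find local
#' maxima above `threshold_sigma` times the frame's robust (MAD-based)
#' background SD, and suppress maxima closer than `min_separation_px`
#' (keeping the brighter).  Detections at the same site in consecutive
#' differential frames are linked into one landing: a particle landing
#' at raw frame `f` appears in the `n_avg` differential frames
#' `f - n_avg, ..., f - 1` with amplitude `I / n_avg`, so the landing
#' frame is recovered as the onset differential frame plus `n_avg`, and
#' the event intensity is measured on the sum of those `n_avg`
#' differential frames (the full step amplitude).
#'
#' @param diff A [frame_stack()] of differential images.
#' @param threshold_sigma Detection threshold as a multiple of the
#'   robust background SD (default 5).
#' @param min_separation_px Minimum peak separation in pixels.
#' @param psf Optional PSF kernel; when supplied each frame is
#'   deconvolved before peak finding.
#' @param n_avg Moving-average window used upstream (maps onset
#'   differential frames to landing frames and sets the linking span).
#' @param min_persist Number of consecutive differential frames a
#'   candidate must exceed the threshold to be accepted (default 2).
#'   A real landing persists over `n_avg` differential frames, whereas
#'   background fluctuations are independent between differentials, so
#'   requiring persistence squares the per-pixel false-positive rate at
#'   essentially no cost in recall.
#' @param intensity_on Measure the 3x3 intensity on the `"deconvolved"`
#'   (default, when a PSF is given) or `"raw"` differential sum.
#' @return `data.frame` with one row per landing: `frame` (0-based raw
#'   landing frame), `time_s`, `y_px`, `x_px` (0-based peak position)
#'   and `intensity`.
#' @export
detect_landings <- function(diff, threshold_sigma = 5, min_separation_px = 5,
                            psf = NULL, n_avg = 10, min_persist = 2,
                            intensity_on = c("deconvolved", "raw")) {
  if (threshold_sigma <= 0 || min_separation_px <= 0)
    stop("thresholds must be positive")
  intensity_on <- match.arg(intensity_on)
  L <- n_frames(diff)
  raw <- diff$frames
  min_persist <- min(min_persist, L)
  # pass 1: per-frame candidate peaks after non-maximum suppression
  frame_peaks <- vector("list", L)
  for (i in seq_len(L)) {
    img <- raw[, , i]
    det <- if (!is.null(psf)) deconvolve_kspace(img, psf) else img
    sd_i <- robust_sd(det)
    if (sd_i == 0) { frame_peaks[[i]] <- matrix(0L, 0L, 2L); next }
    peaks <- local_maxima(det, threshold_sigma * sd_i)
    if (nrow(peaks) > 1L) {
      vals <- det[peaks]
      o <- order(vals, decreasing = TRUE)
      peaks <- peaks[o, , drop = FALSE]
      kept <- matrix(NA_integer_, 0L, 2L)
      for (j in seq_len(nrow(peaks))) {
        p <- peaks[j, ]
        if (nrow(kept) &&
            any((kept[, 1L] - p[1L])^2 + (kept[, 2L] - p[2L])^2 <
                min_separation_px^2)) next
        kept <- rbind(kept, p)
      }
      peaks <- kept
    }
    frame_peaks[[i]] <- peaks
  }
  near_any <- function(peaks, p) {
    nrow(peaks) > 0L &&
      any((peaks[, 1L] - p[1L])^2 + (peaks[, 2L] - p[2L])^2 <
          min_separation_px^2)
  }
  # pass 2: link candidates across frames into landings
  out <- list()
  active <- data.frame(r = integer(0L), c = integer(0L), until = integer(0L))
  for (i in seq_len(L)) {
    active <- active[active$until >= i, , drop = FALSE]
    peaks <- frame_peaks[[i]]
    for (j in seq_len(nrow(peaks))) {
      p <- peaks[j, ]
      if (nrow(active) &&
          any((active$r - p[1L])^2 + (active$c - p[2L])^2 <
              min_separation_px^2)) next
      if (min_persist > 1L) {
        if (i + min_persist - 1L > L) next
        confirmed <- all(vapply(seq_len(min_persist - 1L), function(d)
          near_any(frame_peaks[[i + d]], p), logical(1L)))
        if (!confirmed) next
      }
      span <- i:min(i + n_avg - 1L, L)
      img_sum <- matrix(rowSums(matrix(raw[, , span, drop = FALSE],
                                       ncol = length(span))),
                        dim(raw)[1L], dim(raw)[2L])
      meas <- if (intensity_on == "deconvolved" && !is.null(psf))
        deconvolve_kspace(img_sum, psf) else img_sum
      inten <- tryCatch(particle_intensity(meas, p),
                        error = function(e) meas[p[1L], p[2L]])
      f_land <- (i - 1L) + n_avg
      out[[length(out) + 1L]] <- data.frame(
        frame = f_land, time_s = f_land / diff$fps,
        y_px = p[1L] - 1L, x_px = p[2L] - 1L, intensity = inten)
      active <- rbind(active,
                      data.frame(r = p[1L], c = p[2L], until = i + n_avg))
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0L), time_s = numeric(0L),
                      y_px = integer(0L), x_px = integer(0L),
                      intensity = numeric(0L)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$frame), , drop = FALSE]
}

#' Read and write frame stacks as multi-page TIFF
#'
#' Stacks are stored as 16-bit grayscale multi-page TIFF.  Intensities
#' are affinely mapped to the 16-bit range on write; the mapping is not
#' stored, so absolute scale is not preserved (detection thresholds are
#' relative to background SD and unaffected).
#'
#' @param stack A [frame_stack()].
#' @param path File path.
#' @param fps Frame rate to attach on read.
#' @return `read_stack_tiff()` returns a [frame_stack()];
#'   `write_stack_tiff()` returns `path` invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  arr <- stack$frames
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(i) (arr[, , i] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, fps) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frame_stack(pages, fps = fps)
}
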