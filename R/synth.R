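#' @importFrom stats plnorm qlnorm runif rbinom rpois rnorm rlnorm quantile
NULL

MARKER_PANEL <- c("CD63", "EpCAM", "HER2", "PSMA", "PTK7")
TOTAL_SURFACE <- "total"

# truncated lognormal sampler (inverse CDF; exact, vectorized)
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(plo + runif(n) * (phi - plo), meanlog, sdlog)
}

#' Class size distribution for synthetic EVP samples
#'
#' Lognormal diameter distribution truncated to the analysable range.
#' Defaults (median 90 nm, `sdlog` 0.35, range 30-160 nm) give a
#' unimodal profile of the shape typically reported by nanoparticle
#' tracking analysis of small-EV preparations.
#'
#' @param meanlog,sdlog Lognormal parameters of the untruncated diameter
#'   distribution (nm on the natural-log scale).
#' @param lo,hi Truncation bounds in nm.
#' @return An object of class `size_dist`.
#' @export
size_dist_lnorm <- function(meanlog = log(90), sdlog = 0.35, lo = 30, hi = 160) {
  structure(list(meanlog = meanlog, sdlog = sdlog, lo = lo, hi = hi),
            class = "size_dist")
}

sample_size_dist <- function(dist, n) {
  rtrunc_lnorm(n, dist$meanlog, dist$sdlog, dist$lo, dist$hi)
}

# probability mass of each base-grid bin under a truncated lognormal
bin_masses <- function(dist, grid = base_grid()) {
  b <- unclass(grid)
  p <- plnorm(b, dist$meanlog, dist$sdlog)
  m <- diff(p)
  m / sum(m)
}

#' Marker positivity-and-kinetics profile
#'
#' Describes how one membrane-protein marker behaves in one sample
#' class: the probability that an EVP of a given diameter carries the
#' marker (piecewise constant on the 10 nm base grid), and the Langmuir
#' binding kinetics of marker-positive EVPs on the aptamer surface.
#'
#' @param marker Marker label.
#' @param positivity Numeric vector of per-base-bin positivity
#'   probabilities in `[0, 1]`, one per base-grid bin (13 by default).
#' @param k Association rate coefficient in 1/s; non-negative.
#' @param n_max Saturation binding count (number of capture events at
#'   infinite time); non-negative.
#' @param grid Base grid the positivity vector is defined on.
#' @return An object of class `marker_profile`.
#' @export
marker_profile <- function(marker, positivity, k, n_max, grid = base_grid()) {
  if (length(positivity) != n_groups(grid))
    stop("positivity must have one value per base bin")
  if (any(positivity < 0 | positivity > 1)) stop("positivity must lie in [0, 1]")
  if (k < 0) stop("k must be non-negative")
  if (n_max < 0) stop("n_max must be non-negative")
  structure(list(marker = marker, positivity = as.numeric(positivity),
                 k = k, n_max = n_max, grid = grid),
            class = "marker_profile")
}

positivity_at <- function(profile, diameter) {
  idx <- assign_group(diameter, profile$grid)
  p <- rep(0, length(diameter))
  ok <- !is.na(idx)
  p[ok] <- profile$positivity[idx[ok]]
  p
}

#' Build a positivity vector with a fixed overall level and a size band
#'
#' Returns per-base-bin positivities whose expectation under `dist`
#' equals `level`, with a fraction `weight` of all marker-positive EVPs
#' concentrated in the bins covering `[band_lo, band_hi)`.  With
#' `band_lo = NULL` the positivity is flat at `level`.  Values are
#' capped at 1 (with a warning) if the requested concentration is
#' infeasible.
#'
#' @param level Overall marker-positive fraction in `[0, 1]`.
#' @param band_lo,band_hi Band limits in nm, on the base grid.
#' @param weight Fraction of positives placed inside the band.
#' @param dist A [size_dist_lnorm()] giving the class size distribution.
#' @param grid Base grid.
#' @return Numeric positivity vector (one value per base bin).
#' @export
banded_positivity <- function(level, band_lo = NULL, band_hi = NULL,
                              weight = 0.5, dist = size_dist_lnorm(),
                              grid = base_grid()) {
  nb <- n_groups(grid)
  if (is.null(band_lo)) return(rep(level, nb))
  b <- unclass(grid)
  in_band <- b[-length(b)] >= band_lo & b[-1L] <= band_hi
  if (!any(in_band)) stop("band covers no base bin")
  m <- bin_masses(dist, grid)
  m_band <- sum(m[in_band])
  p <- numeric(nb)
  p[in_band] <- level * weight / m_band
  p[!in_band] <- level * (1 - weight) / (1 - m_band)
  if (any(p > 1)) {
    warning("requested concentration capped at positivity 1")
    p <- pmin(p, 1)
  }
  p
}

#' Specification of one synthetic sample class
#'
#' @param label Class label.
#' @param dist A [size_dist_lnorm()] class size distribution.
#' @param profiles Named list of [marker_profile()] objects, one per
#'   marker in the panel.
#' @param total_n_max,total_k Kinetics of the positively charged
#'   total-count surface, which captures every EVP regardless of marker.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(label, dist, profiles, total_n_max = 2000,
                       total_k = 0.010) {
  nm <- vapply(profiles, function(p) p$marker, character(1L))
  names(profiles) <- nm
  if (anyDuplicated(nm)) stop("exactly one profile per marker")
  structure(list(label = label, dist = dist, profiles = profiles,
                 total_n_max = total_n_max, total_k = total_k),
            class = "class_spec")
}

# site-binding landing-time model: each of n_max surface sites captures a
# particle at an Exp(k) time; the run observes sites bound by `duration`.
# N(T) ~ Binomial(n_max, 1 - e^(-kT)), times i.i.d. truncated exponential,
# so the expected cumulative curve is exactly n_max * (1 - e^(-kt)).
sample_landing_times <- function(n_max, k, duration) {
  if (k <= 0 || duration <= 0 || n_max <= 0) return(numeric(0L))
  p_T <- 1 - exp(-k * duration)
  n <- rbinom(1L, round(n_max), p_T)
  sort(-log(1 - runif(n) * p_T) / k)
}

# diameters from dist conditioned on marker positivity (rejection sampling)
sample_conditional_diameters <- function(n, dist, profile) {
  out <- numeric(0L)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 1000L) stop("positivity too low to sample conditional diameters")
    need <- n - length(out)
    cand <- sample_size_dist(dist, max(need * 4L, 64L))
    acc <- runif(length(cand)) < positivity_at(profile, cand)
    out <- c(out, cand[acc])
  }
  out[seq_len(n)]
}

new_event_table <- function(n = 0L) {
  data.frame(sample_id = character(n), class_label = character(n),
              surface = character(n), time_s = numeric(n),
              x_px = numeric(n), y_px = numeric(n),
              intensity = numeric(n), diameter_nm = numeric(n),
              stringsAsFactors = FALSE)
}

# forward optical model: intensity ~ c * d^3 / r (r > 1 for EVPs, whose
# refractive-index contrast is below that of the silica calibration beads)
forward_intensity <- function(diameter, instrument_c = 1, r = 1) {
  instrument_c * diameter^3 / r
}

simulate_run <- function(spec, surface, profile, n_max, k, duration,
                         batch_factor = 1, sample_id = "s1",
                         instrument_c = 1, r_evp = ri_compensation_factor(),
                         frame_px = 256) {
  n_max_eff <- round(n_max * batch_factor)
  times <- sample_landing_times(n_max_eff, k, duration)
  n <- length(times)
  if (n == 0L) {
    ev <- new_event_table(0L)
    d <- numeric(0L)
  } else {
    d <- if (is.null(profile)) sample_size_dist(spec$dist, n)
         else sample_conditional_diameters(n, spec$dist, profile)
    ev <- data.frame(sample_id = sample_id, class_label = spec$label,
                     surface = surface, time_s = times,
                     x_px = runif(n, 1, frame_px - 2),
                     y_px = runif(n, 1, frame_px - 2),
                     intensity = forward_intensity(d, instrument_c, r_evp),
                     diameter_nm = d, stringsAsFactors = FALSE)
  }
  truth <- list(n_max = n_max_eff, k = k, surface = surface,
                events = data.frame(time_s = times, diameter_nm = d))
  list(events = ev, truth = truth)
}

#' Simulate one aptamer-surface binding run
#'
#' Draws particle-landing events for one sample on one marker's aptamer
#' surface.  Landing times follow the site-binding model whose expected
#' cumulative count is `n_max * (1 - exp(-k * t))` (the saturating
#' Langmuir form fitted downstream); the observed count never exceeds
#' `n_max`.  Each event's diameter is drawn from the class size
#' distribution conditioned on marker positivity at that diameter.
#'
#' @param spec A [class_spec()].
#' @param marker Marker label; must exist in `spec$profiles`.
#' @param duration Run duration in seconds (> 0).
#' @param seed Optional integer seed for reproducibility.
#' @param batch_factor Multiplicative batch-effect factor on `n_max`.
#' @param sample_id Sample identifier written to the event table.
#' @param instrument_c Instrument intensity constant (intensity per nm^3
#'   for a silica-contrast particle).
#' @param r_evp Refractive-index compensation factor applied to EVP
#'   intensities (see [ri_compensation_factor()]).
#' @return A list with `events` (an event `data.frame` with columns
#'   `sample_id, class_label, surface, time_s, x_px, y_px, intensity,
#'   diameter_nm`) and `truth` (generating `n_max`, `k`, and per-event
#'   ground truth).
#' @export
simulate_marker_run <- function(spec, marker, duration, seed = NULL,
                                batch_factor = 1, sample_id = "s1",
                                instrument_c = 1,
                                r_evp = ri_compensation_factor()) {
  if (duration <= 0) stop("duration must be positive")
  profile <- spec$profiles[[marker]]
  if (is.null(profile)) stop("unknown marker label: ", marker)
  run <- function() simulate_run(spec, marker, profile, profile$n_max,
                                 profile$k, duration, batch_factor,
                                 sample_id, instrument_c, r_evp)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a total-count run on the positively charged surface
#'
#' As [simulate_marker_run()], but the positively charged surface
#' captures every EVP (positivity identically 1), with the class's
#' total-surface kinetics.  The resulting count is the denominator of
#' the expression level.
#'
#' @inheritParams simulate_marker_run
#' @return As [simulate_marker_run()].
#' @export
simulate_total_run <- function(spec, duration, seed = NULL,
                               batch_factor = 1, sample_id = "s1",
                               instrument_c = 1,
                               r_evp = ri_compensation_factor()) {
  if (duration < 0) stop("duration must be non-negative")
  run <- function() simulate_run(spec, TOTAL_SURFACE, NULL, spec$total_n_max,
                                 spec$total_k, duration, batch_factor,
                                 sample_id, instrument_c, r_evp)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a silica-bead calibration run
#'
#' Per bead, intensity follows the cubic scattering law
#' `I = c * d^3 * (1 + eps)` with multiplicative Gaussian noise
#' `eps ~ N(0, cv^2)`.
#'
#' @param diameters Nominal bead diameters in nm (default the standard
#'   five calibration sizes 30, 50, 70, 100, 160 nm).
#' @param n_per_size Beads per nominal size (>= 1).
#' @param cv Relative intensity noise (>= 0).
#' @param seed Optional integer seed.
#' @param instrument_c Instrument intensity constant.
#' @return `data.frame` with columns `nominal_diameter_nm`, `intensity`.
#' @export
simulate_calibration_run <- function(diameters = c(30, 50, 70, 100, 160),
                                     n_per_size = 200, cv = 0.05,
                                     seed = NULL, instrument_c = 1) {
  if (any(diameters <= 0)) stop("diameters must be positive")
  if (n_per_size < 1) stop("n_per_size must be at least 1")
  if (cv < 0) stop("cv must be non-negative")
  run <- function() {
    d <- rep(diameters, each = n_per_size)
    data.frame(nominal_diameter_nm = d,
               intensity = instrument_c * d^3 *
                 (1 + rnorm(length(d), 0, cv)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Synthetic Airy-pattern point-spread function
#'
#' A radially symmetric Airy diffraction pattern `(2 J1(x) / x)^2` with
#' first zero at `radius` pixels, normalized to unit peak — a stand-in
#' for a measured single-particle image kernel.
#'
#' @param size Odd side length in pixels.
#' @param radius Radius of the first dark ring in pixels.
#' @return A `size x size` matrix with peak value 1 at the centre.
#' @export
make_airy_psf <- function(size = 15, radius = 3) {
  if (size %% 2 == 0) stop("size must be odd")
  c0 <- (size + 1) / 2
  idx <- seq_len(size) - c0
  r <- sqrt(outer(idx^2, idx^2, "+"))
  x <- 3.8317 * r / radius   # first zero of J1 at 3.8317
  psf <- matrix(1, size, size)
  nz <- x > 0
  psf[nz] <- (2 * besselJ(x[nz], 1) / x[nz])^2
  psf / max(psf)
}

#' Render an image stack from a table of landing events
#'
#' Each event adds its point-spread function, scaled by the event
#' intensity, permanently to every frame from its landing frame
#' (`floor(time_s * fps)`, 0-based) onward, on a background of i.i.d.
#' Gaussian noise — the image-formation model assumed by the detection
#' stage, where a landed particle persists on the sensor.
#'
#' @param events Event `data.frame` with `time_s`, `x_px` (column),
#'   `y_px` (row) and `intensity`.
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param fps Frame rate in frames per second.
#' @param psf PSF kernel matrix with odd sides and unit peak.
#' @param noise_sd Gaussian background noise SD per pixel per frame.
#' @param duration Stack duration in seconds (defaults to covering the
#'   last event plus one second).
#' @param seed Optional integer seed for the noise.
#' @return A list with `stack` (a [frame_stack()]) and `landing_frames`
#'   (0-based ground-truth landing frame per event).
#' @export
render_image_stack <- function(events, frame_shape = c(256, 256), fps = 10,
                               psf = make_airy_psf(), noise_sd = 1,
                               duration = NULL, seed = NULL) {
  if (is.null(duration))
    duration <- if (nrow(events)) max(events$time_s) + 1 else 1
  if (nrow(events) && any(events$time_s >= duration))
    stop("event times must fall within the stack duration")
  nr <- frame_shape[1L]; nc <- frame_shape[2L]
  if (nrow(events) &&
      any(events$y_px < 0 | events$y_px >= nr |
          events$x_px < 0 | events$x_px >= nc))
    stop("events outside the field of view")
  n_frames <- max(1L, ceiling(duration * fps))
  kh <- (nrow(psf) - 1L) / 2L; kw <- (ncol(psf) - 1L) / 2L
  render <- function() {
    arr <- array(rnorm(nr * nc * n_frames, 0, noise_sd), c(nr, nc, n_frames))
    landing <- integer(nrow(events))
    for (i in seq_len(nrow(events))) {
      f0 <- floor(events$time_s[i] * fps)
      landing[i] <- f0
      if (f0 >= n_frames) next
      r0 <- round(events$y_px[i]); c0 <- round(events$x_px[i])
      rr <- (r0 - kh):(r0 + kh); cc <- (c0 - kw):(c0 + kw)
      ok_r <- rr >= 0 & rr < nr; ok_c <- cc >= 0 & cc < nc
      patch <- psf[ok_r, ok_c, drop = FALSE] * events$intensity[i]
      arr[rr[ok_r] + 1L, cc[ok_c] + 1L, (f0 + 1L):n_frames] <-
        arr[rr[ok_r] + 1L, cc[ok_c] + 1L, (f0 + 1L):n_frames] +
        as.vector(patch)
      }
    list(stack = frame_stack(arr, fps = fps), landing_frames = landing)
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

default_marker_k <- c(CD63 = 0.0028, EpCAM = 0.0040, HER2 = 0.0050,
                      PSMA = 0.0070, PTK7 = 0.0060)

#' Default five-class, five-marker synthetic scenario
#'
#' Emulates a size-localized marker experiment with five sample classes
#' measured on five aptamer surfaces plus the positively charged
#' total-count surface.  All four tumour-like classes share the same
#' overall per-marker positivity (`level_cancer`), so a bulk analysis
#' can separate only healthy from tumour; the classes differ in where
#' marker-positive EVPs sit in the size distribution:
#' `tumourA` concentrates EpCAM and CD63 positives below 70 nm, while
#' `tumourB`/`tumourC`/`tumourD` each concentrate a distinct marker pair
#' (HER2+EpCAM, PSMA+PTK7, CD63+HER2) above 120 nm.  The healthy class
#' is uniformly low (`level_healthy`).  Batch-to-batch heterogeneity
#' multiplies every run's `n_max` by an independent lognormal factor.
#'
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @param replicates Samples per class.
#' @param duration Run duration in seconds.
#' @param level_cancer,level_healthy Overall marker-positive fractions.
#' @param n_max_total Saturation count of the total-count surface.
#' @param batch_sdlog Lognormal sd of the per-run batch factor.
#' @return An object of class `evp_dataset`: list with `events` (all
#'   runs row-bound), `samples` (`sample_id`, `class_label`), `markers`,
#'   `duration`, `class_specs`, and per-run generating `truth`.
#' @export
default_five_class_scenario <- function(seed = 1, replicates = 20,
                                        duration = 900,
                                        level_cancer = 0.30,
                                        level_healthy = 0.05,
                                        n_max_total = 2000,
                                        batch_sdlog = 0.15) {
  dist <- size_dist_lnorm()
  band <- list(
    tumourA  = list(markers = c("EpCAM", "CD63"), lo = 30,  hi = 70,  w = 0.75),
    tumourB  = list(markers = c("HER2", "EpCAM"), lo = 120, hi = 160, w = 0.5),
    tumourC  = list(markers = c("PSMA", "PTK7"),  lo = 120, hi = 160, w = 0.5),
    tumourD  = list(markers = c("CD63", "HER2"),  lo = 120, hi = 160, w = 0.5),
    healthy  = list(markers = character(0L), lo = NULL, hi = NULL, w = 0)
  )
  specs <- lapply(names(band), function(cl) {
    b <- band[[cl]]
    level <- if (cl == "healthy") level_healthy else level_cancer
    profiles <- lapply(MARKER_PANEL, function(m) {
      pos <- if (m %in% b$markers)
        banded_positivity(level, b$lo, b$hi, b$w, dist)
      else banded_positivity(level, dist = dist)
      marker_profile(m, pos, k = default_marker_k[[m]],
                     n_max = level * n_max_total)
    })
    class_spec(cl, dist, profiles, total_n_max = n_max_total, total_k = 0.010)
  })
  names(specs) <- names(band)

  build <- function() {
    events <- list(); truth <- list()
    samples <- data.frame(sample_id = character(0L),
                          class_label = character(0L))
    for (cl in names(specs)) {
      for (r in seq_len(replicates)) {
        sid <- sprintf("%s_%02d", cl, r)
        samples <- rbind(samples,
                         data.frame(sample_id = sid, class_label = cl))
        for (m in MARKER_PANEL) {
          run <- simulate_marker_run(specs[[cl]], m, duration,
                                     batch_factor = rlnorm(1L, 0, batch_sdlog),
                                     sample_id = sid)
          events[[length(events) + 1L]] <- run$events
          truth[[paste(sid, m, sep = ":")]] <- run$truth
        }
        run <- simulate_total_run(specs[[cl]], duration,
                                  batch_factor = rlnorm(1L, 0, batch_sdlog),
                                  sample_id = sid)
        events[[length(events) + 1L]] <- run$events
        truth[[paste(sid, TOTAL_SURFACE, sep = ":")]] <- run$truth
      }
    }
    structure(list(events = do.call(rbind, events), samples = samples,
                   markers = MARKER_PANEL, duration = duration,
                   class_specs = specs, truth = truth, seed = seed),
              class = "evp_dataset")
  }
  withr::with_seed(seed, build())
}

#' @export
print.evp_dataset <- function(x, ...) {
  cat(sprintf("Synthetic EVP dataset: %d samples, %d classes, %d markers, %d events\n",
              nrow(x$samples), length(unique(x$samples$class_label)),
              length(x$markers), nrow(x$events)))
  invisible(x)
}
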