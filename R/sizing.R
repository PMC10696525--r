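#' Gaussian fit to a particle-intensity histogram
#'
#' Bins the intensities (Freedman-Diaconis rule) and fits a Gaussian to
#' the bin counts by nonlinear least squares, returning the peak
#' location and width — the per-size calibration readout (the
#' experimental recipe uses n > 150 beads per size).  Falls back to the
#' sample mean/SD when the curve fit does not converge.
#'
#' @param intensities Numeric vector, at least `floor_n` values.
#' @param floor_n Minimum number of values (default 150).
#' @return List with `mu`, `sigma` and `n`.
#' @export
fit_intensity_peak <- function(intensities, floor_n = 150) {
  x <- intensities
  if (any(!is.finite(x))) stop("intensities must be finite")
  if (length(x) < floor_n)
    stop(sprintf("need at least %d intensities (got %d)", floor_n, length(x)))
  if (max(x) == min(x))
    return(list(mu = x[1L], sigma = 0, n = length(x)))
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ a * exp(-(mid - mu)^2 / (2 * s^2)), data = df,
                      start = list(a = max(df$count), mu = mean(x),
                                   s = stats::sd(x)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(mu = mean(x), sigma = stats::sd(x), n = length(x)))
  cf <- stats::coef(fit)
  list(mu = unname(cf["mu"]), sigma = abs(unname(cf["s"])), n = length(x))
}

#' Refractive-index compensation factor
#'
#' Ratio of Clausius-Mossotti optical contrasts between the silica
#' calibration beads and EVPs in the imaging medium:
#' `r = CM(n_silica, n_medium) / CM(n_evp, n_medium)` with
#' `CM(n_p, n_m) = (n_p^2 - n_m^2) / (n_p^2 + 2 n_m^2)`.
#' Because EVPs have lower contrast than silica, `r > 1` and an EVP of
#' equal measured intensity maps to a larger diameter.  Defaults are
#' standard literature indices (silica 1.46, EVP 1.40, aqueous medium
#' 1.33).
#'
#' @param n_silica,n_evp,n_medium Refractive indices.
#' @return Scalar compensation factor `r`.
#' @export
ri_compensation_factor <- function(n_silica = 1.46, n_evp = 1.40,
                                   n_medium = 1.33) {
  if (n_medium <= 0) stop("n_medium must be positive")
  cm <- function(np) (np^2 - n_medium^2) / (np^2 + 2 * n_medium^2)
  if (abs(cm(n_evp)) < .Machine$double.eps * 10)
    stop("EVP contrast is zero (n_evp equals n_medium)")
  cm(n_silica) / cm(n_evp)
}

#' Fit the intensity-diameter calibration curve
#'
#' Least-squares line in log-log space through the per-size peak
#' intensities: `log I = log c + b log d`.  The slope is expected near
#' 3 (scattering intensity scales with particle volume squared over the
#' interferometric reference, i.e. ~ d^3 in this detection regime); it
#' is fitted rather than fixed so that instrumental deviations from the
#' cubic law are absorbed.
#'
#' @param sizes Nominal bead diameters in nm (>= 2 distinct, positive).
#' @param peaks Peak intensities, one per size (positive).
#' @param r Refractive-index compensation factor stored with the model
#'   (applied to EVP intensities on inversion; see
#'   [intensity_to_diameter()]).
#' @param peak_fits Optional list of per-size [fit_intensity_peak()]
#'   results, stored as metadata.
#' @return An object of class `calibration_model` with elements `b`
#'   (log-log slope), `c` (intensity at d = 1 nm), `r` and `peak_fits`.
#' @export
fit_calibration <- function(sizes, peaks, r = ri_compensation_factor(),
                            peak_fits = NULL) {
  if (length(sizes) != length(peaks) || length(sizes) < 2L)
    stop("need matching sizes and peaks, at least 2")
  if (any(sizes <= 0) || any(peaks <= 0))
    stop("sizes and peak intensities must be positive")
  if (length(unique(sizes)) < 2L) stop("calibration sizes are degenerate")
  fit <- stats::lm(log(peaks) ~ log(sizes))
  b <- unname(stats::coef(fit)[2L])
  cc <- exp(unname(stats::coef(fit)[1L]))
  structure(list(b = b, c = cc, r = r, sizes = sizes, peaks = peaks,
                 peak_fits = peak_fits),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Intensity-size calibration: I = %.4g * d^%.4f  (r = %.4f)\n",
              x$c, x$b, x$r))
  invisible(x)
}

#' Fit a calibration model from a bead-run intensity table
#'
#' Convenience wrapper: groups a calibration run by nominal diameter,
#' fits each size's intensity peak, then fits the log-log calibration
#' line through the peaks.
#'
#' @param run `data.frame` with columns `nominal_diameter_nm` and
#'   `intensity` (as produced by [simulate_calibration_run()]).
#' @param floor_n Minimum beads per size for the peak fit.
#' @inheritParams fit_calibration
#' @return A `calibration_model`.
#' @export
calibrate_from_run <- function(run, r = ri_compensation_factor(),
                               floor_n = 150) {
  sizes <- sort(unique(run$nominal_diameter_nm))
  fits <- lapply(sizes, function(s)
    fit_intensity_peak(run$intensity[run$nominal_diameter_nm == s],
                       floor_n = floor_n))
  fit_calibration(sizes, vapply(fits, `[[`, numeric(1L), "mu"),
                  r = r, peak_fits = fits)
}

#' Convert measured intensities to particle diameters
#'
#' Inverts the calibration power law with refractive-index
#' compensation: `d = (I * r / c)^(1/b)`.  For silica particles set
#' `r = 1`; for EVPs the model's stored `r > 1` maps an equal intensity
#' to a larger diameter, compensating their lower optical contrast.
#'
#' @param intensity Positive numeric vector of measured intensities.
#' @param model A `calibration_model` from [fit_calibration()].
#' @param r Compensation factor; defaults to the model's stored value.
#' @return Diameters in nm.
#' @export
intensity_to_diameter <- function(intensity, model, r = model$r) {
  if (any(intensity <= 0)) stop("intensities must be positive")
  (intensity * r / model$c)^(1 / model$b)
}

#' Persist and restore calibration models as JSON
#'
#' @param model A `calibration_model`.
#' @param path File path.
#' @return `read_calibration_json()` returns the model;
#'   `write_calibration_json()` returns `path` invisibly.
#' @export
write_calibration_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "calibration_model")
}

#' Attach diameters to an event table
#'
#' Applies [intensity_to_diameter()] to the `intensity` column and fills
#' `diameter_nm`.
#'
#' @param events Event `data.frame` with an `intensity` column.
#' @param model A `calibration_model`.
#' @param r Compensation factor (model default).
#' @return The event table with `diameter_nm` filled.
#' @export
size_events <- function(events, model, r = model$r) {
  events$diameter_nm <- intensity_to_diameter(events$intensity, model, r = r)
  events
}
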