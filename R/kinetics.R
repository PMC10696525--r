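#' Cumulative binding curve
#'
#' Cumulative particle count versus time for one size group:
#' `counts[j]` is the number of events with `time_s <= t[j]` on a
#' uniform time grid.
#'
#' @param group Group label.
#' @param time Strictly increasing numeric time grid in seconds.
#' @param counts Non-decreasing, non-negative integer counts.
#' @return An object of class `binding_curve`.
#' @export
binding_curve <- function(group, time, counts) {
  if (length(time) != length(counts)) stop("time and counts must align")
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing")
  if (any(counts < 0) || any(diff(counts) < 0))
    stop("counts must be non-negative and non-decreasing")
  structure(list(group = group, time = time, counts = counts),
            class = "binding_curve")
}

#' @export
print.binding_curve <- function(x, ...) {
  cat(sprintf("Binding curve [%s]: %d time points, final count %d\n",
              x$group, length(x$time), x$counts[length(x$counts)]))
  invisible(x)
}

#' Size-resolved cumulative binding curves
#'
#' Splits sized events by partition group and accumulates counts on a
#' uniform grid `dt, 2 dt, ..., duration`.  Events whose diameter falls
#' outside the partition range are excluded.
#'
#' @param events Sized event `data.frame` (non-missing `diameter_nm`).
#' @param partition A [size_partition()].
#' @param dt Grid step in seconds (> 0); default 1 s.
#' @param duration Observation window in seconds; default 900 s.
#' @return Named list of [binding_curve()] objects, one per group.
#' @export
cumulative_binding_curve <- function(events, partition = size_partition(c(30, 160)),
                                     dt = 1, duration = 900) {
  if (dt <= 0) stop("dt must be positive")
  if (nrow(events) && any(is.na(events$diameter_nm)))
    stop("events must be sized before building binding curves")
  tgrid <- seq(dt, duration, by = dt)
  grp <- assign_group(events$diameter_nm, partition)
  labs <- group_labels(partition)
  out <- lapply(seq_len(n_groups(partition)), function(g) {
    tt <- events$time_s[!is.na(grp) & grp == g & events$time_s <= duration]
    counts <- cumsum(tabulate(pmax(pmin(ceiling(tt / dt), length(tgrid)), 1L),
                              nbins = length(tgrid)))
    binding_curve(labs[g], tgrid, counts)
  })
  names(out) <- labs
  out
}

#' Fit the saturating-exponential binding model
#'
#' Nonlinear least squares of the Langmuir saturation form
#' `N(t) = N_max * (1 - exp(-k t))` to a cumulative binding curve,
#' yielding the maximum binding number `N_max` and the exponential
#' coefficient `k` (in 1/s).  Initialized at `N_max =` final count and
#' `k` from the initial slope; falls back to a multi-start grid over
#' `k` if the first fit fails.
#'
#' @param curve A [binding_curve()].
#' @param min_points Minimum number of time points.
#' @param min_events Minimum final count.
#' @return An object of class `kinetic_fit`: list with `n_max`, `k`,
#'   `rss`, `n_events` and `group`.
#' @export
fit_exponential <- function(curve, min_points = 10, min_events = 5) {
  t <- curve$time; y <- curve$counts
  n_ev <- y[length(y)]
  if (length(t) < min_points || n_ev < min_events)
    stop(sprintf("insufficient data for kinetic fit (%d points, %d events)",
                 length(t), n_ev))
  df <- data.frame(t = t, y = y)
  k0 <- {
    # initial slope ~ N_max * k over the first decile of the window
    i <- max(2L, ceiling(length(t) / 10))
    slope <- (y[i] - y[1L]) / (t[i] - t[1L])
    max(slope / max(n_ev, 1), 1e-5)
  }
  try_fit <- function(nm0, kk0) {
    tryCatch(
      minpack.lm::nlsLM(y ~ nmax * (1 - exp(-k * t)), data = df,
                        start = list(nmax = nm0, k = kk0),
                        lower = c(nmax = 1e-8, k = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }
  fit <- try_fit(n_ev, k0)
  if (is.null(fit)) {
    for (kk in 10^seq(-4, -1, by = 0.5)) {
      fit <- try_fit(n_ev, kk)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) stop("kinetic fit failed to converge after multi-start")
  cf <- stats::coef(fit)
  structure(list(n_max = unname(cf["nmax"]), k = unname(cf["k"]),
                 rss = sum(stats::resid(fit)^2), n_events = n_ev,
                 group = curve$group),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit [%s]: N_max = %.1f, k = %.5f 1/s (n = %d, rss = %.3g)\n",
              x$group, x$n_max, x$k, x$n_events, x$rss))
  invisible(x)
}

#' Write binding curves to CSV
#'
#' Long format: `time_s`, `group`, `cumulative_count`.
#'
#' @param curves List of [binding_curve()] objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(time_s = cv$time, group = cv$group,
               cumulative_count = cv$counts)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
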