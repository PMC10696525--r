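#' Marker expression level
#'
#' Fraction of marker-positive detections relative to the total EVP
#' count measured on the positively charged capture surface.
#'
#' @param positive_count Marker-positive event count (>= 0).
#' @param total_count Total EVP count (> 0).
#' @return `positive_count / total_count`.
#' @export
expression_level <- function(positive_count, total_count) {
  if (any(total_count <= 0)) stop("total count must be positive")
  if (any(positive_count < 0)) stop("counts must be non-negative")
  positive_count / total_count
}

#' Percentile normalization of a feature column
#'
#' Subtracts the 2.5th percentile and divides by the 97.5th-2.5th
#' percentile range (percentiles by linear interpolation of order
#' statistics).  Values outside the band map outside `[0, 1]`; no
#' clipping is applied.
#'
#' @param column Numeric vector with at least 3 distinct values.
#' @return List with `values` (normalized column) and `record`
#'   (`c(p2.5, p97.5)`).
#' @export
percentile_normalize <- function(column) {
  if (length(unique(column)) < 3L)
    stop("need at least 3 distinct values to normalize")
  p <- stats::quantile(column, c(0.025, 0.975), names = FALSE, type = 7)
  if (p[2L] == p[1L]) stop("degenerate column: p97.5 equals p2.5")
  list(values = (column - p[1L]) / (p[2L] - p[1L]),
       record = c(p2.5 = p[1L], p97.5 = p[2L]))
}

#' Row-wise z-scores
#'
#' Each row is centred by its mean and scaled by its standard deviation
#' (denominator `n - 1`), the normalization used for expression
#' heatmaps.
#'
#' @param m Numeric matrix; every row needs >= 2 values and nonzero SD.
#' @return Matrix of the same shape with row mean 0 and row SD 1.
#' @export
zscore_rows <- function(m) {
  if (ncol(m) < 2L) stop("rows need at least 2 values")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  if (any(sd == 0)) stop("zero-SD row cannot be z-scored")
  (m - mu) / sd
}

#' Per-sample marker-by-size profiles
#'
#' Reduces a dataset of event tables to one profile per sample: for
#' each marker and partition group, the expression level (group
#' positive count over total count) and, optionally, the fitted
#' Langmuir parameters of the group's binding curve.
#'
#' @param dataset An `evp_dataset` (see
#'   [default_five_class_scenario()]) or a list with `events`,
#'   `samples`, `markers`, `duration`.
#' @param partition A [size_partition()].
#' @param fit_kinetics Fit `k`/`n_max` per marker-group curve (needed
#'   for the `"k"`/`"n_max"` quantities; slower).
#' @param dt Curve grid step in seconds.
#' @param group_total Use group-resolved total-surface counts as the
#'   expression denominator instead of the overall total.  The default
#'   (overall total) makes group expressions additive: they sum to the
#'   bulk expression level.
#' @return `data.frame` of class `sample_profiles` in long format:
#'   `sample_id`, `class_label`, `marker`, `group`, `expression`, `k`,
#'   `n_max`, plus attributes `partition` and `total_counts`.
#' @export
sample_profiles <- function(dataset, partition, fit_kinetics = FALSE,
                            dt = 1, group_total = FALSE) {
  ev <- dataset$events
  samples <- dataset$samples
  markers <- dataset$markers
  duration <- dataset$duration
  labs <- group_labels(partition)
  grp <- assign_group(ev$diameter_nm, partition)
  in_range <- !is.na(grp) & ev$time_s <= duration
  rows <- list()
  totals <- numeric(nrow(samples)); names(totals) <- samples$sample_id
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    sel_tot <- in_range & ev$sample_id == sid & ev$surface == TOTAL_SURFACE
    tot_all <- sum(sel_tot)
    tot_grp <- tabulate(grp[sel_tot], nbins = n_groups(partition))
    totals[sid] <- tot_all
    if (tot_all == 0) stop("sample ", sid, " has zero total count")
    for (m in markers) {
      sel_m <- in_range & ev$sample_id == sid & ev$surface == m
      pos_grp <- tabulate(grp[sel_m], nbins = n_groups(partition))
      denom <- if (group_total) pmax(tot_grp, 1) else rep(tot_all, length(labs))
      kk <- nmaxx <- rep(NA_real_, length(labs))
      if (fit_kinetics) {
        curves <- cumulative_binding_curve(ev[sel_m, , drop = FALSE],
                                           partition, dt = dt,
                                           duration = duration)
        for (g in seq_along(labs)) {
          ft <- tryCatch(fit_exponential(curves[[g]]), error = function(e) NULL)
          if (!is.null(ft)) { kk[g] <- ft$k; nmaxx[g] <- ft$n_max }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, class_label = samples$class_label[i], marker = m,
        group = labs, expression = pos_grp / denom, k = kk, n_max = nmaxx,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("sample_profiles", "data.frame"),
            partition = partition, total_counts = totals)
}

#' Assemble the sample-by-feature matrix
#'
#' Builds the `samples x (marker x group x quantity)` matrix fed to the
#' classifier.  Empty-group cells are imputed (0 for expression, column
#' median for kinetic quantities), zero-variance columns are dropped
#' with a warning, and every remaining column is percentile-normalized.
#'
#' @param profiles A [sample_profiles()] data frame.
#' @param quantities Subset of `c("expression", "k", "n_max")`.
#' @param normalize Apply [percentile_normalize()] per column.
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix, samples by features), `labels` (class label per sample),
#'   `normalization` (per-feature percentile records), and `partition`.
#' @export
assemble_features <- function(profiles, quantities = "expression",
                              normalize = TRUE) {
  quantities <- match.arg(quantities, c("expression", "k", "n_max"),
                          several.ok = TRUE)
  if (any(quantities != "expression") && all(is.na(profiles$k)))
    stop("profiles lack kinetic fits; rebuild with fit_kinetics = TRUE")
  sids <- unique(profiles$sample_id)
  labels <- profiles$class_label[match(sids, profiles$sample_id)]
  cols <- list()
  for (q in quantities) {
    for (m in unique(profiles$marker)) {
      for (g in unique(profiles$group)) {
        sub <- profiles[profiles$marker == m & profiles$group == g, ,
                        drop = FALSE]
        v <- sub[[q]][match(sids, sub$sample_id)]
        if (anyNA(v))
          v[is.na(v)] <- if (q == "expression") 0 else
            stats::median(v, na.rm = TRUE)
        cols[[paste(m, g, q, sep = ":")]] <- v
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- sids
  keep <- apply(x, 2L, function(col) length(unique(col)) >= 3L)
  if (any(!keep)) {
    warning(sprintf("dropping %d zero/low-variance feature column(s): %s",
                    sum(!keep), paste(colnames(x)[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  norm_rec <- NULL
  if (normalize) {
    normed <- lapply(seq_len(ncol(x)), function(j) percentile_normalize(x[, j]))
    norm_rec <- do.call(rbind, lapply(normed, `[[`, "record"))
    rownames(norm_rec) <- colnames(x)
    x <- matrix(unlist(lapply(normed, `[[`, "values")), nrow(x), ncol(x),
                dimnames = dimnames(x))
  }
  structure(list(x = x, labels = labels,
                 normalization = norm_rec,
                 partition = attr(profiles, "partition")),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d samples x %d features (%d classes)\n",
              nrow(x$x), ncol(x$x), length(unique(x$labels))))
  invisible(x)
}

#' Z-score heatmap table of class-mean expression
#'
#' Convenience export mirroring a marker-by-class expression heatmap:
#' class-mean expression per marker-group feature, z-scored across
#' classes within each row.
#'
#' @param profiles A [sample_profiles()] data frame.
#' @return Matrix of z-scores, rows `marker:group`, columns classes.
#' @export
zscore_heatmap <- function(profiles) {
  agg <- stats::aggregate(expression ~ marker + group + class_label,
                          data = profiles, FUN = mean)
  classes <- unique(agg$class_label)
  rowsid <- unique(paste(agg$marker, agg$group, sep = ":"))
  m <- matrix(NA_real_, length(rowsid), length(classes),
              dimnames = list(rowsid, classes))
  m[cbind(match(paste(agg$marker, agg$group, sep = ":"), rowsid),
          match(agg$class_label, classes))] <- agg$expression
  zscore_rows(m)
}
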