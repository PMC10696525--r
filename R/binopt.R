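partition_key <- function(partition) paste(unclass(partition), collapse = ",")

#' Fast cross-validated partition objective
#'
#' Builds the objective function used by the partition search: for a
#' candidate size partition, assemble expression features (markers by
#' groups, group positive counts over the sample's total count),
#' percentile-normalize each column, and return the stratified k-fold
#' cross-validated LDA accuracy.  The fold assignment is fixed once
#' (from `fold_seed`) and shared across all partitions, so candidate
#' partitions are compared on identical folds; objective values are
#' memoized per partition.
#'
#' Per-sample base-bin counts are precomputed once, so each candidate
#' evaluation reduces to a contiguous-sum aggregation plus the CV fit.
#'
#' @param dataset An `evp_dataset` (events must carry diameters).
#' @param grid Base grid partition (13 bins by default).
#' @param k Number of CV folds.
#' @param fold_seed Integer seed fixing the fold assignment.
#' @param shrinkage Passed to [fit_lda()].
#' @return A function `partition -> accuracy` with attributes
#'   `"labels"` and `"evaluations"` (an environment counting unique
#'   evaluations).
#' @export
cv_partition_objective <- function(dataset, grid = base_grid(), k = 5,
                                   fold_seed = 1, shrinkage = "lw") {
  ev <- dataset$events
  samples <- dataset$samples
  markers <- dataset$markers
  nb <- n_groups(grid)
  bin <- assign_group(ev$diameter_nm, grid)
  ok <- !is.na(bin) & ev$time_s <= dataset$duration
  # counts[sample, marker x basebin]; totals[sample]
  sid_i <- match(ev$sample_id, samples$sample_id)
  m_i <- match(ev$surface, markers)
  tot_sel <- ok & ev$surface == TOTAL_SURFACE
  totals <- tabulate(sid_i[tot_sel], nbins = nrow(samples))
  if (any(totals == 0)) stop("every sample needs a nonzero total count")
  mk_sel <- ok & !is.na(m_i)
  idx <- (sid_i[mk_sel] - 1L) +
    nrow(samples) * ((m_i[mk_sel] - 1L) * nb + bin[mk_sel] - 1L)
  counts <- array(tabulate(idx + 1L, nbins = nrow(samples) * length(markers) * nb),
                  c(nrow(samples), nb, length(markers)))
  y <- samples$class_label
  single_class <- length(unique(y)) < 2L
  folds <- if (single_class) rep(1L, length(y)) else make_folds(y, k, fold_seed)
  cache <- new.env(parent = emptyenv())
  evals <- new.env(parent = emptyenv())
  evals$n <- 0L
  objective <- function(partition) {
    key <- partition_key(partition)
    if (!is.null(cache[[key]])) return(cache[[key]])
    evals$n <- evals$n + 1L
    if (single_class) { cache[[key]] <- 1; return(1) }
    b <- unclass(partition)
    gidx <- assign_group(unclass(grid)[-(nb + 1L)] + 1e-9, partition)
    G <- n_groups(partition)
    # aggregate base bins into groups, per marker
    feats <- matrix(0, nrow(samples), G * length(markers))
    for (m in seq_along(markers)) {
      agg <- rowsum(t(counts[, , m]), gidx)        # G x samples
      feats[, (m - 1L) * G + seq_len(G)] <- t(agg)
    }
    feats <- feats / totals
    # percentile-normalize columns; drop degenerate ones
    keep <- logical(ncol(feats))
    for (j in seq_len(ncol(feats))) {
      p <- stats::quantile(feats[, j], c(0.025, 0.975), names = FALSE, type = 7)
      if (p[2L] > p[1L]) {
        feats[, j] <- (feats[, j] - p[1L]) / (p[2L] - p[1L])
        keep[j] <- TRUE
      }
    }
    feats <- feats[, keep, drop = FALSE]
    acc <- if (ncol(feats) == 0L) {
      # no informative feature: majority-class accuracy
      max(table(y)) / length(y)
    } else {
      correct <- 0L
      for (f in seq_len(k)) {
        test <- folds == f
        model <- fit_lda(feats[!test, , drop = FALSE], y[!test],
                         shrinkage = shrinkage)
        pred <- predict(model, feats[test, , drop = FALSE])
        correct <- correct + sum(pred == y[test])
      }
      correct / length(y)
    }
    cache[[key]] <- acc
    acc
  }
  attr(objective, "labels") <- y
  attr(objective, "evaluations") <- evals
  objective
}

#' Greedy hill climbing over size partitions
#'
#' Steepest-ascent local search: from a random starting partition, move
#' to the best-scoring single-boundary-toggle neighbour while it
#' strictly improves the objective; stop at a local optimum, after
#' `max_iter` moves, or once `target_accuracy` is reached.  Repeats
#' from `restarts` random starts and returns the best partition found.
#' Objective values are memoized per partition within the run.
#'
#' @param objective Function `partition -> accuracy` (see
#'   [cv_partition_objective()]).
#' @param grid Base grid partition.
#' @param restarts Number of random restarts (>= 1).
#' @param max_iter Maximum moves per restart.
#' @param seed Integer seed for the random starts.
#' @param target_accuracy Optional early-stop threshold.
#' @return An object of class `partition_search_result`: `best`
#'   (partition), `best_value`, `trace` (per restart, the objective
#'   value after each move), `evaluations` (unique objective
#'   evaluations), `restarts`, `seed`.
#' @export
hill_climb <- function(objective, grid = base_grid(), restarts = 10,
                       max_iter = 100, seed = NULL, target_accuracy = NULL) {
  if (restarts < 1) stop("restarts must be at least 1")
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_memo <- function(p) {
    key <- partition_key(p)
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    cache[[key]] <- objective(p)
  }
  run <- function() {
    best <- NULL; best_val <- -Inf; traces <- vector("list", restarts)
    for (r in seq_len(restarts)) {
      cur <- random_partition(grid)
      cur_val <- eval_memo(cur)
      trace <- cur_val
      for (it in seq_len(max_iter)) {
        if (!is.null(target_accuracy) && cur_val >= target_accuracy) break
        nb <- neighbors(cur, grid)
        vals <- vapply(nb, eval_memo, numeric(1L))
        j <- which.max(vals)
        if (vals[j] <= cur_val) break
        # tie-break among equal-best neighbours: fewer groups first
        ties <- which(vals == vals[j])
        if (length(ties) > 1L)
          j <- ties[which.min(vapply(nb[ties], n_groups, integer(1L)))]
        cur <- nb[[j]]; cur_val <- vals[j]
        trace <- c(trace, cur_val)
      }
      traces[[r]] <- trace
      if (cur_val > best_val ||
          (cur_val == best_val && !is.null(best) &&
           n_groups(cur) < n_groups(best))) {
        best <- cur; best_val <- cur_val
      }
      if (!is.null(target_accuracy) && best_val >= target_accuracy) break
    }
    structure(list(best = best, best_value = best_val, trace = traces,
                   evaluations = n_eval, restarts = restarts, seed = seed),
              class = "partition_search_result")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Exhaustive search over all contiguous partitions
#'
#' Enumerates every contiguous grouping of the base bins (`2^(n-1)`
#' partitions; 4096 for the standard 13-bin grid) and returns the
#' global optimum — the oracle against which [hill_climb()] is
#' validated.  Ties are broken toward fewer groups, then
#' lexicographically smaller boundary sets.
#'
#' @inheritParams hill_climb
#' @return A `partition_search_result` (trace holds every evaluated
#'   value in enumeration order).
#' @export
exhaustive_search <- function(objective, grid = base_grid()) {
  nb <- n_groups(grid)
  if (nb > 20L) stop("base grid too large for exhaustive enumeration")
  n_int <- nb - 1L
  best <- NULL; best_val <- -Inf
  vals <- numeric(2^n_int)
  for (code in 0:(2^n_int - 1)) {
    keep <- bitwAnd(code, 2^(seq_len(n_int) - 1L)) > 0
    p <- partition_from_keep(keep, grid)
    v <- objective(p)
    vals[code + 1] <- v
    better <- v > best_val ||
      (v == best_val && (n_groups(p) < n_groups(best) ||
        (n_groups(p) == n_groups(best) &&
         partition_key(p) < partition_key(best))))
    if (is.null(best) || better) { best <- p; best_val <- v }
  }
  structure(list(best = best, best_value = best_val, trace = list(vals),
                 evaluations = length(vals), restarts = 1L, seed = NULL),
            class = "partition_search_result")
}

#' @export
print.partition_search_result <- function(x, ...) {
  cat(sprintf("Partition search: best accuracy %.1f%% with %s (%d evaluations)\n",
              100 * x$best_value, format_partition(x$best), x$evaluations))
  invisible(x)
}
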