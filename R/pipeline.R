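#' Read and write single-particle event tables
#'
#' CSV dialect with header columns `sample_id, class_label, surface,
#' time_s, x_px, y_px, intensity, diameter_nm` (`diameter_nm` may be
#' blank until sizing).
#'
#' @param events Event `data.frame`.
#' @param path File path.
#' @return `read_events_csv()` returns the event `data.frame`;
#'   `write_events_csv()` returns `path` invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "class_label", "surface", "time_s",
                "x_px", "y_px", "intensity", "diameter_nm")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("event table lacks columns: ", paste(missing, collapse = ", "))
  ev
}

#' Bulk (single-size-group) classification analysis
#'
#' Profiles every sample over the single 30-160 nm group — the
#' conventional whole-population readout — assembles the feature
#' matrix, and reports cross-validated LDA performance.
#'
#' @param dataset An `evp_dataset`.
#' @param quantities Feature quantities (see [assemble_features()]);
#'   add `"k"` to include per-marker association coefficients, which
#'   requires kinetic fits.
#' @param scheme,k,seed Cross-validation settings (see
#'   [cross_validate()]).
#' @return List with `report` (a `classification_report`), `features`
#'   (the `feature_matrix`) and `partition`.
#' @export
run_bulk_analysis <- function(dataset, quantities = "expression",
                              scheme = "loo", k = 5, seed = NULL) {
  lo <- attr(base_grid(), "lo"); hi <- attr(base_grid(), "hi")
  partition <- size_partition(c(lo, hi))
  profiles <- sample_profiles(dataset, partition,
                              fit_kinetics = any(quantities != "expression"))
  fm <- assemble_features(profiles, quantities = quantities)
  report <- cross_validate(fm$x, fm$labels, scheme = scheme, k = k, seed = seed)
  list(report = report, features = fm, partition = partition)
}

#' Size-subtyped classification analysis
#'
#' Runs the size-resolved analysis under a fixed partition (default the
#' three empirical subpopulations EVP-S/M/L, 30-70/70-120/120-160 nm)
#' or, with `partition = "optimize"`, searches for the partition
#' maximizing the cross-validated accuracy by [hill_climb()] and
#' reports the optimized result.
#'
#' @param dataset An `evp_dataset`.
#' @param partition A [size_partition()], a partition string such as
#'   `"30-70,70-120,120-160"`, or `"optimize"`.
#' @param quantities Feature quantities for the fixed-partition report.
#' @param scheme,k,seed Cross-validation settings.
#' @param restarts,max_iter Hill-climbing settings (optimization only).
#' @param fold_seed Fold seed of the search objective.
#' @return List with `report`, `features`, `partition`, and (when
#'   optimizing) `search` (a `partition_search_result`).
#' @export
run_subtyped_analysis <- function(dataset, partition = "30-70,70-120,120-160",
                                  quantities = "expression",
                                  scheme = "loo", k = 5, seed = NULL,
                                  restarts = 10, max_iter = 100,
                                  fold_seed = 1) {
  search <- NULL
  if (identical(partition, "optimize")) {
    objective <- cv_partition_objective(dataset, k = k, fold_seed = fold_seed)
    search <- hill_climb(objective, restarts = restarts, max_iter = max_iter,
                         seed = if (is.null(seed)) 1L else seed)
    partition <- search$best
  } else if (is.character(partition)) {
    partition <- parse_partition(partition)
  }
  profiles <- sample_profiles(dataset, partition,
                              fit_kinetics = any(quantities != "expression"))
  fm <- assemble_features(profiles, quantities = quantities)
  report <- cross_validate(fm$x, fm$labels, scheme = scheme, k = k, seed = seed)
  list(report = report, features = fm, partition = partition, search = search)
}

#' Paired comparison of bulk, fixed-subtype and optimized partitions
#'
#' Evaluates the bulk single-group partition, a fixed subtyping
#' partition, and the hill-climbing-optimized partition under one
#' shared cross-validated objective (identical folds for every
#' candidate), so that the three accuracies are directly comparable.
#'
#' @param dataset An `evp_dataset`.
#' @param fixed Fixed comparison partition (default EVP-S/M/L).
#' @param k,fold_seed Objective settings (see
#'   [cv_partition_objective()]).
#' @param restarts,max_iter,seed Hill-climbing settings.
#' @return List with `accuracy` (named vector: bulk, fixed, optimized),
#'   `search`, and the three partitions.
#' @export
compare_partitions <- function(dataset, fixed = "30-70,70-120,120-160",
                               k = 5, fold_seed = 1, restarts = 10,
                               max_iter = 100, seed = 1) {
  grid <- base_grid()
  bulk <- size_partition(c(attr(grid, "lo"), attr(grid, "hi")))
  fixed <- if (is.character(fixed)) parse_partition(fixed) else fixed
  objective <- cv_partition_objective(dataset, grid = grid, k = k,
                                      fold_seed = fold_seed)
  acc_bulk <- objective(bulk)
  acc_fixed <- objective(fixed)
  search <- hill_climb(objective, grid = grid, restarts = restarts,
                       max_iter = max_iter, seed = seed)
  list(accuracy = c(bulk = acc_bulk, fixed = acc_fixed,
                    optimized = search$best_value),
       partitions = list(bulk = bulk, fixed = fixed, optimized = search$best),
       search = search)
}
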