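#' Size partitions over the 30-160 nm range
#'
#' A size partition groups the contiguous 10 nm base bins spanning the
#' analysable diameter range (30-160 nm by default) into contiguous size
#' groups.  It is represented by its ordered boundary vector; group `i`
#' covers the half-open interval `[b_i, b_{i+1})`, except the last group,
#' which is closed at the upper end so that the largest analysable
#' diameter still belongs to a group.
#'
#' @param boundaries Numeric vector of strictly increasing group
#'   boundaries.  Must start at `lo`, end at `hi`, and every boundary must
#'   lie on the base grid (a multiple of `step` away from `lo`).
#' @param lo,hi,step Base grid parameters in nm.  Defaults follow the
#'   standard 13-bin grid: 30 to 160 nm in 10 nm steps.
#' @return An object of class `size_partition`: the boundary vector with
#'   attributes `lo`, `hi` and `step`.
#' @examples
#' size_partition(c(30, 70, 120, 160))   # EVP-S / EVP-M / EVP-L
#' @export
size_partition <- function(boundaries, lo = 30, hi = 160, step = 10) {
  b <- as.numeric(boundaries)
  if (length(b) < 2L) stop("a partition needs at least two boundaries")
  if (any(!is.finite(b))) stop("boundaries must be finite")
  if (any(diff(b) <= 0)) stop("boundaries must be strictly increasing")
  if (b[1L] != lo || b[length(b)] != hi)
    stop(sprintf("partition must span [%g, %g] nm", lo, hi))
  off <- (b - lo) / step
  if (any(abs(off - round(off)) > 1e-9))
    stop(sprintf("every boundary must sit on the %g nm base grid", step))
  structure(b, class = "size_partition", lo = lo, hi = hi, step = step)
}

#' @export
print.size_partition <- function(x, ...) {
  cat("Size partition:", format_partition(x), sprintf("(%d groups)\n", n_groups(x)))
  invisible(x)
}

#' Number of groups in a partition
#' @param partition A [size_partition()].
#' @return Integer group count.
#' @export
n_groups <- function(partition) length(unclass(partition)) - 1L

#' Group labels such as `"30-70"` for each group of a partition
#' @inheritParams n_groups
#' @return Character vector, one label per group.
#' @export
group_labels <- function(partition) {
  b <- unclass(partition)
  paste0(b[-length(b)], "-", b[-1L])
}

#' Parse and format partition strings
#'
#' Partitions are serialized as comma-separated contiguous ranges, e.g.
#' `"30-70,70-120,120-160"`.  Ranges must tile the base range without
#' gaps or overlaps.
#'
#' @param x A partition string.
#' @inheritParams size_partition
#' @return `parse_partition()` returns a [size_partition()];
#'   `format_partition()` returns the string form.
#' @export
parse_partition <- function(x, lo = 30, hi = 160, step = 10) {
  parts <- strsplit(trimws(strsplit(x, ",", fixed = TRUE)[[1L]]), "-", fixed = TRUE)
  if (!length(parts)) stop("empty partition string")
  rng <- t(vapply(parts, function(p) {
    if (length(p) != 2L) stop("each range must look like 'lo-hi'")
    as.numeric(p)
  }, numeric(2L)))
  if (any(!is.finite(rng))) stop("non-numeric range in partition string")
  o <- order(rng[, 1L])
  rng <- rng[o, , drop = FALSE]
  if (any(rng[-1L, 1L] != rng[-nrow(rng), 2L]))
    stop("ranges must tile the size range without gaps or overlaps")
  size_partition(c(rng[, 1L], rng[nrow(rng), 2L]), lo = lo, hi = hi, step = step)
}

#' @rdname parse_partition
#' @param partition A [size_partition()].
#' @export
format_partition <- function(partition) {
  paste(group_labels(partition), collapse = ",")
}

#' Assign diameters to partition groups
#'
#' Groups are half-open `[lo_i, hi_i)`; the last group is closed so that
#' `hi` itself (160 nm by default) belongs to it.  Diameters outside the
#' partition range are out of range and return `NA`.
#'
#' @param diameter Numeric vector of diameters in nm.
#' @param partition A [size_partition()].
#' @return Integer vector of 1-based group indices, `NA` where the
#'   diameter falls outside the partition range.
#' @examples
#' p <- size_partition(c(30, 70, 120, 160))
#' assign_group(c(69.9, 70, 160, 25), p)   # 1, 2, 3, NA
#' @export
assign_group <- function(diameter, partition) {
  b <- unclass(partition)
  idx <- findInterval(diameter, b, rightmost.closed = TRUE)
  idx[idx < 1L | idx > n_groups(partition)] <- NA_integer_
  idx[!is.finite(diameter)] <- NA_integer_
  as.integer(idx)
}

#' Base 10 nm bin grid
#'
#' The analysable size range is pre-separated into contiguous base bins
#' (13 bins of 10 nm between 30 and 160 nm by default); every candidate
#' partition is a contiguous grouping of these bins.
#'
#' @inheritParams size_partition
#' @return A [size_partition()] with one group per base bin.
#' @examples
#' n_groups(base_grid())   # 13
#' @export
base_grid <- function(lo = 30, hi = 160, step = 10) {
  if (hi <= lo) stop("'hi' must exceed 'lo'")
  n <- (hi - lo) / step
  if (abs(n - round(n)) > 1e-9) stop("(hi - lo) must be divisible by step")
  size_partition(seq(lo, hi, by = step), lo = lo, hi = hi, step = step)
}

# internal: partition <-> logical vector of kept internal boundaries
partition_from_keep <- function(keep, grid) {
  b <- unclass(grid)
  size_partition(c(b[1L], b[-c(1L, length(b))][keep], b[length(b)]),
                 lo = attr(grid, "lo"), hi = attr(grid, "hi"),
                 step = attr(grid, "step"))
}

keep_from_partition <- function(partition, grid) {
  internal <- unclass(grid)[-c(1L, n_groups(grid) + 1L)]
  internal %in% unclass(partition)
}

#' Draw a random partition of the base bins
#'
#' Each internal base-grid boundary is kept independently with
#' probability 1/2; the outer boundaries are always kept.  Over the 13
#' standard base bins this samples uniformly from the 4096 contiguous
#' partitions.
#'
#' @param grid Base grid, a [size_partition()] from [base_grid()].
#' @return A random [size_partition()].  Uses the current RNG state; seed
#'   with [set.seed()] or [withr::with_seed()] for reproducibility.
#' @export
random_partition <- function(grid = base_grid()) {
  n <- n_groups(grid)
  if (n == 1L) return(grid)
  partition_from_keep(stats::runif(n - 1L) < 0.5, grid)
}

#' Single-boundary-toggle neighbours of a partition
#'
#' The search neighbourhood used by [hill_climb()]: one neighbour per
#' internal base-grid boundary, obtained by flipping that boundary's
#' presence (splitting a group at a base edge, or merging the two groups
#' it separates).  The resulting move graph connects all partitions.
#'
#' @param partition A [size_partition()].
#' @param grid The base grid the partition lives on.
#' @return List of `size_partition` objects, length `n_base - 1`.
#' @export
neighbors <- function(partition, grid = base_grid()) {
  keep <- keep_from_partition(partition, grid)
  lapply(seq_along(keep), function(i) {
    k <- keep
    k[i] <- !k[i]
    partition_from_keep(k, grid)
  })
}
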