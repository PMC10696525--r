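test_that("expression level is the positive fraction of the total count", {
  expect_identical(expression_level(0, 1000), 0)
  expect_equal(expression_level(250, 1000), 0.25)
  expect_error(expression_level(5, 0), "positive")
  expect_error(expression_level(-1, 10), "non-negative")
})

test_that("per-group expression sums to the bulk expression level", {
  ds <- default_five_class_scenario(seed = 13, replicates = 2, duration = 200)
  bulk <- sample_profiles(ds, size_partition(c(30, 160)))
  fine <- sample_profiles(ds, base_grid())
  agg <- stats::aggregate(expression ~ sample_id + marker, fine, sum)
  key <- paste(agg$sample_id, agg$marker)
  bkey <- paste(bulk$sample_id, bulk$marker)
  expect_equal(agg$expression[match(bkey, key)], bulk$expression,
               tolerance = 1e-12)
})

test_that("percentile normalization maps the band edges to 0 and 1", {
  x <- withr::with_seed(2, rnorm(200))
  norm <- percentile_normalize(x)
  p <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  expect_equal((p[1] - p[1]) / (p[2] - p[1]), 0)
  expect_equal(min(abs(norm$values -
    (x - norm$record[1]) / diff(norm$record))), 0)
  # value equal to p2.5 maps to 0, p97.5 to 1
  expect_equal(unname((p[1] - norm$record[1]) / diff(norm$record)), 0,
               tolerance = 1e-12)
  expect_equal(unname((p[2] - norm$record[1]) / diff(norm$record)), 1,
               tolerance = 1e-12)
  expect_error(percentile_normalize(rep(3, 10)), "at least 3 distinct")
})

test_that("percentile normalization agrees with a brute-force order-statistic oracle", {
  x <- 0:40
  # linear-interpolation percentile computed from first principles:
  # order statistic index h = (n - 1) * p + 1, interpolated
  oracle_q <- function(x, p) {
    s <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(x))] - s[lo])
  }
  norm <- percentile_normalize(x)
  q1 <- oracle_q(x, 0.025); q2 <- oracle_q(x, 0.975)
  expect_equal(unname(norm$record), c(q1, q2), tolerance = 1e-12)
  expect_equal(norm$values, (x - q1) / (q2 - q1), tolerance = 1e-12)
})

test_that("percentile normalization is affine-invariant", {
  x <- withr::with_seed(4, rexp(60))
  n1 <- percentile_normalize(x)$values
  n2 <- percentile_normalize(3.7 * x - 2)$values
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("row z-scores have mean 0 and SD 1 to machine accuracy", {
  expect_equal(zscore_rows(matrix(c(1, 2, 3), 1, 3))[1, ], c(-1, 0, 1))
  m <- withr::with_seed(5, matrix(rnorm(50), 5, 10))
  z <- zscore_rows(m)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  expect_error(zscore_rows(matrix(5, 2, 3)), "zero-SD")
})

test_that("feature counts follow markers x groups x quantities", {
  ds <- default_five_class_scenario(seed = 17, replicates = 4, duration = 300)
  three <- parse_partition("30-70,70-120,120-160")
  prof <- sample_profiles(ds, three, fit_kinetics = TRUE)
  fm <- assemble_features(prof, quantities = c("expression", "k"))
  expect_identical(ncol(fm$x), 5L * 3L * 2L)
  expect_identical(nrow(fm$x), 20L)
  # bulk partition with both quantities: 10 features
  prof_bulk <- sample_profiles(ds, size_partition(c(30, 160)),
                               fit_kinetics = TRUE)
  fm_bulk <- assemble_features(prof_bulk, quantities = c("expression", "k"))
  expect_identical(ncol(fm_bulk$x), 10L)
  # normalization record present for every feature
  expect_identical(rownames(fm$normalization), colnames(fm$x))
  # kinetic quantities without fits are refused
  prof2 <- sample_profiles(ds, three)
  expect_error(assemble_features(prof2, quantities = c("expression", "k")),
               "kinetic")
})

test_that("constant feature columns are dropped with a warning", {
  prof <- data.frame(
    sample_id = rep(sprintf("s%d", 1:6), each = 2),
    class_label = rep(c("a", "b"), each = 6),
    marker = rep(c("m1", "m2"), 6),
    group = "30-160",
    expression = c(rbind(seq(0.1, 0.6, by = 0.1), 0.5)),
    k = NA_real_, n_max = NA_real_)
  attr(prof, "partition") <- size_partition(c(30, 160))
  class(prof) <- c("sample_profiles", "data.frame")
  expect_warning(fm <- assemble_features(prof), "m2")
  expect_identical(colnames(fm$x), "m1:30-160:expression")
})

test_that("z-score heatmap rows are standardized across classes", {
  ds <- default_five_class_scenario(seed = 19, replicates = 3, duration = 200)
  prof <- sample_profiles(ds, parse_partition("30-70,70-120,120-160"))
  z <- zscore_heatmap(prof)
  expect_identical(dim(z), c(15L, 5L))
  expect_lt(max(abs(rowMeans(z))), 1e-12)
})
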