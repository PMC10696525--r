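test_that("zero rate or zero duration produce no events", {
  spec <- flat_spec(k = 0)
  run <- simulate_marker_run(spec, "CD63", 900, seed = 1)
  expect_identical(nrow(run$events), 0L)
  run0 <- simulate_total_run(flat_spec(), 0, seed = 1)
  expect_identical(nrow(run0$events), 0L)
  expect_error(simulate_marker_run(flat_spec(), "CD63", -1), "positive")
  expect_error(simulate_marker_run(flat_spec(), "nope", 10), "unknown marker")
})

test_that("mean event count matches the closed-form saturating expectation", {
  spec <- flat_spec(k = 0.0070, n_max = 500)
  counts <- vapply(1:200, function(s)
    nrow(simulate_marker_run(spec, "CD63", 900, seed = s)$events), numeric(1))
  expected <- 500 * (1 - exp(-0.0070 * 900))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
  # the observed count never exceeds the saturation count
  expect_true(all(counts <= 500))
})

test_that("cumulative counts are non-decreasing and times ordered", {
  run <- simulate_marker_run(flat_spec(), "CD63", 900, seed = 3)
  expect_true(all(diff(run$events$time_s) >= 0))
  expect_true(all(run$events$time_s > 0 & run$events$time_s <= 900))
})

test_that("positivity restricted below 70 nm yields only sub-70 nm diameters", {
  pos <- ifelse(unclass(base_grid())[-14] < 70, 1, 0)
  spec <- class_spec("x", size_dist_lnorm(),
                     list(marker_profile("CD63", pos, k = 0.01, n_max = 300)))
  run <- simulate_marker_run(spec, "CD63", 600, seed = 2)
  expect_gt(nrow(run$events), 0)
  expect_true(all(run$events$diameter_nm < 70))
  expect_true(all(run$events$diameter_nm >= 30))
})

test_that("same seed gives identical runs; total run dominates marker runs", {
  spec <- flat_spec()
  expect_identical(simulate_total_run(spec, 300, seed = 9),
                   simulate_total_run(spec, 300, seed = 9))
  expect_identical(simulate_marker_run(spec, "CD63", 300, seed = 9),
                   simulate_marker_run(spec, "CD63", 300, seed = 9))
  # total surface has larger n_max and k, so its mean count dominates
  m_tot <- mean(vapply(1:200, function(s)
    nrow(simulate_total_run(spec, 300, seed = s)$events), numeric(1)))
  m_mark <- mean(vapply(1:200, function(s)
    nrow(simulate_marker_run(spec, "CD63", 300, seed = 1000 + s)$events),
    numeric(1)))
  expect_gt(m_tot, m_mark)
})

test_that("calibration runs follow the noiseless cubic law and ordering", {
  cal <- simulate_calibration_run(cv = 0, seed = 1, instrument_c = 1)
  i100 <- cal$intensity[cal$nominal_diameter_nm == 100]
  expect_true(all(i100 == 1e6))
  means <- tapply(cal$intensity, cal$nominal_diameter_nm, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
  noisy <- simulate_calibration_run(cv = 0.1, seed = 2)
  m2 <- tapply(noisy$intensity, noisy$nominal_diameter_nm, mean)
  expect_true(all(diff(m2[order(as.numeric(names(m2)))]) > 0))
  expect_error(simulate_calibration_run(n_per_size = 0), "at least 1")
  expect_error(simulate_calibration_run(cv = -0.1), "non-negative")
  expect_error(simulate_calibration_run(diameters = c(-30, 50)), "positive")
})

test_that("the default scenario has the documented structure", {
  ds <- default_five_class_scenario(seed = 4, replicates = 2, duration = 200)
  expect_identical(nrow(ds$samples), 10L)
  expect_identical(length(unique(ds$samples$class_label)), 5L)
  # 6 runs per sample: 5 markers + 1 total surface
  runs <- unique(ds$events[, c("sample_id", "surface")])
  expect_identical(nrow(runs), 10L * 6L)
  expect_setequal(unique(ds$events$surface),
                  c("CD63", "EpCAM", "HER2", "PSMA", "PTK7", "total"))
  # reproducibility from the seed
  ds2 <- default_five_class_scenario(seed = 4, replicates = 2, duration = 200)
  expect_identical(ds$events, ds2$events)
  # diameters stay inside the truncation range
  expect_true(all(ds$events$diameter_nm >= 30 & ds$events$diameter_nm <= 160))
})

test_that("healthy-class mean expression is below every cancer class for every marker", {
  ds <- default_five_class_scenario(seed = 8, replicates = 6, duration = 400)
  bulk <- size_partition(c(30, 160))
  prof <- sample_profiles(ds, bulk)
  agg <- stats::aggregate(expression ~ class_label + marker, prof, mean)
  for (m in unique(agg$marker)) {
    sub <- agg[agg$marker == m, ]
    healthy <- sub$expression[sub$class_label == "healthy"]
    cancer <- sub$expression[sub$class_label != "healthy"]
    expect_true(all(healthy < cancer))
  }
})

test_that("empirical mean cumulative curve converges to the Langmuir form", {
  spec <- flat_spec(k = 0.005, n_max = 300)
  tgrid <- seq(10, 600, by = 10)
  reps <- c(10, 80)
  dev <- vapply(reps, function(R) {
    curves <- vapply(1:R, function(s) {
      tt <- simulate_marker_run(spec, "CD63", 600, seed = 5000 + s)$events$time_s
      vapply(tgrid, function(g) sum(tt <= g), numeric(1))
    }, numeric(length(tgrid)))
    expected <- 300 * (1 - exp(-0.005 * tgrid))
    max(abs(rowMeans(curves) - expected))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2] / 300, 0.03)
})
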