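make_gaussian_classes <- function(n_per = 20, sep = 4, p = 3, K = 3, seed = 1) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(K), function(k) {
      mu <- rep(0, p); mu[min(k, p)] <- sep * (k - 1)
      matrix(rnorm(n_per * p), n_per, p) + rep(mu, each = n_per)
    }))
    list(x = x, y = rep(paste0("c", seq_len(K)), each = n_per))
  })
}

test_that("LDA separates well-separated Gaussian classes", {
  d <- make_gaussian_classes(sep = 6)
  model <- fit_lda(d$x, d$y)
  expect_identical(unname(predict(model, d$x)), d$y)
  # two spherical classes: boundary is the perpendicular bisector of means
  d2 <- make_gaussian_classes(n_per = 50, sep = 5, p = 2, K = 2, seed = 3)
  m2 <- fit_lda(d2$x, d2$y, shrinkage = "none")
  mid <- colMeans(m2$means)
  dirv <- m2$means[2, ] - m2$means[1, ]
  probe <- rbind(mid + 0.5 * dirv, mid - 0.5 * dirv)
  expect_identical(unname(predict(m2, probe)), c("c2", "c1"))
  expect_error(fit_lda(d$x[1:20, ], rep("only", 20)), "2 classes")
  expect_error(fit_lda(d$x[1:3, ], c("a", "a", "b")), "2 samples")
})

test_that("shrinkage LDA matches MASS::lda when shrinkage is off", {
  d <- make_gaussian_classes(n_per = 30, sep = 2.5, K = 3, seed = 5)
  ours <- predict(fit_lda(d$x, d$y, shrinkage = "none", priors = "equal"), d$x)
  mass <- as.character(predict(MASS::lda(d$x, grouping = d$y,
                                         prior = rep(1 / 3, 3)), d$x)$class)
  expect_gt(mean(ours == mass), 0.99)
})

test_that("shrinkage keeps the model defined when features outnumber samples", {
  withr::with_seed(6, {
    x <- matrix(rnorm(20 * 50), 20, 50)
    x[1:10, 1] <- x[1:10, 1] + 5
    y <- rep(c("a", "b"), each = 10)
  })
  expect_error(fit_lda(x, y, shrinkage = "none"), "singular")
  model <- fit_lda(x, y, shrinkage = "lw")
  expect_true(model$lambda > 0)
  expect_identical(unname(predict(model, x)), y)
})

test_that("cross-validation reports are coherent and reproducible", {
  d <- make_gaussian_classes(n_per = 12, sep = 8, K = 4, seed = 7)
  rep1 <- cross_validate(d$x, d$y, scheme = "kfold", k = 4, seed = 42)
  rep2 <- cross_validate(d$x, d$y, scheme = "kfold", k = 4, seed = 42)
  expect_identical(rep1$accuracy, rep2$accuracy)
  expect_identical(rep1$probability_matrix, rep2$probability_matrix)
  # perfectly separated clusters: accuracy 1, every AUC 1
  expect_identical(rep1$accuracy, 1)
  expect_true(all(rep1$auc == 1))
  # probability-matrix rows sum to 1
  expect_equal(unname(rowSums(rep1$probability_matrix)), rep(1, 4),
               tolerance = 1e-9)
  # class-size-weighted diagonal equals the overall accuracy
  sizes <- table(d$y)[rownames(rep1$probability_matrix)]
  expect_equal(sum(diag(rep1$probability_matrix) * sizes) / sum(sizes),
               rep1$accuracy)
  expect_error(cross_validate(d$x, d$y, scheme = "kfold", k = 13), "smallest")
})

test_that("permuted labels give chance-level leave-one-out accuracy", {
  d <- make_gaussian_classes(n_per = 10, sep = 5, K = 5, seed = 8)
  accs <- withr::with_seed(9, vapply(1:30, function(i) {
    cross_validate(d$x, sample(d$y), scheme = "loo")$accuracy
  }, numeric(1)))
  expect_lt(abs(mean(accs) - 0.2), 0.1)
})

test_that("one-vs-rest AUC equals the brute-force concordance count", {
  withr::with_seed(10, {
    scores <- cbind(a = rnorm(40), b = rnorm(40), c = rnorm(40))
    labels <- sample(c("a", "b", "c"), 40, replace = TRUE)
  })
  auc <- roc_auc_ovr(scores, labels)
  brute <- vapply(colnames(scores), function(cl) {
    pos <- which(labels == cl); neg <- which(labels != cl)
    s <- 0
    for (i in pos) for (j in neg)
      s <- s + (scores[i, cl] > scores[j, cl]) + 0.5 * (scores[i, cl] == scores[j, cl])
    s / (length(pos) * length(neg))
  }, numeric(1))
  expect_equal(auc, brute, tolerance = 1e-12)
})

test_that("AUC handles ties, perfect separation and monotone transforms", {
  labels <- rep(c("a", "b"), each = 5)
  flat <- cbind(a = rep(1, 10), b = rep(1, 10))
  expect_equal(unname(roc_auc_ovr(flat, labels)), c(0.5, 0.5))
  sep <- cbind(a = c(6:10, 1:5), b = c(1:5, 6:10))
  expect_equal(unname(roc_auc_ovr(sep, labels)), c(1, 1))
  # strictly monotone transform leaves AUC unchanged
  withr::with_seed(11, s <- cbind(a = rnorm(20), b = rnorm(20)))
  l <- rep(c("a", "b"), 10)
  expect_equal(roc_auc_ovr(s, l), roc_auc_ovr(exp(s), l))
  expect_error(roc_auc_ovr(flat, rep("a", 10)), "2 classes")
})

test_that("AUC agrees with pROC on a random instance", {
  withr::with_seed(12, {
    sc <- cbind(a = rnorm(40), b = rnorm(40))
    y <- sample(c("a", "b"), 40, replace = TRUE)
  })
  ours <- roc_auc_ovr(sc, y)[["a"]]
  ref <- as.numeric(pROC::auc(pROC::roc(y == "a", sc[, "a"], quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
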