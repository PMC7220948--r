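test_that("auc reproduces hand-counted examples", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5) # all ties
  expect_equal(auc(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1.0) # scores = labels
  expect_error(auc(c(1, 1, 1), c(0.1, 0.2, 0.3)), "both classes")
})

test_that("auc equals the pairwise counting oracle on random tied data", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
    expect_equal(auc(labels, scores), auc_oracle(labels, scores),
                 tolerance = 1e-14)
  }
})

test_that("a label-equal gene yields near-certain probabilities via the ridge fallback", {
  y <- rep(c(0, 1), each = 10)
  ds <- make_ds(rbind(g1 = y + 8), y)
  expect_warning(m <- fit_predictor(ds, "g1", "mlr"), "separation")
  p <- predict_proba(m, ds)
  expect_true(all(p[y == 1] >= 0.99))
  expect_true(all(p[y == 0] <= 0.01))
})

test_that("constant genes and single-class data are errors", {
  y <- rep(c(0, 1), each = 5)
  ds <- make_ds(rbind(g1 = rep(4, 10), g2 = rnorm(10)), y)
  expect_error(fit_predictor(ds, "g1", "mlr"), "zero-variance")
  ds2 <- make_ds(rbind(g2 = rnorm(10)), rep(1L, 10))
  expect_error(fit_predictor(ds2, "g2", "mlr"), "single class")
  m <- fit_predictor(ds, "g2", "mlr")
  expect_error(predict_proba(m, make_ds(rbind(other = rnorm(4)), c(0, 1, 0, 1))),
               "missing gene")
})

test_that("mlr probabilities follow the logistic link and are reproducible", {
  ds <- random_ds(n = 50, n_genes = 3, informative = 1, delta = 1.5, seed = 21)
  m <- fit_predictor(ds, rownames(ds$values), "mlr")
  p1 <- predict_proba(m, ds)
  expect_identical(p1, predict_proba(m, ds))
  expect_true(all(p1 >= 0 & p1 <= 1))
  # hand-build a model with zero weights: probability is exactly 0.5
  m0 <- m
  m0$fit$coef[] <- 0
  expect_equal(unname(predict_proba(m0, ds)), rep(0.5, 50))
  # monotone in a positive-coefficient gene
  g <- names(which(m$fit$coef[-1] > 0))[1]
  ds_hi <- ds
  ds_hi$values[g, ] <- ds_hi$values[g, ] + 1
  expect_true(all(predict_proba(m, ds_hi) >= p1 - 1e-12))
})

test_that("training AUC exceeds validation AUC on average (optimism)", {
  gap <- vapply(1:20, function(s) {
    ds <- random_ds(n = 100, n_genes = 12, informative = 3, delta = 0.8,
                    seed = 300 + s)
    sp <- stratified_split(ds, split_spec(c(2, 1), 1, master_seed = s), 1)
    m <- fit_predictor(ds[, sp$train], rownames(ds$values), "mlr")
    y <- outcomes(ds)
    auc(y[sp$train], predict_proba(m, ds[, sp$train])) -
      auc(y[sp$valid], predict_proba(m, ds[, sp$valid]))
  }, numeric(1))
  expect_gt(mean(gap), 0)
})

test_that("linear SVM and random forest comparators learn informative data", {
  ds <- random_ds(n = 80, n_genes = 5, informative = 2, delta = 2, seed = 31)
  y <- outcomes(ds)
  for (kind in c("linear_svm", "rf")) {
    m <- fit_predictor(ds, rownames(ds$values), kind, seed = 31)
    expect_gt(auc(y, predict_proba(m, ds)), 0.8)
  }
  # rf is seed-reproducible
  m1 <- fit_predictor(ds, rownames(ds$values), "rf", seed = 5)
  m2 <- fit_predictor(ds, rownames(ds$values), "rf", seed = 5)
  expect_identical(predict_proba(m1, ds), predict_proba(m2, ds))
})
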