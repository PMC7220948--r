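test_that("orthogonal centred features have VIF exactly 1", {
  x <- cbind(a = c(1, -1, 1, -1, 1, -1), b = c(1, 1, -1, -1, 0, 0))
  expect_equal(sum(x[, 1] * x[, 2]), 0) # centred and orthogonal by construction
  expect_equal(vif(x, 1), 1.0)
  expect_equal(vif(x, 2), 1.0)
})

test_that("an exact linear combination returns the infinity sentinel", {
  set.seed(1)
  x <- cbind(rnorm(20), rnorm(20))
  x <- cbind(x, x[, 1] - 2 * x[, 2])
  expect_identical(vif(x, 3), Inf)
  expect_identical(vif(x, 1), Inf) # collinearity is symmetric among the trio
})

test_that("vif matches the normal-equations oracle on random designs", {
  for (trial in 1:30) {
    set.seed(trial)
    p <- sample(2:8, 1)
    x <- corr_pool(n = 50, p = max(p, 2), rho = runif(1, 0, 0.95), seed = trial)
    j <- sample(seq_len(ncol(x)), 1)
    expect_equal(vif(x, j), vif_oracle(x, j), tolerance = 1e-8)
  }
})

test_that("vif agrees with the car package on a standard regression design", {
  skip_if_not_installed("car")
  set.seed(5)
  x <- corr_pool(n = 60, p = 4, rho = 0.8, seed = 5)
  d <- data.frame(y = rnorm(60), x)
  cv <- car::vif(lm(y ~ g1 + g2 + g3 + g4, data = d))
  ours <- vapply(1:4, function(j) vif(x, j), numeric(1))
  expect_equal(unname(ours), unname(cv), tolerance = 1e-8)
})

test_that("vif preconditions: p >= 2 and n > p", {
  expect_error(vif(matrix(rnorm(10), 10, 1), 1), "at least 2")
  expect_error(vif(matrix(rnorm(12), 3, 4), 1), "n <= p")
})

test_that("mutually orthogonal rankings are selected unchanged with VIF 1", {
  # orthogonal polynomial columns: centred and mutually orthogonal exactly
  x <- unclass(stats::poly(1:30, 3))[, 1:3]
  colnames(x) <- paste0("g", 1:3)
  ds <- make_ds(t(x) + 8, rep(c(0, 1), each = 15))
  rep <- select_by_vif(ds, new_ranking(c("g1", "g2", "g3")), threshold = 10)
  expect_equal(rep$selected_genes, c("g1", "g2", "g3"))
  expect_equal(unname(rep$vif_values), rep(1, 3), tolerance = 1e-8)
  expect_equal(nrow(rep$rejected), 0L)
})

test_that("a near-duplicate gene is rejected with the offending VIF recorded", {
  set.seed(3)
  a <- rnorm(50); c_ <- rnorm(50)
  b <- a + rnorm(50, sd = 0.02) # r ~ 0.999
  ds <- make_ds(rbind(A = a, B = b, C = c_) + 8, rep(c(0, 1), 25))
  rep <- select_by_vif(ds, new_ranking(c("A", "B", "C")), threshold = 10)
  expect_equal(rep$selected_genes, c("A", "C"))
  expect_equal(rep$rejected$gene_id, "B")
  # the recorded VIF matches the oracle on the standardised tentative set
  x <- scale(cbind(a, b))
  expect_gt(vif_oracle(x, 2), 10)
  expect_equal(rep$rejected$max_vif_if_added,
               max(vif_oracle(x, 1), vif_oracle(x, 2)), tolerance = 1e-6)
})

test_that("every selected set satisfies its own VIF bound (audit property)", {
  for (s in 1:10) {
    x <- corr_pool(n = 50, p = 8, rho = 0.97, seed = s + 100)
    ds <- make_ds(t(x) + 8, rep(c(0, 1), 25))
    rep <- select_by_vif(ds, new_ranking(colnames(x)), threshold = 5)
    xs <- scale(t(ds$values[rep$selected_genes, , drop = FALSE]))
    if (length(rep$selected_genes) >= 2) {
      audit <- vapply(seq_along(rep$selected_genes),
                      function(j) vif_oracle(xs, j), numeric(1))
      expect_lt(max(audit), 5)
    }
    expect_true(all(rep$vif_values >= 1 - 1e-10))
  }
})

test_that("selected-set size is non-decreasing in the threshold", {
  x <- corr_pool(n = 50, p = 8, rho = 0.9, seed = 77)
  ds <- make_ds(t(x) + 8, rep(c(0, 1), 25))
  sizes <- vapply(c(5, 10, 100), function(th)
    length(select_by_vif(ds, new_ranking(colnames(x)), th)$selected_genes),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("backward elimination also ends below the threshold", {
  x <- corr_pool(n = 50, p = 6, rho = 0.95, seed = 8)
  ds <- make_ds(t(x) + 8, rep(c(0, 1), 25))
  rep <- select_by_vif(ds, new_ranking(colnames(x)), 10, method = "backward")
  expect_true(all(rep$vif_values < 10))
})

test_that("select_by_vif rejects invalid thresholds and empty rankings", {
  ds <- random_ds(n = 20, n_genes = 3, seed = 1)
  expect_error(select_by_vif(ds, new_ranking(character(0))), "empty")
  expect_error(select_by_vif(ds, new_ranking(rownames(ds$values)), threshold = 1),
               "threshold")
})
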