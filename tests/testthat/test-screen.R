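test_that("identical groups give t = 0, p = 1 and fail the p-value cut", {
  ds <- make_ds(rbind(c(1, 2, 3, 1, 2, 3)) + 6, c(0, 0, 0, 1, 1, 1))
  res <- screen_genes(ds)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$passed_pvalue)
  expect_true(res$passed_intensity)
})

test_that("intensity rule 'both' keeps a gene high in one group, 'any' drops it", {
  # medians 4.9 (group 0) and 8.0 (group 1)
  x <- rbind(c(4.8, 4.9, 5.0, 7.9, 8.0, 8.1))
  ds <- make_ds(x, c(0, 0, 0, 1, 1, 1))
  expect_true(screen_genes(ds, intensity_rule = "both")$passed_intensity)
  expect_false(screen_genes(ds, intensity_rule = "any")$passed_intensity)
  # low in both groups: dropped under either rule, and never t-tested
  lo <- make_ds(rbind(c(1, 2, 1, 2, 1, 2)), c(0, 0, 0, 1, 1, 1))
  r <- screen_genes(lo, intensity_rule = "both")
  expect_false(r$passed_intensity)
  expect_true(is.na(r$p_value))
})

test_that("a near-separated gene passes and matches the pooled-variance formula", {
  set.seed(42)
  eps <- rnorm(8, sd = 0.01)
  vals <- c(0, 0, 0, 0, 1, 1, 1, 1) + eps + 8
  ds <- make_ds(rbind(vals), c(0, 0, 0, 0, 1, 1, 1, 1))
  res <- screen_genes(ds)
  # textbook pooled-variance t on the jittered values
  a <- vals[1:4]; b <- vals[5:8]
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_ref <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$t_stat, t_ref, tolerance = 1e-12)
  expect_lt(res$p_value, 0.005)
  expect_true(res$passed_pvalue)
})

test_that("t statistics match the closed form on random genes within 1e-10", {
  ds <- random_ds(n = 30, n_genes = 40, informative = 5, delta = 1, seed = 3)
  ds$values <- ds$values + 8
  res <- screen_genes(ds, p_threshold = 1)
  y <- outcomes(ds)
  for (i in sample(seq_len(40), 10)) {
    tt <- t.test(ds$values[i, y == 1], ds$values[i, y == 0], var.equal = TRUE)
    expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
  # welch variant matches Welch's t.test
  resw <- screen_genes(ds, p_threshold = 1, t_variant = "welch")
  tt <- t.test(ds$values[1, y == 1], ds$values[1, y == 0])
  expect_equal(resw$p_value[1], tt$p.value, tolerance = 1e-10)
})

test_that("screening is invariant to sample order and monotone in p_threshold", {
  ds <- random_ds(n = 24, n_genes = 30, informative = 3, delta = 1.5, seed = 9)
  ds$values <- ds$values + 8
  perm <- sample(colnames(ds$values))
  r1 <- screen_genes(ds)
  r2 <- screen_genes(ds[, perm])
  expect_equal(r1$t_stat, r2$t_stat)
  expect_equal(r1$p_value, r2$p_value)
  counts <- vapply(c(0.001, 0.01, 0.05, 0.2, 1), function(p)
    sum(screen_genes(ds, p_threshold = p)$passed), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("screen preconditions are enforced", {
  ds <- make_ds(rbind(c(1, 2, 3, 4)), c(0, 1, 1, 1))
  expect_error(screen_genes(ds), "at least 2 samples")
  ds2 <- make_ds(rbind(c(1, 2, 3, 4)), c(0, 0, 1, 1))
  expect_error(screen_genes(ds2, p_threshold = 0), "p_threshold")
})

test_that("passing_genes orders by p-value with stable ties and allows empty", {
  scr <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    median_g0 = 8, median_g1 = 8, passed_intensity = TRUE,
    t_stat = 1, p_value = c(0.004, 0.2, 0.001, 0.004),
    passed_pvalue = c(TRUE, FALSE, TRUE, TRUE),
    passed = c(TRUE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  class(scr) <- c("gene_screen", "data.frame")
  rk <- passing_genes(scr)
  expect_equal(rk$ordered_genes, c("c", "a", "d")) # tie a/d keeps input order
  scr$passed <- FALSE
  expect_equal(length(passing_genes(scr)), 0L)
})
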