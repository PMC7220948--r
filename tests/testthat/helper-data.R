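# Build a small expr_dataset from a genes x samples matrix and outcome vector.
make_ds <- function(values, outcome, strata = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  ann <- data.frame(sample_id = colnames(values), outcome = outcome,
                    stringsAsFactors = FALSE)
  if (!is.null(strata)) ann$strata <- strata
  expr_dataset(values, ann)
}

# Random two-group dataset: `informative` genes get a mean shift `delta`
# between outcome groups, the rest are independent noise.
random_ds <- function(n = 60, n_genes = 10, informative = 1, delta = 2,
                      prevalence = 0.5, seed = 1) {
  set.seed(seed)
  y <- as.integer(seq_len(n) <= round(n * prevalence))
  y <- sample(y)
  x <- matrix(rnorm(n_genes * n), nrow = n_genes)
  if (informative > 0) {
    x[seq_len(informative), ] <- x[seq_len(informative), , drop = FALSE] +
      rep(ifelse(y == 1, delta / 2, -delta / 2), each = informative)
  }
  rownames(x) <- c(if (informative > 0) paste0("inf", seq_len(informative)),
                   paste0("noise", seq_len(n_genes - informative)))
  make_ds(x, y)
}

# Brute-force AUC oracle: all (positive, negative) pairs, ties counted 1/2.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Normal-equations OLS oracle for VIF: explicit (X'X)^-1 X'y regression of
# column j on the others plus an intercept, independent of lm/lm.fit.
vif_oracle <- function(x, j) {
  y <- x[, j]
  xo <- cbind(1, x[, -j, drop = FALSE])
  beta <- solve(crossprod(xo), crossprod(xo, y))
  res <- y - xo %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  if (r2 >= 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

# Correlated gene pool (samples x p) with a mix of near-duplicates and
# independent columns, for exercising VIF selection.
corr_pool <- function(n = 50, p = 8, rho = 0.9, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(n * p), n, p)
  for (j in seq(2, p, by = 2)) {
    base[, j] <- sqrt(rho) * base[, j - 1] + sqrt(1 - rho) * base[, j]
  }
  colnames(base) <- paste0("g", seq_len(p))
  base
}
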