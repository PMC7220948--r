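#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney identity: AUC = U / (n1 * n0), the fraction
#' of (positive, negative) pairs in which the positive sample receives the
#' higher score, counting ties as 1/2. Implemented with midranks, which is
#' exactly equivalent to pairwise counting.
#'
#' @param labels 0/1 outcome per sample; both classes must be present.
#' @param scores numeric score per sample (higher = more outcome-1-like).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a prediction model on a gene subset
#'
#' Standardises the chosen genes on training statistics and fits the
#' requested classifier. `"mlr"` (the default) is maximum-likelihood
#' multiple logistic regression with an intercept and no penalty; when the
#' fit fails to converge or the classes are completely separated, the model
#' falls back to a vanishingly small ridge penalty (lambda = 1e-6) with a
#' warning, which leaves non-degenerate fits untouched but keeps separable
#' ones finite. `"linear_svm"` is a C = 1 linear-kernel SVM whose signed
#' margin is mapped through the logistic function; `"rf"` is a 500-tree
#' random forest with sqrt(p) candidate features per node.
#'
#' @param ds_train an [expr_dataset]; >= 2 samples per class.
#' @param genes gene ids to use as predictors (all must be present).
#' @param model_kind `"mlr"`, `"linear_svm"` or `"rf"`.
#' @param seed integer seed (only the random forest consumes randomness).
#' @return a `sig_model` object usable with [predict_proba()].
#' @export
fit_predictor <- function(ds_train, genes, model_kind = c("mlr", "linear_svm", "rf"),
                          seed = 1L) {
  model_kind <- match.arg(model_kind)
  y <- outcomes(ds_train)
  if (length(unique(y)) < 2) stop("training data has a single class")
  mg <- match(genes, gene_ids(ds_train))
  if (anyNA(mg)) stop("missing gene(s) in training data: ",
                      paste(genes[is.na(mg)], collapse = ", "))
  x <- t(ds_train$values[genes, , drop = FALSE])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  xs <- standardise_cols(x, center, scale)

  fitobj <- switch(model_kind,
    mlr = fit_mlr(xs, y),
    linear_svm = e1071::svm(xs, factor(y, levels = c(0, 1)),
                            kernel = "linear", cost = 1, scale = FALSE),
    rf = {
      set.seed(seed)
      randomForest::randomForest(
        xs, factor(y, levels = c(0, 1)), ntree = 500,
        mtry = max(1, floor(sqrt(ncol(xs)))))
    })
  structure(list(model_kind = model_kind, gene_ids = genes,
                 center = center, scale = scale, fit = fitobj,
                 seed = as.integer(seed)),
            class = "sig_model")
}

# Unpenalised logistic regression, with a tiny-ridge fallback on
# non-convergence / complete separation.
fit_mlr <- function(xs, y) {
  sep_warn <- FALSE
  g <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, xs), y,
                   family = stats::binomial()),
    warning = function(w) {
      sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  eps <- 1e-8
  degenerate <- !g$converged || sep_warn ||
    any(g$fitted.values > 1 - eps) || any(g$fitted.values < eps)
  if (!degenerate) {
    return(list(kind = "glm", coef = g$coefficients))
  }
  warning("logistic fit did not converge cleanly (likely complete separation); ",
          "refit with ridge penalty lambda = 1e-6")
  xfit <- xs
  if (ncol(xfit) == 1) {
    # glmnet needs >= 2 columns; pad with an all-zero dummy whose
    # coefficient is identically 0 and is dropped below
    xfit <- cbind(xfit, `.pad.` = 0)
  }
  gn <- glmnet::glmnet(xfit, y, family = "binomial", alpha = 0,
                       lambda = 1e-6, standardize = FALSE)
  cf <- as.numeric(stats::coef(gn))[seq_len(ncol(xs) + 1)]
  names(cf) <- c("(Intercept)", colnames(xs))
  list(kind = "ridge", coef = cf)
}

#' Predicted probability of outcome 1
#'
#' @param model a `sig_model` from [fit_predictor()].
#' @param ds an [expr_dataset] containing every gene of the model.
#' @return numeric vector in \[0, 1\], named by sample id.
#' @export
predict_proba <- function(model, ds) {
  mg <- match(model$gene_ids, gene_ids(ds))
  if (anyNA(mg)) stop("missing gene(s) in prediction data: ",
                      paste(model$gene_ids[is.na(mg)], collapse = ", "))
  x <- t(ds$values[model$gene_ids, , drop = FALSE])
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  p <- switch(model$model_kind,
    mlr = {
      cf <- model$fit$coef
      stats::plogis(drop(cbind(1, xs) %*% cf))
    },
    linear_svm = {
      dv <- attr(stats::predict(model$fit, xs, decision.values = TRUE),
                 "decision.values")
      m <- drop(dv)
      # decision value sign depends on which class e1071 treated as first
      if (grepl("^0", colnames(dv)[1])) m <- -m
      stats::plogis(m)
    },
    rf = stats::predict(model$fit, xs, type = "prob")[, "1"])
  stats::setNames(as.numeric(p), sample_ids(ds))
}

#' @export
print.sig_model <- function(x, ...) {
  cat(sprintf("sig_model (%s): %d genes\n", x$model_kind, length(x$gene_ids)))
  invisible(x)
}
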