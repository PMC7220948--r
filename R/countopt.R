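#' Cross-validated AUC as a function of gene count
#'
#' For each candidate count c, fits the chosen model on the top-c ranked
#' genes within each of k outcome-stratified folds and averages the
#' validation-fold AUCs. Fold assignment is derived deterministically from
#' `seed`, and the same folds are reused for every count so the curve
#' reflects the gene count alone.
#'
#' @param ds an [expr_dataset] (the training data).
#' @param ranking a `gene_ranking`; `counts` must not exceed its length.
#' @param counts increasing vector of gene counts to evaluate.
#' @param k number of CV folds (default 10); both classes need >= k samples.
#' @param model_kind classifier passed to [fit_predictor()].
#' @param seed integer seed for fold assignment.
#' @return a `count_curve`: list with `counts`, `cv_auc`, and (after
#'   [choose_count()]) `diffs`, `diff_threshold`, `chosen_count`.
#' @export
cv_auc_curve <- function(ds, ranking, counts, k = 10,
                         model_kind = c("mlr", "linear_svm", "rf"),
                         seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(k >= 2, all(counts >= 1), all(diff(counts) > 0))
  if (max(counts) > length(ranking)) {
    stop("counts exceed ranking length (", length(ranking), ")")
  }
  y <- outcomes(ds)
  if (min(table(y)) < k) stop("each class needs at least k samples; reduce k")
  fold <- stratified_folds(y, k, derive_seed(seed, 0L))
  sids <- sample_ids(ds)

  cv_auc <- vapply(counts, function(cc) {
    g <- utils::head(ranking$ordered_genes, cc)
    fold_auc <- vapply(seq_len(k), function(f) {
      tr <- sids[fold != f]; va <- sids[fold == f]
      yv <- y[va]
      if (length(unique(yv)) < 2) {
        stop("a CV fold contains a single class; use a smaller k")
      }
      m <- fit_predictor(ds[, tr], g, model_kind,
                         seed = derive_seed(seed, f))
      auc(yv, predict_proba(m, ds[, va]))
    }, numeric(1))
    mean(fold_auc)
  }, numeric(1))

  structure(list(counts = as.integer(counts), cv_auc = cv_auc,
                 diffs = NULL, diff_threshold = NULL, chosen_count = NULL,
                 k = k, model_kind = model_kind),
            class = "count_curve")
}

#' Choose the operating gene count by the top-quartile differential-AUC rule
#'
#' First differences of the CV-AUC curve over increasing counts are sorted in
#' descending order; the value at rank `ceiling(quantile * n_diffs)` — the
#' smallest difference still inside the top quantile (default top 25%) — is
#' the threshold, and the chosen count is the largest count whose incoming
#' difference still meets it, i.e. the last count at which the curve is
#' still gaining at a top-quartile rate. When several differences tie at the
#' threshold the largest qualifying count wins.
#'
#' @param curve a `count_curve` with at least 3 counts.
#' @param quantile top fraction of sorted differences that defines the
#'   threshold (default 0.25).
#' @return the `count_curve` with `diffs`, `diff_threshold` and
#'   `chosen_count` filled in.
#' @export
choose_count <- function(curve, quantile = 0.25) {
  stopifnot(inherits(curve, "count_curve"), quantile > 0, quantile <= 1)
  if (length(curve$counts) < 3) stop("need at least 3 counts to choose from")
  d <- diff(curve$cv_auc)
  sorted <- sort(d, decreasing = TRUE)
  r <- ceiling(quantile * length(d))
  thr <- sorted[r]
  # d[i] is the gain arriving at counts[i + 1]; a count must be genuinely
  # gaining (d > 0) to qualify, so a flat plateau never drags the choice out
  # even when zero diffs fall inside the top quartile
  qualifying <- which(d >= thr & d > 0)
  curve$diffs <- d
  curve$diff_threshold <- thr
  curve$chosen_count <- if (length(qualifying) == 0) {
    curve$counts[1]
  } else {
    curve$counts[max(qualifying) + 1L]
  }
  curve
}

#' @export
print.count_curve <- function(x, ...) {
  cat(sprintf("count_curve: %d counts, CV-AUC %.3f..%.3f",
              length(x$counts), min(x$cv_auc), max(x$cv_auc)))
  if (!is.null(x$chosen_count)) {
    cat(sprintf("; chosen count = %d (diff threshold %.4g)",
                x$chosen_count, x$diff_threshold))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.count_curve <- function(x, ...) {
  graphics::plot(x$counts, x$cv_auc, type = "b", pch = 19,
                 xlab = "gene count", ylab = "CV AUC", ...)
  if (!is.null(x$chosen_count)) {
    graphics::abline(v = x$chosen_count, lty = 2, col = "red")
  }
  invisible(x)
}

#' Export a count curve as a plain table
#' @param curve a `count_curve`.
#' @return data.frame with count, cv_auc, diff_from_previous, chosen.
#' @export
count_table <- function(curve) {
  data.frame(
    count = curve$counts,
    cv_auc = curve$cv_auc,
    diff_from_previous = c(NA, curve$diffs %||% diff(curve$cv_auc)),
    chosen = curve$counts == (curve$chosen_count %||% NA_integer_),
    stringsAsFactors = FALSE
  )
}
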