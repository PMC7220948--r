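#' Repeated stratified-split evaluation of one or more signatures
#'
#' For each of `spec$n_repeats` random stratified splits, every signature's
#' model is refit on the training portion and scored on both portions; the
#' per-split validation AUCs form the arm's distribution. All arms share the
#' same splits (variance-reducing pairing); arm comparisons use a two-sided
#' Mann-Whitney U test on the validation AUC lists, which treats the lists
#' as unpaired.
#'
#' @param ds an [expr_dataset].
#' @param signatures named list of gene-id vectors, one per arm.
#' @param spec a [split_spec()].
#' @param model_kind classifier passed to [fit_predictor()].
#' @return a `signature_eval`: list with `arms` (per-arm data.frame of
#'   train/valid AUC per split), `summary` (arm, median, q1, q3, ci_lo,
#'   ci_hi over validation AUC) and `comparisons` (arm_a, arm_b, U, p_value).
#' @export
evaluate_signatures <- function(ds, signatures, spec,
                                model_kind = c("mlr", "linear_svm", "rf")) {
  model_kind <- match.arg(model_kind)
  stopifnot(is.list(signatures), length(signatures) >= 1,
            !is.null(names(signatures)))
  for (nm in names(signatures)) {
    miss <- setdiff(signatures[[nm]], gene_ids(ds))
    if (length(miss) > 0) {
      stop("signature '", nm, "' has gene(s) absent from the data: ",
           paste(miss, collapse = ", "))
    }
  }
  arms <- lapply(signatures, function(g) {
    data.frame(repeat_index = seq_len(spec$n_repeats),
               train_auc = NA_real_, valid_auc = NA_real_)
  })
  y <- outcomes(ds)
  for (r in seq_len(spec$n_repeats)) {
    sp <- stratified_split(ds, spec, r)
    ds_tr <- ds[, sp$train]; ds_va <- ds[, sp$valid]
    for (nm in names(signatures)) {
      m <- fit_predictor(ds_tr, signatures[[nm]], model_kind,
                         seed = derive_seed(spec$master_seed, r))
      arms[[nm]]$train_auc[r] <- auc(y[sp$train], predict_proba(m, ds_tr))
      arms[[nm]]$valid_auc[r] <- auc(y[sp$valid], predict_proba(m, ds_va))
    }
  }
  build_eval_report(arms)
}

build_eval_report <- function(arms) {
  summ <- do.call(rbind, lapply(names(arms), function(nm) {
    v <- arms[[nm]]$valid_auc
    q <- stats::quantile(v, c(0.25, 0.5, 0.75, 0.025, 0.975), names = FALSE)
    data.frame(arm = nm, median = q[2], q1 = q[1], q3 = q[3],
               ci_lo = q[4], ci_hi = q[5], stringsAsFactors = FALSE)
  }))
  comp <- NULL
  nms <- names(arms)
  if (length(nms) >= 2) {
    pairs <- utils::combn(nms, 2)
    comp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      wt <- suppressWarnings(
        stats::wilcox.test(arms[[a]]$valid_auc, arms[[b]]$valid_auc,
                           alternative = "two.sided"))
      data.frame(arm_a = a, arm_b = b, U = unname(wt$statistic),
                 p_value = wt$p.value, stringsAsFactors = FALSE)
    }))
  }
  structure(list(arms = arms, summary = summ, comparisons = comp),
            class = "signature_eval")
}

#' @export
print.signature_eval <- function(x, ...) {
  cat("signature_eval over", nrow(x$arms[[1]]), "splits\n")
  print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$comparisons)) {
    cat("comparisons (Mann-Whitney, validation AUC):\n")
    print(x$comparisons, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
plot.signature_eval <- function(x, ...) {
  vals <- lapply(x$arms, `[[`, "valid_auc")
  graphics::boxplot(vals, ylab = "validation AUC", ...)
  invisible(x)
}

#' External validation of a fixed signature (Exp. 1 / Exp. 2 designs)
#'
#' Two designs for judging how a signature selected on one study transfers
#' to an independent one:
#'
#' * `"exp1"` — only the gene set is transferred. The external dataset is
#'   repeatedly split; the model is refit on each external training portion
#'   (signature fixed, coefficients refit) and scored on the external
#'   validation portion.
#' * `"exp2"` — the fitted model itself is transferred. Both datasets are
#'   first Z-scored per gene on all of their own samples (no labels used),
#'   removing study-level location/scale shifts; the selection dataset is
#'   repeatedly split, the model is fit on each training portion, and every
#'   fitted model is scored on the entire external dataset.
#'
#' @param selection_ds the dataset the signature was selected on.
#' @param external_ds the independent dataset.
#' @param signature character vector of gene ids; must be present in both
#'   datasets (missing genes are an error, never imputed).
#' @param mode `"exp1"` or `"exp2"`.
#' @param spec a [split_spec()].
#' @param model_kind classifier passed to [fit_predictor()].
#' @param zscore whether to apply the per-dataset Z-score renormalisation in
#'   exp2 mode (default TRUE; exposed so the effect of omitting it can be
#'   measured).
#' @return a `signature_eval` with one arm named after the mode; in exp2
#'   `valid_auc` is the AUC on the full external dataset per repeat.
#' @export
external_validate <- function(selection_ds, external_ds, signature,
                              mode = c("exp1", "exp2"), spec,
                              model_kind = c("mlr", "linear_svm", "rf"),
                              zscore = TRUE) {
  mode <- match.arg(mode)
  model_kind <- match.arg(model_kind)
  for (dsn in list(selection = selection_ds, external = external_ds)) {
    miss <- setdiff(signature, gene_ids(dsn))
    if (length(miss) > 0) {
      stop("signature gene(s) absent from a dataset: ",
           paste(miss, collapse = ", "))
    }
  }
  if (mode == "exp1") {
    return(evaluate_signatures(external_ds, list(exp1 = signature), spec,
                               model_kind))
  }
  if (zscore) {
    selection_ds <- zscore_genes(selection_ds)
    external_ds <- zscore_genes(external_ds)
  }
  y_tr <- outcomes(selection_ds)
  y_ex <- outcomes(external_ds)
  arm <- data.frame(repeat_index = seq_len(spec$n_repeats),
                    train_auc = NA_real_, valid_auc = NA_real_)
  for (r in seq_len(spec$n_repeats)) {
    sp <- stratified_split(selection_ds, spec, r)
    m <- fit_predictor(selection_ds[, sp$train], signature, model_kind,
                       seed = derive_seed(spec$master_seed, r))
    arm$train_auc[r] <- auc(y_tr[sp$train],
                            predict_proba(m, selection_ds[, sp$train]))
    arm$valid_auc[r] <- auc(y_ex, predict_proba(m, external_ds))
  }
  build_eval_report(list(exp2 = arm))
}
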