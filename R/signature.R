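#' Fit a minimal low-collinearity gene signature
#'
#' The full selection pipeline, in four stages on the supplied training
#' data:
#'
#' 1. **Screen** ([screen_genes()]): drop low-intensity genes (median < 5 in
#'    both outcome groups by default) and keep genes with a two-sided
#'    Student's t-test P <= `p_threshold`.
#' 2. **Rank** ([rfe_rank()]): order the survivors by linear-kernel SVM
#'    recursive feature elimination, truncated to the top `rfe_count`
#'    candidates.
#' 3. **Decorrelate** ([select_by_vif()]): greedy forward pass in rank
#'    order keeping only genes whose addition leaves every variance
#'    inflation factor below `vif_threshold`.
#' 4. **Size** ([cv_auc_curve()], [choose_count()]): compute the k-fold
#'    cross-validated AUC for every prefix of the decorrelated ranking and
#'    pick the operating gene count by the top-quartile differential-AUC
#'    rule.
#'
#' The final model (`model_kind`, default multiple logistic regression) is
#' then fit on all training samples with the chosen genes. Every
#' intermediate table (screen, ranking, VIF report, count curve, per-gene
#' audit) is retained on the returned object.
#'
#' @param ds an [expr_dataset] used for selection and training.
#' @param p_threshold t-test p-value cutoff (default 0.005).
#' @param intensity_threshold,intensity_rule see [screen_genes()].
#' @param rfe_count number of top-SVM-RFE genes carried into the VIF stage
#'   (default 102); capped so the candidate count stays below the sample
#'   count.
#' @param rfe_step,svm_cost see [rfe_rank()].
#' @param vif_threshold VIF cutoff (default 10).
#' @param cv_k folds for the gene-count search (default 10).
#' @param count_quantile top fraction for the differential-AUC rule
#'   (default 0.25).
#' @param model_kind final (and CV) classifier: `"mlr"`, `"linear_svm"` or
#'   `"rf"`.
#' @param seed integer master seed; the whole fit is deterministic given it.
#' @return an object of class `gene_signature` with elements `genes`
#'   (the signature, best-ranked first), `model` (the fitted final
#'   predictor), `chosen_count`, `screen`, `ranking`, `vif_report`,
#'   `curve`, `audit` (per-gene fate table) and `config`.
#' @seealso [evaluate_signatures()], [external_validate()], [run_full()]
#' @examples
#' sim <- generate_expression(synthetic_config(n_noise = 200, seed = 7))
#' sig <- fit_signature(sim$dataset, seed = 7)
#' print(sig)
#' head(predict(sig, sim$dataset))
#' @export
fit_signature <- function(ds, p_threshold = 0.005, intensity_threshold = 5,
                          intensity_rule = "both", rfe_count = 102,
                          rfe_step = 1, svm_cost = 1.0, vif_threshold = 10,
                          cv_k = 10, count_quantile = 0.25,
                          model_kind = c("mlr", "linear_svm", "rf"),
                          seed = 1L) {
  model_kind <- match.arg(model_kind)
  cl <- match.call()
  n <- ncol(ds$values)

  screen <- screen_genes(ds, p_threshold, intensity_threshold, intensity_rule)
  passing <- passing_genes(screen)
  if (length(passing) == 0) {
    stop("prefilter stage left no genes (P <= ", p_threshold,
         ", median intensity >= ", intensity_threshold, ")")
  }

  # keep the candidate pool below the sample count so VIF fits stay
  # well-posed (n > p)
  cap <- min(rfe_count, length(passing), n - 2L)
  truncated <- truncate_ranking(passing, cap)
  ranking <- if (length(truncated) >= 2) {
    rfe_rank(ds, truncated, step = rfe_step, C = svm_cost)
  } else {
    truncated
  }

  vrep <- select_by_vif(ds, ranking, threshold = vif_threshold)
  selected <- vrep$selected_genes
  if (length(selected) == 0) {
    stop("VIF stage left no genes (threshold ", vif_threshold, ")")
  }
  sel_ranking <- new_ranking(selected)

  if (length(selected) >= 3) {
    curve <- cv_auc_curve(ds, sel_ranking, counts = seq_along(selected),
                          k = cv_k, model_kind = model_kind, seed = seed)
    curve <- choose_count(curve, quantile = count_quantile)
    chosen <- curve$chosen_count
  } else {
    curve <- NULL
    chosen <- length(selected)
  }
  genes <- utils::head(selected, chosen)
  model <- fit_predictor(ds, genes, model_kind, seed = seed)

  audit <- build_audit(screen, ranking, vrep, genes)
  config <- list(p_threshold = p_threshold,
                 intensity_threshold = intensity_threshold,
                 intensity_rule = intensity_rule, rfe_count = rfe_count,
                 rfe_step = rfe_step, svm_cost = svm_cost,
                 vif_threshold = vif_threshold, cv_k = cv_k,
                 count_quantile = count_quantile, model_kind = model_kind,
                 seed = as.integer(seed))
  structure(list(genes = genes, model = model, chosen_count = chosen,
                 screen = screen, ranking = ranking, vif_report = vrep,
                 curve = curve, audit = audit, config = config, call = cl),
            class = "gene_signature")
}

# Assign every input gene to exactly one pipeline fate.
build_audit <- function(screen, ranking, vrep, final_genes) {
  fate <- rep(NA_character_, nrow(screen))
  names(fate) <- screen$gene_id
  fate[!screen$passed_intensity] <- "filtered_low_intensity"
  fate[screen$passed_intensity & !screen$passed] <- "failed_t_test"
  passed <- screen$gene_id[screen$passed]
  fate[setdiff(passed, c(ranking$ordered_genes))] <- "rfe_eliminated"
  in_rank <- ranking$ordered_genes
  fate[setdiff(in_rank, vrep$selected_genes)] <- "rfe_eliminated"
  fate[vrep$rejected$gene_id] <- "vif_rejected"
  fate[setdiff(vrep$selected_genes, final_genes)] <- "selected_beyond_count"
  fate[final_genes] <- "final_signature"
  data.frame(gene_id = names(fate), fate = unname(fate),
             stringsAsFactors = FALSE)
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d genes (%s model)\n",
              length(x$genes), x$config$model_kind))
  cat("genes:", paste(x$genes, collapse = ", "), "\n")
  cat(sprintf("screen: %d/%d genes passed; VIF-selected: %d (threshold %g)\n",
              sum(x$screen$passed), nrow(x$screen),
              length(x$vif_report$selected_genes), x$config$vif_threshold))
  if (!is.null(x$curve)) {
    cat(sprintf("chosen count %d by top-%.0f%% differential CV-AUC rule\n",
                x$chosen_count, 100 * x$config$count_quantile))
  }
  invisible(x)
}

#' Per-gene provenance of a fitted signature
#'
#' @param object a `gene_signature`.
#' @param ... ignored.
#' @return data.frame, one row per signature gene, with its screening
#'   p-value, SVM-RFE rank and final VIF, printed along with the pipeline
#'   stage tallies.
#' @export
summary.gene_signature <- function(object, ...) {
  s <- object$screen
  prov <- data.frame(
    gene_id = object$genes,
    p_value = s$p_value[match(object$genes, s$gene_id)],
    rfe_rank = match(object$genes, object$ranking$ordered_genes),
    final_vif = as.numeric(object$vif_report$vif_values[object$genes]),
    stringsAsFactors = FALSE
  )
  cat("Signature of", length(object$genes), "genes\n")
  print(prov, row.names = FALSE, digits = 3)
  cat("\nPipeline fates:\n")
  print(table(object$audit$fate))
  invisible(prov)
}

#' @export
coef.gene_signature <- function(object, ...) {
  if (object$model$model_kind != "mlr") {
    stop("coefficients are only available for the mlr model")
  }
  object$model$fit$coef
}

#' Predict metastasis probability from a fitted signature
#'
#' @param object a `gene_signature`.
#' @param newdata an [expr_dataset] containing the signature genes.
#' @param type `"response"` (probability of outcome 1, default) or
#'   `"class"` (0/1 at a 0.5 cut).
#' @param ... ignored.
#' @export
predict.gene_signature <- function(object, newdata,
                                   type = c("response", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object$model, newdata)
  if (type == "class") return(as.integer(p >= 0.5))
  p
}

#' @export
plot.gene_signature <- function(x, ...) {
  if (is.null(x$curve)) stop("no count curve was computed for this signature")
  plot(x$curve, ...)
}

#' Fit, internally validate and (optionally) externally validate
#'
#' Runs [fit_signature()] on the training data, evaluates the resulting
#' signature over repeated stratified splits, and — when an external
#' dataset is supplied — runs both external-validation designs (exp1:
#' signature transferred, model refit externally; exp2: model transferred
#' to the Z-scored external dataset).
#'
#' @param ds an [expr_dataset] used for selection and internal validation.
#' @param external optional independent [expr_dataset].
#' @param n_repeats random splits per evaluation (default 200).
#' @param ratio train:validation ratio (default `c(2, 1)`).
#' @param seed master seed.
#' @param ... further arguments to [fit_signature()].
#' @return list of class `signature_report` with `signature`, `internal`
#'   and, when external data is given, `exp1` and `exp2` evaluation
#'   reports.
#' @export
run_full <- function(ds, external = NULL, n_repeats = 200, ratio = c(2, 1),
                     seed = 1L, ...) {
  sig <- fit_signature(ds, seed = seed, ...)
  spec <- split_spec(ratio = ratio, n_repeats = n_repeats, master_seed = seed)
  out <- list(signature = sig,
              internal = evaluate_signatures(
                ds, list(signature = sig$genes), spec,
                model_kind = sig$config$model_kind))
  if (!is.null(external)) {
    out$exp1 <- external_validate(ds, external, sig$genes, "exp1", spec,
                                  model_kind = sig$config$model_kind)
    out$exp2 <- external_validate(ds, external, sig$genes, "exp2", spec,
                                  model_kind = sig$config$model_kind)
  }
  class(out) <- "signature_report"
  out
}

#' @export
print.signature_report <- function(x, ...) {
  print(x$signature)
  cat("\ninternal validation:\n"); print(x$internal)
  if (!is.null(x$exp1)) { cat("\nexternal (exp1):\n"); print(x$exp1) }
  if (!is.null(x$exp2)) { cat("\nexternal (exp2):\n"); print(x$exp2) }
  invisible(x)
}
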