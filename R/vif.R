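#' Variance inflation factor of one feature
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j is the coefficient of determination
#' from the least-squares regression of feature j on all other features plus
#' an intercept. VIF = 1 means feature j is orthogonal to the rest; large
#' values flag multicollinearity.
#'
#' @param x numeric matrix, n samples x p features (p >= 2, n > p).
#' @param j column index of the feature to assess.
#' @return the VIF; `Inf` when feature j is an exact linear combination of
#'   the others (R^2 = 1 within 1e-12).
#' @export
vif <- function(x, j) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p < 2) stop("VIF needs at least 2 features")
  if (n <= p) {
    stop("n <= p: too few samples for a VIF fit; reduce the candidate set")
  }
  yj <- x[, j]
  xo <- cbind(`(Intercept)` = 1, x[, -j, drop = FALSE])
  fit <- stats::lm.fit(xo, yj)
  rss <- sum(fit$residuals^2)
  tss <- sum((yj - mean(yj))^2)
  if (tss == 0) stop("feature ", j, " has zero variance")
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

vif_all <- function(x) vapply(seq_len(ncol(x)), function(j) vif(x, j), numeric(1))

#' Select a minimal low-collinearity gene subset by VIF
#'
#' Greedy forward pass over the ranking: the top-ranked gene is always
#' accepted; each subsequent gene is tentatively added and the VIFs of the
#' whole tentative set are recomputed; the gene is kept only if every VIF is
#' below `threshold`, and otherwise recorded as rejected with the offending
#' maximum VIF. One full pass over the ranking. Because the full set is
#' re-checked at every addition, the returned set is guaranteed to satisfy
#' max(VIF) < threshold. A backward mode (start from all genes, repeatedly
#' drop the max-VIF gene until all pass) is available for comparison.
#'
#' VIF is scale-invariant; genes are standardised internally purely for
#' numerical conditioning.
#'
#' @param ds an [expr_dataset] containing the ranked genes.
#' @param ranking a non-empty `gene_ranking`.
#' @param threshold VIF cutoff (> 1); the conventional multicollinearity
#'   alarm level is 10.
#' @param method `"forward"` (default) or `"backward"`.
#' @return a `vif_report`: list with `selected_genes` (in ranking order),
#'   `vif_values` (final VIFs within the selected set; 1 for a singleton),
#'   `rejected` (data.frame gene_id, max_vif_if_added) and `threshold`.
#' @export
select_by_vif <- function(ds, ranking, threshold = 10,
                          method = c("forward", "backward")) {
  method <- match.arg(method)
  genes <- ranking$ordered_genes
  if (length(genes) == 0) stop("empty ranking")
  if (threshold <= 1) stop("threshold must exceed 1 (VIF >= 1 by construction)")
  x <- t(ds$values[genes, , drop = FALSE])
  x <- standardise_cols(x)
  n <- nrow(x)
  if (n <= length(genes) && method == "backward") {
    stop("n <= p: too few samples for backward VIF elimination; truncate the ranking")
  }

  if (method == "forward") {
    selected <- genes[1]
    rej_id <- character(0); rej_vif <- numeric(0)
    for (g in genes[-1]) {
      tent <- c(selected, g)
      if (n <= length(tent)) {
        stop("n <= p while adding '", g,
             "': too few samples for a VIF fit; truncate the ranking")
      }
      v <- vif_all(x[, tent, drop = FALSE])
      if (all(v < threshold)) {
        selected <- tent
      } else {
        rej_id <- c(rej_id, g)
        rej_vif <- c(rej_vif, max(v))
      }
    }
  } else {
    selected <- genes
    rej_id <- character(0); rej_vif <- numeric(0)
    while (length(selected) >= 2) {
      v <- vif_all(x[, selected, drop = FALSE])
      if (all(v < threshold)) break
      worst <- which.max(v)
      rej_id <- c(rej_id, selected[worst])
      rej_vif <- c(rej_vif, v[worst])
      selected <- selected[-worst]
    }
  }

  final_v <- if (length(selected) >= 2) {
    vif_all(x[, selected, drop = FALSE])
  } else {
    1.0
  }
  structure(list(
    selected_genes = selected,
    vif_values = stats::setNames(final_v, selected),
    rejected = data.frame(gene_id = rej_id, max_vif_if_added = rej_vif,
                          stringsAsFactors = FALSE),
    threshold = threshold
  ), class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("vif_report: %d selected (max VIF %.3f < %g), %d rejected\n",
              length(x$selected_genes), max(x$vif_values), x$threshold,
              nrow(x$rejected)))
  invisible(x)
}

#' Export a VIF report as a plain table
#' @param report a `vif_report`.
#' @return data.frame with gene_id, status, vif.
#' @export
vif_table <- function(report) {
  sel <- data.frame(gene_id = report$selected_genes, status = "selected",
                    vif = as.numeric(report$vif_values),
                    stringsAsFactors = FALSE)
  if (nrow(report$rejected) == 0) return(sel)
  rbind(sel, data.frame(gene_id = report$rejected$gene_id, status = "rejected",
                        vif = report$rejected$max_vif_if_added,
                        stringsAsFactors = FALSE))
}
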