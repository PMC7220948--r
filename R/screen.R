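#' Stage-1 gene screening: intensity filter and two-sample t-test
#'
#' Eliminates low-intensity genes, then keeps genes whose mean intensity
#' differs between the two outcome groups by a two-sided Student's t-test at
#' `p_threshold`. The intensity filter removes a gene whose median intensity
#' falls below `intensity_threshold`; under `rule = "both"` (default) only
#' genes low in both outcome groups are removed, so a gene expressed in just
#' one group — potentially the most informative kind — survives; `rule =
#' "any"` removes a gene low in either group.
#'
#' @param ds an [expr_dataset] with both outcome groups of size >= 2.
#' @param p_threshold two-sided p-value cutoff (default 0.005).
#' @param intensity_threshold median-intensity cutoff on the input scale
#'   (default 5, log2-like intensities).
#' @param intensity_rule `"both"` or `"any"` (see above).
#' @param t_variant `"student"` for the pooled-variance test (default) or
#'   `"welch"` for unequal variances.
#' @return a data.frame of class `gene_screen`, one row per gene, with
#'   columns `gene_id`, `median_g0`, `median_g1`, `passed_intensity`,
#'   `t_stat`, `p_value`, `passed_pvalue`, `passed`. Genes failing the
#'   intensity filter are not tested (`t_stat`/`p_value` are NA,
#'   `passed_pvalue` FALSE).
#' @export
screen_genes <- function(ds, p_threshold = 0.005, intensity_threshold = 5,
                         intensity_rule = c("both", "any"),
                         t_variant = c("student", "welch")) {
  intensity_rule <- match.arg(intensity_rule)
  t_variant <- match.arg(t_variant)
  if (!(p_threshold > 0 && p_threshold <= 1)) {
    stop("p_threshold must lie in (0, 1]")
  }
  y <- outcomes(ds)
  i0 <- which(y == 0)
  i1 <- which(y == 1)
  if (length(i0) < 2 || length(i1) < 2) {
    stop("each outcome group needs at least 2 samples")
  }
  x0 <- ds$values[, i0, drop = FALSE]
  x1 <- ds$values[, i1, drop = FALSE]
  med0 <- apply(x0, 1, stats::median)
  med1 <- apply(x1, 1, stats::median)
  passed_intensity <- if (intensity_rule == "both") {
    # eliminated only when low in BOTH groups
    !(med0 < intensity_threshold & med1 < intensity_threshold)
  } else {
    !(med0 < intensity_threshold | med1 < intensity_threshold)
  }

  n0 <- length(i0); n1 <- length(i1)
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- apply(x0, 1, stats::var)
  v1 <- apply(x1, 1, stats::var)
  if (t_variant == "student") {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
    df <- rep(n0 + n1 - 2, length(se))
  } else {
    se <- sqrt(v0 / n0 + v1 / n1)
    df <- (v0 / n0 + v1 / n1)^2 /
      ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  }
  t_stat <- ifelse(se > 0, (m1 - m0) / se,
                   ifelse(m1 == m0, 0, sign(m1 - m0) * Inf))
  p_value <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df),
                    ifelse(m1 == m0, 1, 0))

  t_stat[!passed_intensity] <- NA_real_
  p_value[!passed_intensity] <- NA_real_
  passed_pvalue <- passed_intensity & !is.na(p_value) & p_value <= p_threshold

  res <- data.frame(
    gene_id = gene_ids(ds),
    median_g0 = med0, median_g1 = med1,
    passed_intensity = passed_intensity,
    t_stat = t_stat, p_value = p_value,
    passed_pvalue = passed_pvalue,
    passed = passed_intensity & passed_pvalue,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "p_threshold") <- p_threshold
  attr(res, "intensity_threshold") <- intensity_threshold
  class(res) <- c("gene_screen", "data.frame")
  res
}

#' Ranking of genes passing the screen
#'
#' Keeps genes passing both filters, ordered by ascending p-value with ties
#' broken by input (matrix row) order, and carries the per-gene statistics
#' forward as the starting ranking for SVM-RFE.
#'
#' @param screen a `gene_screen` table from [screen_genes()].
#' @return a `gene_ranking` object (possibly empty): list with
#'   `ordered_genes`, `elimination_order` (all 0 before RFE),
#'   `weights_at_removal` (NA before RFE) and the screening `stats`.
#' @export
passing_genes <- function(screen) {
  keep <- screen[screen$passed, , drop = FALSE]
  ord <- order(keep$p_value) # stable: ties keep input order
  keep <- keep[ord, , drop = FALSE]
  rownames(keep) <- NULL
  new_ranking(keep$gene_id, stats = keep)
}

#' Construct a gene ranking
#'
#' Wraps an ordered vector of gene ids (best first) as a `gene_ranking`,
#' the currency passed between the screening, SVM-RFE, VIF and gene-count
#' stages. Useful for ranking genes by other means and feeding them into
#' [select_by_vif()] or [cv_auc_curve()].
#'
#' @param genes character vector of gene ids, best-ranked first.
#' @param elimination_order,weights_at_removal,stats optional per-gene
#'   metadata filled in by [rfe_rank()] / [passing_genes()].
#' @return a `gene_ranking` object.
#' @export
new_ranking <- function(genes, elimination_order = NULL,
                        weights_at_removal = NULL, stats = NULL) {
  genes <- as.character(genes)
  structure(list(
    ordered_genes = genes,
    elimination_order = elimination_order %||%
      stats::setNames(integer(length(genes)), genes),
    weights_at_removal = weights_at_removal %||%
      stats::setNames(rep(NA_real_, length(genes)), genes),
    stats = stats
  ), class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("gene_ranking: %d genes\n", length(x$ordered_genes)))
  if (length(x$ordered_genes) > 0) {
    cat("top:", paste(utils::head(x$ordered_genes, 8), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.gene_ranking <- function(x) length(x$ordered_genes)

#' Truncate a gene ranking to its top genes
#'
#' @param ranking a `gene_ranking`.
#' @param m number of top-ranked genes to keep (capped at the ranking size).
#' @return the truncated `gene_ranking`.
#' @export
truncate_ranking <- function(ranking, m) {
  stopifnot(m >= 1)
  keep <- utils::head(ranking$ordered_genes, m)
  st <- ranking$stats
  if (!is.null(st)) st <- st[st$gene_id %in% keep, , drop = FALSE]
  new_ranking(keep,
              elimination_order = ranking$elimination_order[keep],
              weights_at_removal = ranking$weights_at_removal[keep],
              stats = st)
}
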