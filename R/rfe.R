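#' Rank genes by linear-kernel SVM recursive feature elimination
#'
#' Iteratively fits a linear soft-margin SVM on the per-gene-standardised
#' training matrix and removes, at each iteration, the `step` genes with the
#' smallest squared weight w_i^2 — the standard SVM-RFE elimination
#' criterion. The final ranking lists the last-surviving gene first. Genes
#' are standardised to training mean 0 / sd 1 before fitting so that |w| is
#' comparable across genes regardless of raw intensity scale.
#'
#' Within an elimination batch, ties in w^2 are broken by the incoming
#' ranking order (the later-ranked gene is removed first), which together
#' with the deterministic SVM solver makes the full ordering reproducible.
#'
#' @param ds an [expr_dataset] containing all genes of `ranking`; both
#'   outcome classes must be present.
#' @param ranking a `gene_ranking` (typically from [passing_genes()]) giving
#'   the candidate genes; must contain >= 2 genes.
#' @param step genes removed per iteration (default 1, giving a total order).
#' @param C soft-margin cost of the linear SVM (default 1, the usual
#'   "default option").
#' @return a `gene_ranking` with `ordered_genes` (best first),
#'   `elimination_order` (iteration at which each gene was removed; the
#'   survivor of a step-1 run is coded 0) and `weights_at_removal` (|w| at
#'   removal).
#' @export
rfe_rank <- function(ds, ranking, step = 1, C = 1.0) {
  genes <- ranking$ordered_genes
  if (length(genes) < 2) stop("SVM-RFE needs at least 2 genes")
  stopifnot(step >= 1)
  y <- outcomes(ds)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  x <- t(ds$values[genes, , drop = FALSE]) # samples x genes
  x <- standardise_cols(x)
  yf <- factor(y, levels = c(0, 1))

  remaining <- genes
  elim_seq <- character(0)
  elim_iter <- stats::setNames(integer(length(genes)), genes)
  elim_w <- stats::setNames(rep(NA_real_, length(genes)), genes)

  it <- 0L
  while (length(remaining) >= 2) {
    it <- it + 1L
    fit <- e1071::svm(x[, remaining, drop = FALSE], yf, kernel = "linear",
                      cost = C, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    w2 <- stats::setNames(as.numeric(w)^2, remaining)
    k <- min(step, length(remaining))
    if (k >= length(remaining)) {
      # degenerate final batch: eliminate everything, worst (smallest w^2) first
      ord <- order(w2, -seq_along(w2))
      drop_now <- remaining[ord]
    } else {
      ord <- order(w2, -seq_along(w2))
      drop_now <- remaining[ord[seq_len(k)]]
    }
    elim_seq <- c(elim_seq, drop_now)
    elim_iter[drop_now] <- it
    elim_w[drop_now] <- sqrt(w2[drop_now])
    remaining <- setdiff(remaining, drop_now)
  }
  if (length(remaining) == 1) elim_seq <- c(elim_seq, remaining)
  ordered <- rev(elim_seq)

  st <- ranking$stats
  if (!is.null(st)) {
    st <- st[match(ordered, st$gene_id), , drop = FALSE]
    rownames(st) <- NULL
  }
  new_ranking(ordered,
              elimination_order = elim_iter[ordered],
              weights_at_removal = elim_w[ordered],
              stats = st)
}

#' Export a ranking as a plain table
#' @param ranking a `gene_ranking`.
#' @return data.frame with rank, gene_id, elimination_iteration,
#'   weight_at_removal.
#' @export
ranking_table <- function(ranking) {
  data.frame(
    rank = seq_along(ranking$ordered_genes),
    gene_id = ranking$ordered_genes,
    elimination_iteration = as.integer(ranking$elimination_order),
    weight_at_removal = as.numeric(ranking$weights_at_removal),
    stringsAsFactors = FALSE
  )
}
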