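#' Expression dataset container
#'
#' Bundles a genes x samples matrix of normalised log-scale intensities with
#' per-sample annotations. The outcome is binary (1 = distant metastasis
#' within 5 years, 0 = none); an optional stratum label (typically ER status)
#' is carried for stratified splitting.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   complete dimnames and no missing values.
#' @param annotations data.frame with columns `sample_id`, `outcome`
#'   (0/1) and optionally `strata`; one row per matrix column, same order.
#' @return an object of class `expr_dataset` with elements `values`
#'   (the matrix) and `annotations`.
#' @export
expr_dataset <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("missing or non-finite values in expression matrix")
  }
  annotations <- as.data.frame(annotations)
  if (!all(c("sample_id", "outcome") %in% names(annotations))) {
    stop("annotations need 'sample_id' and 'outcome' columns")
  }
  if (!identical(as.character(annotations$sample_id), colnames(values))) {
    stop("annotation rows must match matrix columns (same ids, same order)")
  }
  if (!all(annotations$outcome %in% c(0, 1))) {
    stop("every outcome must be 0 or 1")
  }
  annotations$outcome <- as.integer(annotations$outcome)
  structure(list(values = values, annotations = annotations),
            class = "expr_dataset")
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' @export
print.expr_dataset <- function(x, ...) {
  d <- dim(x$values)
  n1 <- sum(x$annotations$outcome == 1)
  cat(sprintf("expr_dataset: %d genes x %d samples (%d outcome-positive)\n",
              d[1], d[2], n1))
  if ("strata" %in% names(x$annotations)) {
    cat("strata:", paste(names(table(x$annotations$strata)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

gene_ids <- function(ds) rownames(ds$values)
sample_ids <- function(ds) colnames(ds$values)

#' Outcome labels of an expression dataset
#' @param ds an `expr_dataset`.
#' @return integer vector of 0/1 outcomes, named by sample id.
#' @export
outcomes <- function(ds) {
  stats::setNames(ds$annotations$outcome, ds$annotations$sample_id)
}

#' Read an expression matrix and sample annotations
#'
#' The matrix file is a tab-delimited table in the GEO series-matrix style:
#' lines starting with `!` are ignored, the header row holds sample ids and
#' the first column holds gene/probe ids. The annotation table needs a
#' `sample_id` column (or the first column is taken as such), an `outcome`
#' column and optionally a `strata` column. Samples are taken as the
#' intersection of the two files, in matrix column order; annotated samples
#' missing an outcome are dropped with a warning.
#'
#' @param matrix_path path to the expression table.
#' @param annotation_path path to the annotation table.
#' @param sep field delimiter (default tab; use "," for CSV).
#' @return an [expr_dataset].
#' @export
read_expression <- function(matrix_path, annotation_path, sep = "\t") {
  raw <- readLines(matrix_path)
  raw <- raw[!startsWith(raw, "!")]
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) < 2) stop("expression file has no data rows")
  tab <- utils::read.table(text = raw, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"")
  gids <- tab[[1]]
  if (anyDuplicated(gids)) {
    stop("duplicate gene ids in expression file: ",
         paste(unique(gids[duplicated(gids)]), collapse = ", "))
  }
  sids <- colnames(tab)[-1]
  if (anyDuplicated(sids)) stop("duplicate sample ids in expression file")
  vals <- suppressWarnings(
    vapply(tab[-1], as.numeric, numeric(nrow(tab)))
  )
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(gids, sids))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing cell at gene '%s', sample '%s'",
                 gids[bad[1]], sids[bad[2]]))
  }

  ann <- utils::read.table(annotation_path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(ann)) names(ann)[1] <- "sample_id"
  if (!"outcome" %in% names(ann)) stop("annotation table needs an 'outcome' column")
  ann$sample_id <- as.character(ann$sample_id)
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample ids in annotation table")

  no_outcome <- is.na(ann$outcome)
  if (any(no_outcome)) {
    warning(sum(no_outcome), " annotated sample(s) lack an outcome; dropped")
    ann <- ann[!no_outcome, , drop = FALSE]
  }

  keep <- intersect(sids, ann$sample_id)
  if (length(keep) == 0) {
    # orientation check: sample ids found among gene ids suggests a transposed file
    if (length(intersect(gids, ann$sample_id)) > 0) {
      stop("no matrix columns match annotation sample ids, but matrix rows do: ",
           "the expression matrix appears transposed (expected genes x samples)")
    }
    stop("no samples shared between expression matrix and annotations")
  }
  if (length(keep) < length(sids)) {
    warning(length(sids) - length(keep),
            " matrix sample(s) without annotation; dropped")
  }
  if (length(keep) < length(ann$sample_id)) {
    warning(length(ann$sample_id) - length(keep),
            " annotated sample(s) absent from the matrix; ignored")
  }
  ann <- ann[match(keep, ann$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  expr_dataset(vals[, keep, drop = FALSE], ann)
}

#' Write an expression dataset back to delimited text
#'
#' @param ds an [expr_dataset].
#' @param matrix_path,annotation_path output paths.
#' @param sep field delimiter.
#' @export
write_expression <- function(ds, matrix_path, annotation_path, sep = "\t") {
  tab <- data.frame(gene_id = gene_ids(ds), ds$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$annotations, annotation_path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(ds)
}

#' Per-gene Z-score renormalisation
#'
#' Rescales every gene row to mean 0 and unit (n-1) standard deviation across
#' all samples of the dataset. Used to remove per-study location/scale
#' differences before applying a model trained on another dataset.
#'
#' @param ds an [expr_dataset]; every gene must have nonzero variance.
#' @return an [expr_dataset] with standardised rows; annotations unchanged.
#' @export
zscore_genes <- function(ds) {
  m <- rowMeans(ds$values)
  s <- apply(ds$values, 1, stats::sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad) > 0) {
    stop("zero-variance gene(s), cannot Z-score: ",
         paste(gene_ids(ds)[bad], collapse = ", "))
  }
  out <- (ds$values - m) / s
  expr_dataset(out, ds$annotations)
}

#' Subset an expression dataset by gene and/or sample ids
#'
#' @param x an [expr_dataset].
#' @param genes character vector of gene ids (or missing for all), in the
#'   desired output order.
#' @param samples character vector of sample ids (or missing for all).
#' @param ... ignored.
#' @return the restricted [expr_dataset]; annotations follow the samples.
#' @export
`[.expr_dataset` <- function(x, genes, samples, ...) {
  if (missing(genes)) genes <- gene_ids(x)
  if (missing(samples)) samples <- sample_ids(x)
  genes <- as.character(genes)
  samples <- as.character(samples)
  mg <- match(genes, gene_ids(x))
  if (anyNA(mg)) stop("unknown gene id(s): ",
                      paste(genes[is.na(mg)], collapse = ", "))
  ms <- match(samples, sample_ids(x))
  if (anyNA(ms)) stop("unknown sample id(s): ",
                      paste(samples[is.na(ms)], collapse = ", "))
  ann <- x$annotations[ms, , drop = FALSE]
  rownames(ann) <- NULL
  expr_dataset(x$values[mg, ms, drop = FALSE], ann)
}
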