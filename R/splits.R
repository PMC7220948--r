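#' Specification of the repeated stratified-split protocol
#'
#' @param ratio integer pair `(train_parts, valid_parts)`; `c(2, 1)` is the
#'   paper-style "approximately 2:1" split.
#' @param n_repeats number of random splits (default 200).
#' @param master_seed integer seed from which every per-repeat split seed is
#'   derived deterministically.
#' @return a `split_spec` list.
#' @export
split_spec <- function(ratio = c(2, 1), n_repeats = 200, master_seed = 1L) {
  stopifnot(length(ratio) == 2, all(ratio > 0), n_repeats >= 1)
  structure(list(ratio = as.numeric(ratio), n_repeats = as.integer(n_repeats),
                 master_seed = as.integer(master_seed)),
            class = "split_spec")
}

#' One stratified random train/validation split
#'
#' Samples are stratified jointly on outcome and, when present, the `strata`
#' annotation (e.g. ER status), so that each stratum contributes to train and
#' validation in the spec's ratio. Within each stratum the samples are
#' shuffled with a seed derived deterministically from
#' `(master_seed, repeat_index)`, so the same pair always yields the same
#' split and different repeats yield independent ones.
#'
#' @param ds an [expr_dataset]; every stratum needs >= 2 samples.
#' @param spec a [split_spec()].
#' @param repeat_index which repeat (1-based) this split is.
#' @return list with `train` and `valid` character vectors of sample ids.
#' @export
stratified_split <- function(ds, spec, repeat_index = 1L) {
  ann <- ds$annotations
  key <- paste0("o", ann$outcome)
  if ("strata" %in% names(ann)) key <- paste0(key, ":", ann$strata)
  tab <- table(key)
  if (any(tab < 2)) {
    stop("stratum with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  train_frac <- spec$ratio[1] / sum(spec$ratio)
  seed <- derive_seed(spec$master_seed, repeat_index)
  set.seed(seed)
  train <- character(0); valid <- character(0)
  for (s in sort(unique(key))) {
    ids <- ann$sample_id[key == s]
    ids <- sample(ids)
    n_tr <- round(length(ids) * train_frac)
    n_tr <- min(max(n_tr, 1L), length(ids) - 1L) # >= 1 per side
    train <- c(train, ids[seq_len(n_tr)])
    valid <- c(valid, ids[-seq_len(n_tr)])
  }
  list(train = train, valid = valid)
}

# Outcome-stratified k-fold assignment; returns integer fold id per sample.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
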