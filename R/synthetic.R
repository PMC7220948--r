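#' Configuration for the synthetic expression generator
#'
#' Defaults describe a compact microarray-like study: 150 samples at 35%
#' outcome prevalence, 5 truly informative genes whose group means differ by
#' one baseline standard deviation, 10 blocks of 5 highly correlated decoy
#' genes (equicorrelation 0.9) to exercise the VIF stage, 2000 independent
#' null genes of which 10% sit below the intensity filter, all on a
#' log2-like scale centred at 8, plus an ER-like stratum label independent
#' of outcome.
#'
#' @param n_samples total samples (>= 20).
#' @param prevalence fraction of outcome-1 samples, in (0, 1).
#' @param n_informative number of independent informative genes.
#' @param effect_size group mean shift in units of `baseline_sd`.
#' @param n_corr_blocks,block_size,block_rho correlated decoy-block layout;
#'   `block_rho` in \[0, 1) is the within-block equicorrelation.
#' @param n_noise independent null genes.
#' @param baseline_mean,baseline_sd location/scale of adequately expressed
#'   genes on the log2-like intensity scale.
#' @param low_intensity_fraction fraction of the noise genes centred below
#'   the conventional intensity filter (their mean is set to 3).
#' @param er_positive_fraction frequency of the "ERpos" stratum label,
#'   assigned independently of outcome.
#' @param block_informative if TRUE, the first gene of every correlated
#'   block also receives the group mean shift (signal entangled with
#'   collinearity).
#' @param seed integer seed; generation is bit-reproducible given the
#'   config.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 150, prevalence = 0.35,
                             n_informative = 5, effect_size = 1.0,
                             n_corr_blocks = 10, block_size = 5,
                             block_rho = 0.9, n_noise = 2000,
                             baseline_mean = 8, baseline_sd = 1,
                             low_intensity_fraction = 0.1,
                             er_positive_fraction = 0.6,
                             block_informative = FALSE,
                             seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), prevalence = prevalence,
              n_informative = as.integer(n_informative),
              effect_size = effect_size,
              n_corr_blocks = as.integer(n_corr_blocks),
              block_size = as.integer(block_size), block_rho = block_rho,
              n_noise = as.integer(n_noise), baseline_mean = baseline_mean,
              baseline_sd = baseline_sd,
              low_intensity_fraction = low_intensity_fraction,
              er_positive_fraction = er_positive_fraction,
              block_informative = isTRUE(block_informative),
              seed = as.integer(seed))
  problems <- character(0)
  if (cfg$n_samples < 20) problems <- c(problems, "n_samples must be >= 20")
  if (!(cfg$prevalence > 0 && cfg$prevalence < 1)) {
    problems <- c(problems, "prevalence must lie in (0, 1)")
  }
  if (!(cfg$block_rho >= 0 && cfg$block_rho < 1)) {
    problems <- c(problems, "block_rho must lie in [0, 1)")
  }
  if (cfg$baseline_sd <= 0) problems <- c(problems, "baseline_sd must be positive")
  if (cfg$low_intensity_fraction < 0 || cfg$low_intensity_fraction > 1) {
    problems <- c(problems, "low_intensity_fraction must lie in [0, 1]")
  }
  if (cfg$n_informative < 0 || cfg$n_noise < 0 || cfg$n_corr_blocks < 0) {
    problems <- c(problems, "gene counts must be non-negative")
  }
  if (length(problems) > 0) {
    stop("invalid synthetic_config: ", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Outcome-1 membership is a fixed count (`round(n * prevalence)`), shuffled
#' over samples. Informative genes are independent normals whose group means
#' differ by `effect_size * baseline_sd`. Each decoy block is equicorrelated
#' normal, built from a shared per-sample latent factor
#' (`x = sqrt(rho) * f + sqrt(1 - rho) * eps`), which gives exactly the
#' target correlation in expectation. Noise genes are independent normals
#' with no group effect; a `low_intensity_fraction` of them is centred at
#' intensity 3, below the conventional < 5 filter. The ER-like stratum is
#' drawn independently of outcome.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (an [expr_dataset]) and `truth` (data.frame
#'   gene_id, role in informative / block_decoy / noise / low_intensity).
#' @export
generate_expression <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  generate_expression_impl(config)
}

generate_expression_impl <- function(cfg) {
  n <- cfg$n_samples
  n1 <- round(n * cfg$prevalence)
  y <- sample(c(rep(1L, n1), rep(0L, n - n1)))
  er <- sample(c("ERpos", "ERneg"), n, replace = TRUE,
               prob = c(cfg$er_positive_fraction, 1 - cfg$er_positive_fraction))
  shift <- cfg$effect_size * cfg$baseline_sd
  half <- shift / 2

  blocks <- list(); roles <- character(0); ids <- character(0)

  if (cfg$n_informative > 0) {
    m <- matrix(stats::rnorm(cfg$n_informative * n, cfg$baseline_mean,
                             cfg$baseline_sd),
                nrow = cfg$n_informative)
    m <- m + rep(ifelse(y == 1, half, -half), each = cfg$n_informative)
    blocks <- c(blocks, list(m))
    ids <- c(ids, paste0("INF", seq_len(cfg$n_informative)))
    roles <- c(roles, rep("informative", cfg$n_informative))
  }
  if (cfg$n_corr_blocks > 0 && cfg$block_size > 0) {
    rho <- cfg$block_rho
    for (b in seq_len(cfg$n_corr_blocks)) {
      f <- stats::rnorm(n)
      eps <- matrix(stats::rnorm(cfg$block_size * n), nrow = cfg$block_size)
      z <- sqrt(rho) * rep(f, each = cfg$block_size) + sqrt(1 - rho) * eps
      m <- cfg$baseline_mean + cfg$baseline_sd * z
      if (cfg$block_informative) {
        m[1, ] <- m[1, ] + ifelse(y == 1, half, -half)
      }
      blocks <- c(blocks, list(m))
      ids <- c(ids, paste0("BLK", b, "_", seq_len(cfg$block_size)))
      roles <- c(roles, rep("block_decoy", cfg$block_size))
    }
  }
  if (cfg$n_noise > 0) {
    n_low <- round(cfg$n_noise * cfg$low_intensity_fraction)
    mu <- c(rep(3, n_low), rep(cfg$baseline_mean, cfg$n_noise - n_low))
    m <- matrix(stats::rnorm(cfg$n_noise * n, sd = cfg$baseline_sd),
                nrow = cfg$n_noise) + mu
    blocks <- c(blocks, list(m))
    ids <- c(ids, paste0("NOISE", seq_len(cfg$n_noise)))
    roles <- c(roles, c(rep("low_intensity", n_low),
                        rep("noise", cfg$n_noise - n_low)))
  }
  vals <- do.call(rbind, blocks)
  rownames(vals) <- ids
  colnames(vals) <- sprintf("S%03d", seq_len(n))
  ann <- data.frame(sample_id = colnames(vals), outcome = y, strata = er,
                    stringsAsFactors = FALSE)
  list(dataset = expr_dataset(vals, ann),
       truth = data.frame(gene_id = ids, role = roles,
                          stringsAsFactors = FALSE))
}

#' Generate an internal/external dataset pair with a batch effect
#'
#' Draws two datasets from the same class-conditional model (emulating a
#' discovery study and an independent validation study), then applies an
#' independent per-gene location shift `Normal(0, batch_shift_sd^2)` and a
#' mild per-gene log-normal scale jitter (sd 0.1 on the log scale) to the
#' second — the kind of cross-study batch effect that per-dataset Z-scoring
#' removes.
#'
#' @param config a [synthetic_config()] (used for both datasets).
#' @param batch_shift_sd standard deviation of the per-gene location shift
#'   applied to the second dataset (0 = exchangeable pair).
#' @param seed2 seed for the second dataset and its batch effect.
#' @return list with `internal` and `external` datasets and `truth`.
#' @export
generate_pair <- function(config = synthetic_config(), batch_shift_sd = 0,
                          seed2 = config$seed + 1L) {
  first <- generate_expression(config)
  set.seed(as.integer(seed2))
  second <- generate_expression_impl(config)
  if (batch_shift_sd > 0) {
    ng <- nrow(second$dataset$values)
    loc <- stats::rnorm(ng, 0, batch_shift_sd)
    scl <- exp(stats::rnorm(ng, 0, 0.1))
    v <- second$dataset$values
    mu <- rowMeans(v)
    v <- (v - mu) * scl + mu + loc
    second$dataset <- expr_dataset(v, second$dataset$annotations)
  }
  list(internal = first$dataset, external = second$dataset,
       truth = first$truth)
}
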