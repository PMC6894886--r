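#' Configuration for the two-condition hurdle simulator
#'
#' Planted truth for the hurdle mixed model: per gene, an
#' expression-induction effect `delta` (log-odds of a cell expressing the
#' gene, treated vs control) and an expression-level effect `beta`
#' (natural-log fold change among expressing cells), with per-sample random
#' intercepts on both components.
#'
#' @param n_genes number of genes; `delta`, `beta`, `pi0` and
#'   `baseline_mean` are recycled to this length.
#' @param n_cells_per_condition cells per condition (split evenly across
#'   samples).
#' @param n_samples_per_condition biological replicates per condition
#'   (must be >= 2).
#' @param sample_random_intercept_sd standard deviation of the per-sample
#'   random intercepts (shared scale for the logit and log components).
#' @param delta per-gene induction effect, log-odds.
#' @param beta per-gene level effect, natural-log fold change.
#' @param pi0 baseline probability that a control cell expresses the gene;
#'   strictly inside (0, 1).
#' @param baseline_mean baseline mean UMI count among expressing cells.
#' @param gamma_shape shape of the gamma level distribution.
#' @param seed integer seed.
#' @return a `condition_sim_config` list.
#' @export
condition_sim_config <- function(n_genes = 100,
                                 n_cells_per_condition = 1000,
                                 n_samples_per_condition = 2,
                                 sample_random_intercept_sd = 0.2,
                                 delta = 0,
                                 beta = 0,
                                 pi0 = 0.3,
                                 baseline_mean = 5,
                                 gamma_shape = 2,
                                 seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_cells_per_condition = as.integer(n_cells_per_condition),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    sample_random_intercept_sd = sample_random_intercept_sd,
    delta = rep_len(delta, n_genes),
    beta = rep_len(beta, n_genes),
    pi0 = rep_len(pi0, n_genes),
    baseline_mean = rep_len(baseline_mean, n_genes),
    gamma_shape = gamma_shape,
    seed = as.integer(seed)
  )
  class(cfg) <- "condition_sim_config"
  if (cfg$n_samples_per_condition < 2) {
    abort("invalid config: need at least 2 samples per condition")
  }
  if (any(cfg$pi0 <= 0 | cfg$pi0 >= 1)) {
    abort("invalid config: pi0 must lie strictly inside (0, 1)")
  }
  if (any(!is.finite(cfg$delta)) || any(!is.finite(cfg$beta))) {
    abort("invalid config: effects must be finite")
  }
  if (cfg$sample_random_intercept_sd < 0) {
    abort("invalid config: sample_random_intercept_sd must be >= 0")
  }
  cfg
}

#' Simulate two-condition expression with induction and level effects
#'
#' Per gene `g` and cell `i` in sample `s`, the cell expresses with
#' probability `plogis(qlogis(pi0_g) + delta_g * treated + b_s)` and, if it
#' expresses, draws a gamma level with log-mean
#' `log(baseline_mean_g) + beta_g * treated + b'_s`, discretized to a
#' positive count. `b_s` and `b'_s` are independent
#' `N(0, sample_random_intercept_sd^2)` per sample, emulating
#' treated-vs-control animal replicates.
#'
#' @param cond a [condition_sim_config()].
#' @return list of class `condition_sim`:
#'   * `counts`: genes x cells sparse matrix over both conditions;
#'   * `cells`: tibble with `barcode`, `condition`
#'     (`control` / `treated`) and `sample`;
#'   * `genes`: tibble of planted per-gene truth
#'     (`gene`, `delta`, `beta`, `pi0`).
#' @export
simulate_condition_effects <- function(cond = condition_sim_config()) {
  cfg <- if (inherits(cond, "condition_sim_config")) cond else
    abort("`cond` must be a condition_sim_config")
  set.seed(cfg$seed)

  n_per <- cfg$n_cells_per_condition
  n_samp <- cfg$n_samples_per_condition
  condition <- rep(c("control", "treated"), each = n_per)
  sample_id <- paste0(
    condition, "_s",
    rep(rep_len(seq_len(n_samp), n_per), 2)
  )
  samples <- unique(sample_id)
  b_ind <- setNames(rnorm(length(samples), 0, cfg$sample_random_intercept_sd),
                    samples)
  b_lev <- setNames(rnorm(length(samples), 0, cfg$sample_random_intercept_sd),
                    samples)
  treated <- as.integer(condition == "treated")
  n_cells <- length(condition)

  counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_cells)
  for (g in seq_len(cfg$n_genes)) {
    eta <- qlogis(cfg$pi0[g]) + cfg$delta[g] * treated + b_ind[sample_id]
    expressed <- rbinom(n_cells, 1, plogis(eta)) == 1
    n_on <- sum(expressed)
    if (n_on > 0) {
      mu <- exp(log(cfg$baseline_mean[g]) + cfg$beta[g] * treated[expressed] +
                  b_lev[sample_id[expressed]])
      lev <- rgamma(n_on, shape = cfg$gamma_shape,
                    rate = cfg$gamma_shape / mu)
      counts[g, expressed] <- pmax(1L, as.integer(round(lev)))
    }
  }
  dimnames(counts) <- list(sprintf("gene%04d", seq_len(cfg$n_genes)),
                           sprintf("cell%05d", seq_len(n_cells)))

  structure(list(
    counts = as_count_matrix(counts),
    cells = tibble(barcode = colnames(counts),
                   condition = condition, sample = sample_id),
    genes = tibble(gene = rownames(counts), delta = cfg$delta,
                   beta = cfg$beta, pi0 = cfg$pi0),
    config = cfg
  ), class = "condition_sim")
}
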