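#' Configuration for the droplet experiment simulator
#'
#' Collects every knob of [simulate_droplet_experiment()]. Defaults describe a
#' typical 10x-style spleen run at desk scale: a tight high-depth cell mode, a
#' low-depth empty-droplet mode separated by many empty-mode standard
#' deviations, a small doublet fraction, and a couple of ambient
#' ("hemoglobin-like") genes leaking into every droplet.
#'
#' @param n_cells,n_empty,n_genes numbers of true cells, empty droplets and
#'   genes.
#' @param k_clusters number of planted cell populations.
#' @param markers_per_cluster planted marker genes per population.
#' @param marker_logfc natural-log fold change of a marker in its own
#'   population relative to baseline.
#' @param cell_depth_log10_mean,cell_depth_log10_sd log10 UMI depth
#'   distribution of single cells. The default sd (0.05) is deliberately
#'   tight so that the doublet mode (displaced by `+log10(2)`) is resolvable
#'   as a separate local mode, which is what the multiplet rule detects; at
#'   wider spreads the doublet mass is only a shoulder of the cell mode.
#' @param empty_depth_log10_mean,empty_depth_log10_sd log10 UMI depth of
#'   empty droplets (ambient material only).
#' @param multiplet_fraction fraction of `n_cells` added as doublet barcodes
#'   (each the sum of two freshly drawn cells); must be `< 1`, and the default
#'   0.03 respects the `< 5%` share that makes a doublet mode detectable.
#' @param ambient_genes named numeric vector: names are gene indices, values
#'   the ambient UMI fraction of each barcode's depth contributed by that
#'   gene (added as Poisson background to all barcodes).
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`) of per-gene counts in cells.
#' @param seed integer seed; every draw in the simulator descends from it.
#' @return a `droplet_sim_config` list.
#' @export
droplet_sim_config <- function(n_cells = 2000,
                               n_empty = 2000,
                               n_genes = 1000,
                               k_clusters = 3,
                               markers_per_cluster = 10,
                               marker_logfc = 2,
                               cell_depth_log10_mean = 3.5,
                               cell_depth_log10_sd = 0.05,
                               empty_depth_log10_mean = 1.5,
                               empty_depth_log10_sd = 0.20,
                               multiplet_fraction = 0.03,
                               ambient_genes = c("1" = 0.02, "2" = 0.01),
                               nb_dispersion = 0.1,
                               seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_empty = as.integer(n_empty),
    n_genes = as.integer(n_genes), k_clusters = as.integer(k_clusters),
    markers_per_cluster = as.integer(markers_per_cluster),
    marker_logfc = marker_logfc,
    cell_depth_log10_mean = cell_depth_log10_mean,
    cell_depth_log10_sd = cell_depth_log10_sd,
    empty_depth_log10_mean = empty_depth_log10_mean,
    empty_depth_log10_sd = empty_depth_log10_sd,
    multiplet_fraction = multiplet_fraction,
    ambient_genes = ambient_genes,
    nb_dispersion = nb_dispersion,
    seed = as.integer(seed)
  )
  class(cfg) <- "droplet_sim_config"
  validate_droplet_sim_config(cfg)
}

validate_droplet_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_cells > 0, cfg$n_empty >= 0, cfg$n_genes > 1,
    cfg$k_clusters > 0, cfg$markers_per_cluster >= 0,
    cfg$cell_depth_log10_sd > 0, cfg$empty_depth_log10_sd > 0,
    cfg$nb_dispersion > 0
  )
  if (cfg$k_clusters > cfg$n_cells) {
    abort("invalid config: k_clusters exceeds n_cells")
  }
  if (cfg$multiplet_fraction < 0 || cfg$multiplet_fraction >= 1) {
    abort("invalid config: multiplet_fraction must lie in [0, 1)")
  }
  if (cfg$k_clusters * cfg$markers_per_cluster +
      length(cfg$ambient_genes) > cfg$n_genes) {
    abort("invalid config: not enough genes for the requested markers")
  }
  cfg
}

#' Simulate a droplet scRNA-seq experiment with planted truth
#'
#' Generates a gene-by-barcode UMI count matrix containing true cells
#' (negative-binomial expression with cluster-specific marker up-shifts),
#' empty droplets (the population-average ambient profile at low depth), and
#' doublet barcodes (sums of two freshly drawn cells). Ambient genes are
#' added as Poisson background to every barcode in proportion to its depth,
#' mimicking lysed-red-blood-cell hemoglobin transcripts captured by
#' essentially all droplets.
#'
#' @param config a [droplet_sim_config()].
#' @return a list of class `droplet_sim`:
#'   * `counts`: sparse genes x barcodes count matrix;
#'   * `barcodes`: tibble with `barcode`, `class`
#'     (`cell` / `empty` / `multiplet`) and `cluster` (NA off-cells);
#'   * `markers`: tibble with `gene` and the `cluster` it marks;
#'   * `config`: the configuration used.
#' @examples
#' sim <- simulate_droplet_experiment(droplet_sim_config(
#'   n_cells = 200, n_empty = 200, n_genes = 300, seed = 7
#' ))
#' dplyr::count(sim$barcodes, class)
#' @export
simulate_droplet_experiment <- function(config = droplet_sim_config()) {
  cfg <- validate_droplet_sim_config(config)
  set.seed(cfg$seed)

  g <- cfg$n_genes
  k <- cfg$k_clusters
  ambient_idx <- as.integer(names(cfg$ambient_genes))

  # baseline relative expression; skewed like real transcriptomes
  base_rate <- rgamma(g, shape = 0.5, rate = 1) + 1e-4
  base_rate <- base_rate / sum(base_rate)

  marker_pool <- setdiff(seq_len(g), ambient_idx)
  marker_idx <- matrix(
    marker_pool[seq_len(k * cfg$markers_per_cluster)],
    nrow = cfg$markers_per_cluster
  )
  profiles <- matrix(base_rate, nrow = g, ncol = k)
  for (j in seq_len(k)) {
    profiles[marker_idx[, j], j] <-
      profiles[marker_idx[, j], j] * exp(cfg$marker_logfc)
  }
  profiles <- sweep(profiles, 2, colSums(profiles), "/")

  draw_cell <- function(cluster, depth) {
    mu <- depth * profiles[, cluster]
    rnbinom(g, mu = mu, size = 1 / cfg$nb_dispersion)
  }

  clusters <- sample.int(k, cfg$n_cells, replace = TRUE)
  cell_depth <- 10^rnorm(cfg$n_cells, cfg$cell_depth_log10_mean,
                         cfg$cell_depth_log10_sd)
  cells <- vapply(seq_len(cfg$n_cells),
                  function(i) draw_cell(clusters[i], cell_depth[i]),
                  numeric(g))

  n_mult <- round(cfg$multiplet_fraction * cfg$n_cells)
  mult <- NULL
  if (n_mult > 0) {
    mc1 <- sample.int(k, n_mult, replace = TRUE)
    mc2 <- sample.int(k, n_mult, replace = TRUE)
    md1 <- 10^rnorm(n_mult, cfg$cell_depth_log10_mean, cfg$cell_depth_log10_sd)
    md2 <- 10^rnorm(n_mult, cfg$cell_depth_log10_mean, cfg$cell_depth_log10_sd)
    mult <- vapply(seq_len(n_mult),
                   function(i) draw_cell(mc1[i], md1[i]) +
                     draw_cell(mc2[i], md2[i]),
                   numeric(g))
  }

  empties <- NULL
  empty_depth <- numeric(0)
  if (cfg$n_empty > 0) {
    ambient_profile <- rowMeans(profiles)
    empty_depth <- 10^rnorm(cfg$n_empty, cfg$empty_depth_log10_mean,
                            cfg$empty_depth_log10_sd)
    empties <- vapply(empty_depth,
                      function(d) rpois(g, d * ambient_profile),
                      numeric(g))
  }

  counts <- cbind(cells, mult, empties)
  depth_all <- c(cell_depth,
                 if (n_mult > 0) md1 + md2 else NULL,
                 empty_depth)
  for (a in seq_along(ambient_idx)) {
    counts[ambient_idx[a], ] <- counts[ambient_idx[a], ] +
      rpois(ncol(counts), cfg$ambient_genes[a] * depth_all)
  }

  classes <- c(rep("cell", cfg$n_cells),
               rep("multiplet", n_mult),
               rep("empty", cfg$n_empty))
  dimnames(counts) <- list(
    sprintf("gene%04d", seq_len(g)),
    sprintf("bc%05d", seq_len(ncol(counts)))
  )

  structure(list(
    counts = as_count_matrix(counts),
    barcodes = tibble(
      barcode = colnames(counts),
      class = classes,
      cluster = c(clusters, rep(NA_integer_, n_mult + cfg$n_empty))
    ),
    markers = tibble(
      gene = rownames(counts)[as.vector(marker_idx)],
      cluster = rep(seq_len(k), each = cfg$markers_per_cluster)
    ),
    config = cfg
  ), class = "droplet_sim")
}

#' Simulate a nested two-level population structure
#'
#' Convenience wrapper planting `k_top` top-level populations each split into
#' `k_sub` subpopulations: subpopulations within a top-level population share
#' that population's strong markers and differ by their own weaker markers.
#' Used to exercise the iterative clustering procedure.
#'
#' @param n_cells total cells.
#' @param n_genes genes.
#' @param k_top,k_sub top-level populations and subpopulations within each.
#' @param top_logfc,sub_logfc natural-log marker fold changes at each level.
#' @param markers_per_group markers per (top-level or sub) group.
#' @param depth_log10_mean,depth_log10_sd,nb_dispersion as in
#'   [droplet_sim_config()].
#' @param seed integer seed.
#' @return list with `counts`, and a `barcodes` tibble carrying `top` and
#'   `sub` truth labels (sub labels are globally unique, e.g. `2.3`).
#' @export
simulate_nested_populations <- function(n_cells = 2000, n_genes = 1000,
                                        k_top = 3, k_sub = 2,
                                        top_logfc = 2.5, sub_logfc = 1.5,
                                        markers_per_group = 15,
                                        depth_log10_mean = 3.3,
                                        depth_log10_sd = 0.15,
                                        nb_dispersion = 0.1,
                                        seed = 1L) {
  set.seed(seed)
  g <- n_genes
  base_rate <- rgamma(g, shape = 0.5, rate = 1) + 1e-4
  base_rate <- base_rate / sum(base_rate)

  n_groups <- k_top * (k_sub + 1)
  stopifnot(markers_per_group * n_groups <= g)
  marker_idx <- matrix(sample.int(g, markers_per_group * n_groups),
                       nrow = markers_per_group)

  profiles <- matrix(base_rate, nrow = g, ncol = k_top * k_sub)
  col <- 0
  for (tt in seq_len(k_top)) {
    top_cols <- marker_idx[, tt]
    for (ss in seq_len(k_sub)) {
      col <- col + 1
      sub_cols <- marker_idx[, k_top + (tt - 1) * k_sub + ss]
      profiles[top_cols, col] <- profiles[top_cols, col] * exp(top_logfc)
      profiles[sub_cols, col] <- profiles[sub_cols, col] * exp(sub_logfc)
    }
  }
  profiles <- sweep(profiles, 2, colSums(profiles), "/")

  grp <- sample.int(k_top * k_sub, n_cells, replace = TRUE)
  depth <- 10^rnorm(n_cells, depth_log10_mean, depth_log10_sd)
  counts <- vapply(seq_len(n_cells), function(i) {
    rnbinom(g, mu = depth[i] * profiles[, grp[i]], size = 1 / nb_dispersion)
  }, numeric(g))
  dimnames(counts) <- list(sprintf("gene%04d", seq_len(g)),
                           sprintf("bc%05d", seq_len(n_cells)))

  top <- (grp - 1) %/% k_sub + 1
  sub <- (grp - 1) %% k_sub + 1
  list(
    counts = as_count_matrix(counts),
    barcodes = tibble(
      barcode = colnames(counts),
      top = top,
      sub = paste(top, sub, sep = ".")
    )
  )
}
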