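#' Scale counts to a common barcode depth
#'
#' Rescales each barcode's UMI counts to the median barcode total, removing
#' depth differences: `x_gc = u_gc / U_c * median(U)`. Column sums are equal
#' after scaling and a barcode's scaled profile is invariant to multiplying
#' its counts by a constant.
#'
#' @param m a count matrix with strictly positive barcode totals.
#' @param target depth to scale to; defaults to the median barcode total.
#' @return a sparse real matrix, genes x barcodes.
#' @export
depth_scale <- function(m, target = NULL) {
  m <- as_count_matrix(m)
  u <- barcode_totals(m)
  if (any(u == 0)) abort("zero-total barcode: run filter_barcodes() first")
  if (is.null(target)) target <- median(u)
  m %*% Matrix::Diagonal(x = target / u, names = FALSE) |>
    `dimnames<-`(dimnames(m))
}

#' Select high-dispersion (variable) genes
#'
#' Bins genes into `n_bins` equal-occupancy mean-expression bins, z-scores
#' the log dispersion (variance / mean) within each bin, and keeps genes
#' with `z >= z_cutoff`. When all gene means are equal (a single degenerate
#' bin) the z-scoring falls back to a global one.
#'
#' @param scaled a depth-scaled matrix from [depth_scale()].
#' @param n_bins equal-occupancy mean bins.
#' @param z_cutoff within-bin dispersion z-score cutoff.
#' @return character vector of selected gene names, with the per-gene
#'   statistics tibble attached as attribute `"stats"`.
#' @export
select_variable_genes <- function(scaled, n_bins = 20, z_cutoff = 1) {
  if (ncol(scaled) < 2) abort("need at least 2 cells")
  mu <- Matrix::rowMeans(scaled)
  ex2 <- Matrix::rowMeans(scaled^2)
  v <- (ex2 - mu^2) * ncol(scaled) / (ncol(scaled) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)

  stats <- tibble(gene = rownames(scaled), mean = mu, dispersion = disp) |>
    filter(.data$mean > 0, .data$dispersion > 0) |>
    mutate(log_disp = log(.data$dispersion))
  if (nrow(stats) == 0) return(character(0))

  if (dplyr::n_distinct(stats$mean) == 1) {
    stats$bin <- 1L
  } else {
    stats$bin <- dplyr::ntile(stats$mean, min(n_bins, nrow(stats)))
  }
  stats <- stats |>
    group_by(.data$bin) |>
    mutate(z = {
      s <- sd(.data$log_disp)
      if (is.na(s) || s == 0) rep(0, dplyr::n()) else
        (.data$log_disp - mean(.data$log_disp)) / s
    }) |>
    ungroup()

  out <- stats$gene[stats$z >= z_cutoff]
  attr(out, "stats") <- stats
  out
}

#' Principal-component embedding of cells
#'
#' Centers (and unit-scales) the selected genes across cells and computes an
#' exact PCA, retaining the leading `n` components. Exact SVD is
#' deterministic, so no seed is involved.
#'
#' @param scaled depth-scaled matrix.
#' @param genes genes to use (e.g. from [select_variable_genes()]);
#'   default all.
#' @param n number of components to retain (clamped with a warning when it
#'   exceeds the data rank bound).
#' @param scale. unit-scale genes before PCA.
#' @return an `embedding` list: `cells`, `coordinates` (cells x n matrix),
#'   `var_explained`.
#' @export
pca_embed <- function(scaled, genes = NULL, n = 50, scale. = TRUE) {
  x <- if (is.null(genes)) scaled else scaled[genes, , drop = FALSE]
  x <- as.matrix(Matrix::t(x))  # cells x genes
  keep <- apply(x, 2, sd) > 0
  x <- x[, keep, drop = FALSE]
  n_max <- min(dim(x)) - 1L
  if (n > n_max) {
    warn(sprintf("clamping n from %d to %d", n, n_max))
    n <- n_max
  }
  p <- prcomp(x, center = TRUE, scale. = scale., rank. = n)
  structure(list(
    cells = rownames(x),
    coordinates = p$x[, seq_len(n), drop = FALSE],
    var_explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(n)]
  ), class = "embedding")
}

#' Shared-nearest-neighbor graph in PC space
#'
#' Builds the Euclidean k-nearest-neighbor sets (self included) in the
#' embedding, connects every pair of cells with the Jaccard overlap of their
#' neighbor sets, and prunes edges whose weight falls below `prune`
#' (default 1/15, the conventional Jaccard cutoff).
#'
#' @param e an `embedding`.
#' @param k neighborhood size; default `min(750, floor(0.75 * (n - 1)))`.
#'   The cap at three quarters of the cells matters only for small cell
#'   subsets: as k approaches `n - 1` every neighbor set converges to the
#'   full cell set, all Jaccard weights saturate near 1, and the graph
#'   carries no structure to cluster. For any dataset of 1000+ cells the
#'   default equals the conventional `min(750, n - 1)`.
#' @param prune minimum Jaccard similarity for an edge to be kept.
#' @return an [igraph::igraph] weighted undirected graph with vertex names
#'   equal to cell identifiers and attributes `k` and `prune`.
#' @export
build_snn_graph <- function(e, k = NULL, prune = 1 / 15) {
  stopifnot(inherits(e, "embedding"))
  n <- length(e$cells)
  if (n < 2) abort("need at least 2 cells")
  if (is.null(k)) k <- min(750L, max(2L, floor(0.75 * (n - 1))))
  k <- min(k, n)

  d <- as.matrix(dist(e$coordinates))
  # neighbor sets of size k including self (self distance 0 sorts first)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    adj[i, order(d[i, ])[seq_len(k)]] <- 1L
  }
  inter <- tcrossprod(adj)
  jac <- inter / (2 * k - inter)
  diag(jac) <- 0
  jac[jac < prune] <- 0

  g <- igraph::graph_from_adjacency_matrix(
    jac, mode = "undirected", weighted = TRUE, diag = FALSE
  )
  igraph::V(g)$name <- e$cells
  g$k <- k
  g$prune <- prune
  g
}

#' Louvain modularity clustering at a fixed resolution
#'
#' @param g an SNN graph from [build_snn_graph()].
#' @param resolution modularity resolution parameter.
#' @param seed integer seed (the Louvain heuristic is randomized).
#' @return named integer cluster labels per cell.
#' @export
cluster_at_resolution <- function(g, resolution, seed = 1L) {
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                resolution = resolution)
  setNames(as.integer(igraph::membership(cl)), igraph::V(g)$name)
}

#' Mean per-cluster silhouette quality of a labelling
#'
#' The resolution-search quality metric: the mean over clusters of the mean
#' silhouette width of that cluster's cells in PC space — rewarding
#' labellings whose clusters are internally cohesive and isolated from the
#' rest. A one-cluster labelling scores 0 by convention (silhouette is
#' undefined without a second cluster).
#'
#' @param labels integer labels per cell.
#' @param d a [stats::dist] over the same cells (PC-space distances).
#' @return a single numeric score.
#' @export
cluster_quality <- function(labels, d) {
  k <- length(unique(labels))
  if (k < 2) return(0)
  if (k >= length(labels)) return(-1)  # all singletons: no cohesion defined
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  if (!is.matrix(sil)) return(-1)
  per_cell <- tibble(cluster = sil[, 1], width = sil[, 3])
  per_cluster <- per_cell |>
    group_by(.data$cluster) |>
    summarise(width = mean(.data$width), .groups = "drop")
  mean(per_cluster$width)
}

#' Search the Louvain resolution grid for the best labelling
#'
#' Clusters the SNN graph at every resolution on the grid (default 0.05 to
#' 1.225 in steps of 0.025), scores each candidate labelling with
#' [cluster_quality()] and returns the argmax; ties go to the lowest
#' resolution. When no candidate splits the data, or the best multi-cluster
#' candidate scores below `min_metric`, the trivial one-cluster labelling is
#' returned — this is what lets the iterative procedure declare convergence
#' on homogeneous data.
#'
#' @param g SNN graph.
#' @param e the `embedding` the graph was built from (for the metric).
#' @param range,step resolution grid.
#' @param seed integer seed.
#' @param min_metric minimum quality a split must reach to beat the trivial
#'   labelling (0.10: below the conventional 0.25 "weak structure"
#'   silhouette line, so only near-structureless data refuses to split).
#' @return list: `labels`, `resolution` (`NA` for the trivial labelling),
#'   `metric`, and `grid` (tibble of all evaluated candidates).
#' @export
resolution_search <- function(g, e, range = c(0.05, 1.225), step = 0.025,
                              seed = 1L, min_metric = 0.1) {
  stopifnot(range[2] >= range[1])
  d <- dist(e$coordinates)
  grid <- seq(range[1], range[2], by = step)
  best <- list(labels = NULL, resolution = NA_real_, metric = -Inf)
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    labels <- cluster_at_resolution(g, grid[i], seed = seed)
    k_found <- length(unique(labels))
    metric <- cluster_quality(labels, d)
    rows[[i]] <- tibble(resolution = grid[i], n_clusters = k_found,
                        metric = metric)
    if (k_found > 1 && metric > best$metric) {
      best <- list(labels = labels, resolution = grid[i], metric = metric)
    }
  }
  if (is.null(best$labels) || best$metric < min_metric) {
    best <- list(
      labels = setNames(rep(1L, length(e$cells)), e$cells),
      resolution = NA_real_,
      metric = if (is.finite(best$metric)) best$metric else 0
    )
    best$metric <- 0
  }
  best$grid <- list_rbind(rows)
  best
}

cluster_subset <- function(m, pcs, k, prune, range, step, seed, min_metric,
                           min_var_genes = 10) {
  scaled <- depth_scale(m)
  genes <- select_variable_genes(scaled)
  if (length(genes) < min_var_genes) return(NULL)
  e <- pca_embed(scaled, genes = genes,
                 n = min(pcs, length(genes) - 1L, ncol(m) - 1L))
  g <- build_snn_graph(
    e,
    k = if (is.null(k)) NULL else min(k, floor(0.75 * (ncol(m) - 1))),
    prune = prune
  )
  resolution_search(g, e, range = range, step = step, seed = seed,
                    min_metric = min_metric)
}

#' Iterative clustering to convergence
#'
#' Runs the full pipeline — depth scaling, variable genes, PCA, SNN graph,
#' resolution search — on all cells, then recursively on each resulting
#' cluster's cells. A cluster has converged when the resolution search
#' returns a single cluster or the cluster holds fewer than `min_cells`
#' cells. Lineage labels record the split path (`"3"`, `"3.1"`, `"3.1.2"`);
#' converged labels always refine first-iteration labels.
#'
#' @param m a QC-filtered count matrix.
#' @param min_cells do not attempt to split clusters smaller than this.
#' @param pcs,k,prune,range,step,min_metric pipeline parameters (see
#'   [pca_embed()], [build_snn_graph()], [resolution_search()]).
#' @param seed integer seed.
#' @param max_depth recursion-depth guard; exceeding it aborts with a
#'   non-convergence diagnostic.
#' @return a `cluster_assignment` tibble: `barcode`, `first_iteration`,
#'   `converged`, with a `splits` attribute recording each split's lineage,
#'   chosen resolution and metric.
#' @export
iterative_cluster <- function(m, min_cells = 50, pcs = 50, k = NULL,
                              prune = 1 / 15, range = c(0.05, 1.225),
                              step = 0.025, seed = 1L, min_metric = 0.1,
                              max_depth = 10) {
  m <- as_count_matrix(m)
  labels <- setNames(rep("", ncol(m)), colnames(m))
  splits <- list()

  recurse <- function(cols, prefix, depth) {
    if (depth > max_depth) {
      abort(sprintf(
        "iterative clustering failed to converge below %s (depth > %d)",
        prefix, max_depth
      ))
    }
    if (length(cols) < min_cells) return(invisible())
    res <- cluster_subset(m[, cols, drop = FALSE], pcs = pcs, k = k,
                          prune = prune, range = range, step = step,
                          seed = seed, min_metric = min_metric)
    if (is.null(res) || length(unique(res$labels)) < 2) return(invisible())
    splits[[length(splits) + 1]] <<- tibble(
      lineage = if (prefix == "") "(root)" else prefix,
      n_cells = length(cols),
      n_clusters = length(unique(res$labels)),
      resolution = res$resolution,
      metric = res$metric
    )
    for (cl in sort(unique(res$labels))) {
      sub <- cols[res$labels[cols] == cl]
      lab <- if (prefix == "") as.character(cl) else
        paste(prefix, cl, sep = ".")
      labels[sub] <<- lab
      recurse(sub, lab, depth + 1)
    }
    invisible()
  }

  recurse(colnames(m), "", 1)
  labels[labels == ""] <- "1"
  out <- tibble(
    barcode = colnames(m),
    first_iteration = sub("\\..*$", "", unname(labels)),
    converged = unname(labels)
  )
  attr(out, "splits") <- if (length(splits)) list_rbind(splits) else
    tibble(lineage = character(), n_cells = integer(),
           n_clusters = integer(), resolution = numeric(), metric = numeric())
  class(out) <- c("cluster_assignment", class(out))
  out
}
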