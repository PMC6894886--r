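make_small_sim <- function(seed = 21, n_cells = 300, n_genes = 400) {
  simulate_droplet_experiment(droplet_sim_config(
    n_cells = n_cells, n_empty = 0, n_genes = n_genes,
    multiplet_fraction = 0, seed = seed
  ))
}

test_that("depth scaling equalizes column sums and is depth-invariant", {
  sim <- make_small_sim()
  scaled <- depth_scale(sim$counts)
  cs <- Matrix::colSums(scaled)
  expect_lt(diff(range(cs)) / mean(cs), 1e-8)
  # doubling one barcode's counts leaves its scaled profile unchanged
  m2 <- sim$counts
  m2[, 1] <- m2[, 1] * 2
  s2 <- depth_scale(as_count_matrix(m2), target = median(barcode_totals(sim$counts)))
  expect_equal(as.numeric(s2[, 1]), as.numeric(scaled[, 1]), tolerance = 1e-10)
  # equal-depth input: scaling is one common factor
  eq <- matrix(4L, 5, 6, dimnames = list(paste0("g", 1:5), paste0("b", 1:6)))
  se <- depth_scale(as_count_matrix(eq))
  expect_equal(unique(as.numeric(se)), 4)
  # zero-total barcode errors
  z <- eq; z[, 3] <- 0
  expect_error(depth_scale(as_count_matrix(z)), "zero-total")
})

test_that("variable-gene selection recovers planted markers", {
  sim <- simulate_droplet_experiment(droplet_sim_config(
    n_empty = 0, multiplet_fraction = 0, seed = 22
  ))
  scaled <- depth_scale(sim$counts)
  vg <- select_variable_genes(scaled)
  recall <- mean(sim$markers$gene %in% vg)
  expect_gte(recall, 0.9)
})

test_that("variable-gene null fraction matches the z-cutoff tail", {
  set.seed(23)
  lambda <- runif(600, 1, 20)
  m <- matrix(rpois(600 * 500, lambda), nrow = 600,
              dimnames = list(paste0("g", 1:600), paste0("c", 1:500)))
  vg <- select_variable_genes(as_count_matrix(m) |> depth_scale())
  frac <- length(vg) / 600
  expect_lt(abs(frac - pnorm(1, lower.tail = FALSE)), 0.03)
  # constant genes are never selected
  m2 <- rbind(m, const = 5L)
  rownames(m2) <- c(paste0("g", 1:600), "const")
  vg2 <- select_variable_genes(depth_scale(as_count_matrix(m2)))
  expect_false("const" %in% vg2)
})

test_that("PCA of rank-3 data concentrates variance in 3 components", {
  set.seed(24)
  load <- matrix(rnorm(200 * 3), 200)
  fac <- matrix(rnorm(3 * 30), 3)
  x <- exp(load %*% fac)  # positive, exact rank 3 in log space
  m <- t(x)  # hand a genes x cells matrix
  dimnames(m) <- list(paste0("g", 1:30), paste0("c", 1:200))
  e <- pca_embed(Matrix::Matrix(log(t(x)), sparse = TRUE,
                                dimnames = dimnames(m)),
                 n = 10, scale. = FALSE)
  expect_lt(sum(e$var_explained[4:10]) / sum(e$var_explained[1:3]), 1e-8)
  # deterministic: exact SVD twice
  e2 <- pca_embed(Matrix::Matrix(log(t(x)), sparse = TRUE,
                                 dimnames = dimnames(m)),
                  n = 10, scale. = FALSE)
  expect_identical(e$coordinates, e2$coordinates)
  # n beyond rank bound clamps with a warning
  expect_warning(
    pca_embed(Matrix::Matrix(log(t(x)), sparse = TRUE,
                             dimnames = dimnames(m)), n = 500),
    "clamping"
  )
})

test_that("planted clusters separate in PC space", {
  sim <- make_small_sim(seed = 25, n_cells = 800, n_genes = 600)
  scaled <- depth_scale(sim$counts)
  vg <- select_variable_genes(scaled)
  e <- pca_embed(scaled, genes = vg, n = 50)
  truth <- setNames(sim$barcodes$cluster, sim$barcodes$barcode)[e$cells]
  # every pair of planted centroids lies farther apart than the clusters
  # spread around their own centroids
  cent <- sapply(1:3, function(k)
    colMeans(e$coordinates[truth == k, , drop = FALSE]))
  spread <- sapply(1:3, function(k) {
    x <- e$coordinates[truth == k, , drop = FALSE]
    sqrt(mean(rowSums(sweep(x, 2, cent[, k])^2)))
  })
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gt(sqrt(sum((cent[, i] - cent[, j])^2)), max(spread[c(i, j)]))
  }
  # and the labelling scores as clearly structured
  expect_gt(cluster_quality(truth, dist(e$coordinates)), 0.1)
})

test_that("SNN graph matches a brute-force implementation edge for edge", {
  set.seed(26)
  coords <- matrix(rnorm(50 * 5), 50)
  rownames(coords) <- paste0("c", 1:50)
  e <- structure(list(cells = rownames(coords), coordinates = coords,
                      var_explained = rep(0.2, 5)), class = "embedding")
  g <- build_snn_graph(e, k = 10, prune = 1 / 15)
  ed <- igraph::as_data_frame(g)
  ours <- ed[order(ed$from, ed$to), ]
  bf <- brute_snn(coords, k = 10, prune = 1 / 15)
  bf$from <- paste0("c", pmin(bf$i, bf$j))
  bf$to <- paste0("c", pmax(bf$i, bf$j))
  bf <- bf[order(bf$from, bf$to), ]
  expect_equal(nrow(ours), nrow(bf))
  expect_equal(ours$from, bf$from)
  expect_equal(ours$to, bf$to)
  expect_equal(ours$weight, bf$w, tolerance = 1e-12)
})

test_that("identical cells get weight-1 edges; k = n-1 saturates weights", {
  coords <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5.1, 5), c(10, 0), c(0, 10))
  rownames(coords) <- paste0("c", 1:6)
  e <- structure(list(cells = rownames(coords), coordinates = coords,
                      var_explained = c(0.5, 0.5)), class = "embedding")
  g <- build_snn_graph(e, k = 3, prune = 0)
  w12 <- igraph::E(g)[igraph::`%--%`("c1", "c2")]$weight
  expect_equal(w12, 1)
  g_full <- build_snn_graph(e, k = 5, prune = 0)
  expect_gte(min(igraph::E(g_full)$weight), 0.5)
})

test_that("Louvain separates disconnected cliques at any sane resolution", {
  g <- igraph::disjoint_union(igraph::make_full_graph(8),
                              igraph::make_full_graph(8))
  igraph::V(g)$name <- paste0("c", 1:16)
  for (r in c(0.05, 0.5, 1.0)) {
    lab <- cluster_at_resolution(g, r, seed = 1)
    expect_equal(length(unique(lab)), 2)
    expect_equal(length(unique(lab[1:8])), 1)
  }
})

test_that("resolution search recovers planted clusters and ties break low", {
  sim <- make_small_sim(seed = 27, n_cells = 300, n_genes = 400)
  scaled <- depth_scale(sim$counts)
  vg <- select_variable_genes(scaled)
  e <- pca_embed(scaled, genes = vg, n = 20)
  g <- build_snn_graph(e)
  rs <- resolution_search(g, e, seed = 1)
  truth <- setNames(sim$barcodes$cluster, sim$barcodes$barcode)
  expect_equal(length(unique(rs$labels)), 3)
  expect_gte(ari(rs$labels[e$cells], truth[e$cells]), 0.9)
  expect_equal(nrow(rs$grid), length(seq(0.05, 1.225, by = 0.025)))
  # the perfect labelling scores above a random bipartition
  d <- dist(e$coordinates)
  set.seed(1)
  random_split <- setNames(sample(1:2, length(e$cells), TRUE), e$cells)
  expect_gt(cluster_quality(rs$labels, d),
            cluster_quality(random_split, d))
})

test_that("structureless data yields a single cluster", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rpois(300 * 200, 5), nrow = 300,
                dimnames = list(paste0("g", 1:300), paste0("c", 1:200)))
    scaled <- depth_scale(as_count_matrix(m))
    vg <- select_variable_genes(scaled)
    e <- pca_embed(scaled, genes = vg, n = min(20, length(vg) - 1))
    g <- build_snn_graph(e)
    rs <- resolution_search(g, e, seed = s)
    if (length(unique(rs$labels)) == 1) hits <- hits + 1
  }
  expect_gte(hits, 4)  # >= 80% of seeds
})

test_that("merging two planted clusters never improves the metric", {
  sim <- make_small_sim(seed = 28, n_cells = 300)
  scaled <- depth_scale(sim$counts)
  vg <- select_variable_genes(scaled)
  e <- pca_embed(scaled, genes = vg, n = 20)
  d <- dist(e$coordinates)
  truth <- setNames(sim$barcodes$cluster, sim$barcodes$barcode)[e$cells]
  full <- cluster_quality(truth, d)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    merged <- truth
    merged[merged == pair[2]] <- pair[1]
    expect_lte(cluster_quality(merged, d), full)
  }
})

test_that("iterative clustering resolves nested structure and refines", {
  nest <- simulate_nested_populations(n_cells = 600, n_genes = 500, seed = 3)
  ca <- iterative_cluster(nest$counts, seed = 3)
  expect_gte(ari(ca$first_iteration, nest$barcodes$top), 0.9)
  expect_gte(ari(ca$converged, nest$barcodes$sub), 0.9)
  # converged labels refine first-iteration labels
  expect_true(all(
    sub("\\..*$", "", ca$converged) == ca$first_iteration
  ))
  # determinism end to end
  ca2 <- iterative_cluster(nest$counts, seed = 3)
  expect_identical(ca$converged, ca2$converged)
})

test_that("homogeneous data converges immediately to one cluster", {
  set.seed(29)
  m <- matrix(rpois(300 * 150, 5), nrow = 300,
              dimnames = list(paste0("g", 1:300), paste0("c", 1:150)))
  ca <- iterative_cluster(as_count_matrix(m), seed = 1)
  expect_equal(unique(ca$converged), "1")
  expect_equal(nrow(attr(ca, "splits")), 0)
})
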