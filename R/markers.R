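#' Bimodal likelihood-ratio test between two expression groups
#'
#' Models each group's expression values as a point mass at zero with
#' probability `1 - pi` plus a log-normal distribution over the positive
#' values (group-specific mean, variance pooled across the two groups), and
#' compares that against a null in which both groups share one distribution.
#' The statistic is `2 * (l_a + l_b - l_pooled)` referred to a chi-squared
#' distribution with 2 degrees of freedom (`pi` and the positive mean free
#' per group). Direction is the sign of the difference of group means.
#'
#' @param x_a,x_b non-negative expression values of the two groups.
#' @return list: `statistic`, `p`, `direction` (+1 when `x_a` exceeds).
#' @examples
#' bimod_lrt(c(0, 0, 1, 2, 4), c(0, 0, 1, 2, 4))  # identical: p = 1
#' @export
bimod_lrt <- function(x_a, x_b) {
  if (length(x_a) == 0 || length(x_b) == 0) abort("both groups must be non-empty")
  r <- bimod_lrt_matrix(matrix(x_a, nrow = 1), matrix(x_b, nrow = 1))
  list(statistic = r$statistic[1], p = r$p[1], direction = r$direction[1])
}

# vectorized over genes (rows); the closed-form MLE version of the test
bimod_lrt_matrix <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  xlogx <- function(n, p) ifelse(n > 0 & p > 0, n * log(p), 0)
  bern <- function(n1, n) xlogx(n1, n1 / n) + xlogx(n - n1, 1 - n1 / n)

  pos_a <- a > 0; pos_b <- b > 0
  n1a <- rowSums(pos_a); n1b <- rowSums(pos_b)
  la <- suppressWarnings(log(a)); la[!pos_a] <- 0
  lb <- suppressWarnings(log(b)); lb[!pos_b] <- 0
  sa <- rowSums(la); sb <- rowSums(lb)
  qa <- rowSums(la^2); qb <- rowSums(lb^2)
  mu_a <- ifelse(n1a > 0, sa / n1a, 0)
  mu_b <- ifelse(n1b > 0, sb / n1b, 0)
  n1 <- n1a + n1b

  ssr_alt <- (qa - n1a * mu_a^2) + (qb - n1b * mu_b^2)
  mu_0 <- ifelse(n1 > 0, (sa + sb) / n1, 0)
  ssr_null <- (qa + qb) - n1 * mu_0^2

  stat <- 2 * (bern(n1a, na) + bern(n1b, nb) - bern(n1, na + nb))
  s2_alt <- ifelse(n1 > 0, ssr_alt / n1, 0)
  s2_null <- ifelse(n1 > 0, ssr_null / n1, 0)
  cont <- ifelse(n1 > 1 & s2_alt > 0 & s2_null > 0,
                 n1 * (log(s2_null) - log(s2_alt)), 0)
  stat <- pmax(stat + cont, 0)

  list(
    statistic = stat,
    p = pchisq(stat, df = 2, lower.tail = FALSE),
    direction = sign(rowMeans(a) - rowMeans(b))
  )
}

#' Per-cluster marker genes by all-pairwise bimodal tests
#'
#' For every converged cluster, tests each gene against each other cluster
#' with [bimod_lrt()], adjusting p-values (Benjamini-Hochberg) across genes
#' within each pairwise comparison. A gene is a marker of a cluster when it
#' is overexpressed there with adjusted `p < alpha` against **every** other
#' cluster. Singleton clusters are skipped with a warning.
#'
#' @param expr an expression matrix (genes x cells), typically
#'   depth-scaled counts.
#' @param clusters cluster labels per cell (vector aligned to columns, or a
#'   `cluster_assignment`, whose converged labels are used).
#' @param alpha marker significance level on the adjusted p-value.
#' @return tibble per gene x cluster: `gene`, `cluster`, `min_q`, `max_q`
#'   (worst adjusted p across opponents), `overexpressed_all`, `marker`;
#'   the full per-opponent test table is attached as attribute `"tests"`.
#' @export
find_markers <- function(expr, clusters, alpha = 0.05) {
  if (inherits(clusters, "cluster_assignment")) {
    clusters <- setNames(clusters$converged, clusters$barcode)[colnames(expr)]
  }
  stopifnot(length(clusters) == ncol(expr))
  clusters <- as.character(clusters)
  sizes <- table(clusters)
  if (any(sizes < 2)) {
    warn(sprintf("skipping singleton cluster(s): %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  keep <- names(sizes)[sizes >= 2]
  if (length(keep) < 2) abort("need at least 2 non-singleton clusters")

  expr <- as.matrix(expr)
  tests <- list()
  for (i in seq_along(keep)) {
    for (j in seq_along(keep)) {
      if (i == j) next
      a <- expr[, clusters == keep[i], drop = FALSE]
      b <- expr[, clusters == keep[j], drop = FALSE]
      r <- bimod_lrt_matrix(a, b)
      tests[[length(tests) + 1]] <- tibble(
        gene = rownames(expr), cluster = keep[i], opponent = keep[j],
        statistic = r$statistic, p = r$p,
        q = p.adjust(r$p, method = "BH"),
        overexpressed = r$direction > 0
      )
    }
  }
  tests <- list_rbind(tests)

  out <- tests |>
    group_by(.data$gene, .data$cluster) |>
    summarise(
      min_q = min(.data$q), max_q = max(.data$q),
      overexpressed_all = all(.data$overexpressed),
      .groups = "drop"
    ) |>
    mutate(marker = .data$overexpressed_all & .data$max_q < alpha)
  attr(out, "tests") <- tests
  out
}

#' Annotate clusters against a reference cell-type TPM profile
#'
#' Keeps, for each cluster, the marker genes that are strongly
#' (`top-type TPM >= min_tpm`) and specifically (top type at least `fold`
#' times the runner-up) expressed in one reference cell type, and labels the
#' cluster with the plurality reference type among its retained markers.
#' Clusters with no retained markers, or with a tie, are `"unassigned"`.
#'
#' @param markers a marker table from [find_markers()] (rows with
#'   `marker == TRUE` are used), or any tibble with `gene` and `cluster`.
#' @param ref a `reference_profile` (see [make_reference_profiles()]) or a
#'   genes x types TPM matrix.
#' @param min_tpm minimum own-type TPM of a retained marker.
#' @param fold minimum specificity fold over the runner-up type.
#' @return tibble: `cluster`, `cell_type`, `n_markers`, `n_retained`.
#' @export
annotate_clusters <- function(markers, ref, min_tpm = 50, fold = 4) {
  tpm <- if (inherits(ref, "reference_profile")) ref$tpm else ref
  if ("marker" %in% names(markers)) {
    markers <- filter(markers, .data$marker)
  }
  markers <- select(markers, "gene", "cluster")

  present <- markers$gene %in% rownames(tpm)
  if (!any(present)) {
    warn("no marker gene overlaps the reference; all clusters unassigned")
  }
  assign_gene <- function(g) {
    if (!g %in% rownames(tpm)) return(NA_character_)
    v <- tpm[g, ]
    top <- which.max(v)
    second <- max(v[-top])
    specific <- second == 0 || v[top] >= fold * second  # Inf-fold safe
    if (v[top] >= min_tpm && specific) {
      colnames(tpm)[top]
    } else {
      NA_character_
    }
  }
  markers$ref_type <- vapply(markers$gene, assign_gene, character(1))

  markers |>
    group_by(.data$cluster) |>
    summarise(
      n_markers = dplyr::n(),
      n_retained = sum(!is.na(.data$ref_type)),
      cell_type = {
        tt <- table(.data$ref_type[!is.na(.data$ref_type)])
        if (length(tt) == 0) "unassigned"
        else {
          winners <- names(tt)[tt == max(tt)]
          if (length(winners) > 1) "unassigned" else winners
        }
      },
      .groups = "drop"
    ) |>
    select("cluster", "cell_type", "n_markers", "n_retained")
}

#' Proportionally downsample cells for heatmap display
#'
#' Reduces the total number of cells to at most `max_total`, allocating the
#' budget to clusters in proportion to their sizes (largest-remainder
#' rounding, with every non-empty cluster keeping at least one cell) and
#' sampling uniformly within each cluster. Identity when the total is
#' already within budget.
#'
#' @param clusters cluster labels named by barcode (or a
#'   `cluster_assignment`).
#' @param max_total cell budget.
#' @param seed integer seed.
#' @return character vector of retained barcodes.
#' @export
downsample_for_heatmap <- function(clusters, max_total = 2500, seed = 1L) {
  if (inherits(clusters, "cluster_assignment")) {
    clusters <- setNames(clusters$converged, clusters$barcode)
  }
  if (length(clusters) == 0) abort("empty assignment")
  if (is.null(names(clusters))) abort("labels must be named by barcode")
  if (length(clusters) <= max_total) return(names(clusters))
  set.seed(seed)

  sizes <- table(clusters)
  quota_real <- as.numeric(sizes) / length(clusters) * max_total
  quota <- floor(quota_real)
  rem <- max_total - sum(quota)
  if (rem > 0) {
    bump <- order(quota_real - quota, decreasing = TRUE)[seq_len(rem)]
    quota[bump] <- quota[bump] + 1
  }
  # rounding guard: every non-empty cluster keeps a cell
  while (any(quota == 0)) {
    z <- which(quota == 0)[1]
    donor <- which.max(quota)
    quota[z] <- 1
    quota[donor] <- quota[donor] - 1
  }

  unlist(lapply(seq_along(sizes), function(i) {
    bcs <- names(clusters)[clusters == names(sizes)[i]]
    sample(bcs, quota[i])
  }), use.names = FALSE)
}
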