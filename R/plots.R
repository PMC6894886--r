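#' Plot a log10 density curve with its QC landmarks
#'
#' @param curve a `density_curve` from [estimate_log10_density()].
#' @param threshold optional vertical line (e.g. the local-minimum
#'   threshold found).
#' @return a ggplot.
#' @export
plot_density_curve <- function(curve, threshold = NULL) {
  df <- tibble(x = curve$grid, density = curve$density)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log10(value)", y = "density")
  if (!is.null(threshold) && is.finite(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2)
  }
  p
}

#' Barcode QC overview: log10 UMI distribution by kept/dropped status
#'
#' @param m the unfiltered count matrix.
#' @param report a `qc_report` covering its barcodes.
#' @return a ggplot.
#' @export
plot_qc_barcodes <- function(m, report) {
  df <- tibble(
    barcode = colnames(m),
    log10_umis = log10(pmax(barcode_totals(m), 0.5))
  ) |>
    left_join(report$barcodes, by = "barcode") |>
    mutate(status = if_else(.data$kept, "kept",
                            dplyr::coalesce(.data$reason, "dropped")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_umis,
                                   fill = .data$status)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "log10(#UMIs)", y = "barcodes", fill = NULL)
}

#' Cells in PC space colored by cluster
#'
#' @param e an `embedding`.
#' @param clusters labels named by barcode (or a `cluster_assignment`).
#' @param dims the two components to draw.
#' @return a ggplot.
#' @export
plot_embedding <- function(e, clusters, dims = c(1, 2)) {
  if (inherits(clusters, "cluster_assignment")) {
    clusters <- setNames(clusters$converged, clusters$barcode)
  }
  df <- tibble(
    x = e$coordinates[, dims[1]],
    y = e$coordinates[, dims[2]],
    cluster = factor(clusters[e$cells])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$cluster)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = paste0("PC", dims[1]), y = paste0("PC", dims[2]))
}

#' Volcano-style view of hurdle effects for one component
#'
#' @param effects a `hurdle_effect` table from [hurdle_de()].
#' @param component `"induction"` or `"level"`.
#' @param alpha significance line on the adjusted p-value.
#' @return a ggplot.
#' @export
plot_hurdle_effects <- function(effects, component = c("induction", "level"),
                                alpha = 0.05) {
  component <- match.arg(component)
  eff <- if (component == "induction") effects$ind_effect else
    effects$lev_effect
  q <- if (component == "induction") effects$ind_q else effects$lev_q
  df <- tibble(effect = eff, q = q,
               significant = !is.na(q) & q < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = -log10(pmax(.data$q, 1e-300)),
                                   color = .data$significant)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(
      x = if (component == "induction") "induction effect (log-odds)"
      else "level effect (log fold change)",
      y = "-log10(q)"
    )
}

#' Phyletic pattern heat table
#'
#' @param pattern output of [compile_phyletic_pattern()].
#' @param fill which count to shade: `"total"`, `"protein_coding"`,
#'   `"annotated_pseudogene"` or `"putative_pseudogene"`.
#' @return a ggplot.
#' @export
plot_phyletic_pattern <- function(pattern, fill = "total") {
  ggplot2::ggplot(pattern, ggplot2::aes(x = .data$family, y = .data$species,
                                        fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data[[fill]]), size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = fill)
}

#' Ancestral state probabilities per internal node
#'
#' The bar-per-node analogue of pie-chart ancestral counts: each internal
#' node's co-optimal states with their probabilities.
#'
#' @param anc an `ancestral_states` object.
#' @return a ggplot.
#' @export
plot_ancestral_states <- function(anc) {
  df <- filter(anc$states, .data$probability > 0,
               .data$node > length(anc$tree$tip.label))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$state),
                                   y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$node) +
    ggplot2::labs(x = "gene count", y = "probability")
}
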