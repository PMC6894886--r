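#' Kernel density of log10-transformed values
#'
#' Gaussian kernel density (Silverman's rule by default) of `log10(values)`
#' on a uniform 512-point grid covering the data range padded by three
#' bandwidths. This is the smoother behind all the distributional QC rules
#' (local-minimum barcode/gene thresholds, multiplet modes).
#'
#' @param values positive values (at least 10); zeros must be stripped by
#'   the caller.
#' @param bandwidth a positive bandwidth on the log10 axis, or `"auto"` for
#'   Silverman's rule-of-thumb.
#' @param n grid resolution.
#' @return a `density_curve` list with `grid`, `density` and `bandwidth`.
#' @export
estimate_log10_density <- function(values, bandwidth = "auto", n = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 10) abort("need at least 10 values")
  if (any(values <= 0)) abort("values must be positive (strip zeros first)")
  x <- log10(values)
  if (diff(range(x)) == 0) abort("degenerate distribution: all values equal")
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(x) else bandwidth
  stopifnot(is.numeric(bw), bw > 0)
  d <- stats::density(x, bw = bw, kernel = "gaussian", n = n,
                      from = min(x) - 3 * bw, to = max(x) + 3 * bw)
  structure(list(grid = d$x, density = d$y, bandwidth = bw),
            class = "density_curve")
}

#' Local extrema of a density curve
#'
#' `local_maxima()` returns the locations of the curve's modes: strict
#' local maxima whose height exceeds `min_height_frac` of the global
#' maximum. The height floor discards the microscopic ripples a kernel
#' density estimate develops in sparse tails, which are sampling noise, not
#' modes — a genuine minority mode (a few percent of the observations)
#' sits far above the default 1% floor.
#'
#' `first_local_minimum_above()` returns the smallest valley location
#' strictly greater than `x0`, where a valley is the density minimum
#' between two adjacent modes and must dip to at most `min_dip` of the
#' lower adjacent mode (shallower dips are tail ripples, not separations);
#' `NA` if the curve has fewer than two modes or no qualifying valley lies
#' above `x0`.
#'
#' @param curve a `density_curve`.
#' @param x0 lower bound on the log10 axis.
#' @param min_height_frac mode height floor, as a fraction of the global
#'   maximum density.
#' @param min_dip maximum ratio of valley density to the smaller adjacent
#'   mode's density for the valley to count as a separation.
#' @return a grid location (or `NA_real_`); for `local_maxima()` a numeric
#'   vector.
#' @export
first_local_minimum_above <- function(curve, x0, min_height_frac = 0.01,
                                      min_dip = 0.9) {
  stopifnot(inherits(curve, "density_curve"))
  modes <- local_maxima(curve, min_height_frac = min_height_frac)
  if (length(modes) < 2) return(NA_real_)
  dens_at <- function(x) curve$density[match(x, curve$grid)]
  valleys <- vapply(seq_len(length(modes) - 1), function(i) {
    between <- curve$grid > modes[i] & curve$grid < modes[i + 1]
    v <- curve$grid[between][which.min(curve$density[between])]
    if (dens_at(v) <= min_dip * min(dens_at(modes[i]), dens_at(modes[i + 1])))
      v else NA_real_
  }, numeric(1))
  valleys <- valleys[!is.na(valleys) & valleys > x0]
  if (length(valleys) == 0) NA_real_ else valleys[1]
}

#' @rdname first_local_minimum_above
#' @export
local_maxima <- function(curve, min_height_frac = 0.01) {
  stopifnot(inherits(curve, "density_curve"))
  y <- curve$density
  i <- which(diff(sign(diff(y))) < 0) + 1L
  i <- i[y[i] >= min_height_frac * max(y)]
  curve$grid[i]
}

new_qc_report <- function(barcodes, genes, thresholds) {
  structure(list(barcodes = barcodes, genes = genes,
                 thresholds = thresholds), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  if (nrow(x$barcodes)) {
    cat("barcodes:", sum(x$barcodes$kept), "kept /",
        sum(!x$barcodes$kept), "dropped\n")
  }
  if (nrow(x$genes)) {
    cat("genes:   ", sum(x$genes$kept), "kept /",
        sum(!x$genes$kept), "dropped\n")
  }
  print(x$thresholds)
  invisible(x)
}

#' Turn a QC report into a tidy per-unit table
#'
#' @param x a `qc_report`.
#' @param ... unused.
#' @return tibble with `unit` (`barcode` / `gene`), `id`, `kept`, `reason`.
#' @export
tidy.qc_report <- function(x, ...) {
  bind_rows(
    mutate(rename(x$barcodes, id = "barcode"), unit = "barcode"),
    mutate(rename(x$genes, id = "gene"), unit = "gene")
  ) |> select("unit", "id", "kept", "reason")
}

empty_barcode_report <- function() {
  tibble(barcode = character(), kept = logical(), reason = character())
}
empty_gene_report <- function() {
  tibble(gene = character(), kept = logical(), reason = character())
}

#' Filter cell-less barcodes by the first local minimum rule
#'
#' Drops barcodes whose total UMI count falls below the first local minimum
#' above `x0` (default 2) in the kernel density of `log10(#UMIs)` across
#' barcodes — the valley separating the empty-droplet mode from the captured
#' cells. If no local minimum exists above `x0` nothing is dropped and the
#' report records that. Zero-total barcodes are always dropped.
#'
#' @param m a count matrix.
#' @param x0 lower bound (log10 UMIs) for the threshold search.
#' @param bandwidth passed to [estimate_log10_density()].
#' @return list with `counts` (filtered matrix) and `report` (a
#'   `qc_report`; `thresholds` records the threshold found, `NA` if none).
#' @export
filter_barcodes <- function(m, x0 = 2, bandwidth = "auto") {
  m <- as_count_matrix(m)
  u <- barcode_totals(m)
  pos <- u > 0
  curve <- estimate_log10_density(u[pos], bandwidth = bandwidth)
  thr <- first_local_minimum_above(curve, x0)
  keep <- pos & (if (is.na(thr)) rep(TRUE, length(u)) else log10(pmax(u, 1)) >= thr)
  report <- new_qc_report(
    barcodes = tibble(
      barcode = colnames(m), kept = keep,
      reason = if_else(keep, NA_character_, "low_umi")
    ),
    genes = empty_gene_report(),
    thresholds = tibble(step = "filter_barcodes", quantity = "log10_umis",
                        threshold = thr)
  )
  list(counts = m[, keep, drop = FALSE], report = report)
}

#' Filter sparsely captured genes by the first local minimum rule
#'
#' Mirrors [filter_barcodes()] on the gene axis: drops genes whose
#' number of detecting barcodes falls below the first local minimum above
#' `x0` (default 3) in the density of `log10(#barcodes)` per gene. Genes
#' detected in zero barcodes are removed before density estimation and are
#' always dropped.
#'
#' @param m a count matrix (typically already barcode-filtered).
#' @param x0 lower bound (log10 barcodes) for the threshold search. The
#'   default follows the published rule; it implies detection in ~1000
#'   barcodes and can be lowered for small experiments.
#' @param bandwidth passed to [estimate_log10_density()].
#' @return list with `counts` and `report`, as in [filter_barcodes()].
#' @export
filter_genes <- function(m, x0 = 3, bandwidth = "auto") {
  m <- as_count_matrix(m)
  d <- gene_detection(m)
  pos <- d > 0
  curve <- estimate_log10_density(d[pos], bandwidth = bandwidth)
  thr <- first_local_minimum_above(curve, x0)
  keep <- pos & (if (is.na(thr)) rep(TRUE, length(d)) else log10(pmax(d, 1)) >= thr)
  report <- new_qc_report(
    barcodes = empty_barcode_report(),
    genes = tibble(
      gene = rownames(m), kept = keep,
      reason = if_else(keep, NA_character_, "sparse_gene")
    ),
    thresholds = tibble(step = "filter_genes", quantity = "log10_barcodes",
                        threshold = thr)
  )
  list(counts = m[keep, , drop = FALSE], report = report)
}

#' Detect and remove multiplet barcodes as inflated local modes
#'
#' In each of the `log10(#genes)` and `log10(#UMIs)` distributions across
#' (already barcode-filtered) barcodes, finds local modes that are inflated
#' relative to the global mode and hold fewer than `max_frac` of all
#' barcodes; barcodes belonging to such a mode (above the density valley
#' separating it from the global mode) are flagged as multiplets, taking the
#' union over the two distributions.
#'
#' Inflation is judged by `ratio_scale`:
#' * `"linear"` (default): the mode's UMI/gene count is more than `ratio`
#'   times the global mode's count, i.e. `10^x > ratio * 10^x_global`. A
#'   doublet carries about twice a singlet's UMIs, so it clears the default
#'   1.5 threshold.
#' * `"log10"`: the literal position ratio on the log10 axis,
#'   `x > ratio * x_global`. At realistic depths no genuine doublet mode can
#'   satisfy this; the option is kept for strict reproduction of the rule as
#'   worded.
#'
#' @param m a barcode-filtered count matrix.
#' @param ratio mode-location inflation threshold.
#' @param max_frac maximum barcode share of a multiplet mode.
#' @param ratio_scale `"linear"` or `"log10"` (see above).
#' @param bandwidth passed to [estimate_log10_density()].
#' @param min_dip a candidate mode counts only if the valley separating it
#'   from the global mode dips to at most this fraction of the smaller of
#'   the two mode heights (see [first_local_minimum_above()]).
#' @return list with `counts` and `report` (dropped reason `"multiplet"`).
#' @export
detect_multiplets <- function(m, ratio = 1.5, max_frac = 0.05,
                              ratio_scale = c("linear", "log10"),
                              bandwidth = "auto", min_dip = 0.9) {
  m <- as_count_matrix(m)
  ratio_scale <- match.arg(ratio_scale)
  flagged <- rep(FALSE, ncol(m))
  thresholds <- list()

  for (quantity in c("log10_genes", "log10_umis")) {
    v <- if (quantity == "log10_genes") barcode_gene_counts(m) else
      barcode_totals(m)
    # a constant distribution (e.g. every gene detected everywhere) simply
    # carries no multiplet signal on this axis
    curve <- tryCatch(
      estimate_log10_density(v[v > 0], bandwidth = bandwidth),
      error = function(e) NULL
    )
    if (is.null(curve)) next
    maxima <- local_maxima(curve)
    if (length(maxima) < 2) next
    heights <- curve$density[match(maxima, curve$grid)]
    x_glob <- maxima[which.max(heights)]
    inflated <- switch(ratio_scale,
      linear = maxima[maxima - x_glob > log10(ratio)],
      log10 = maxima[maxima > ratio * x_glob & maxima > x_glob]
    )
    dens_at <- function(x) curve$density[match(x, curve$grid)]
    for (x_mode in inflated) {
      between <- curve$grid > x_glob & curve$grid < x_mode
      if (!any(between)) next
      valley <- curve$grid[between][which.min(curve$density[between])]
      if (dens_at(valley) > min_dip * min(dens_at(x_glob), dens_at(x_mode)))
        next  # shallow ripple, not a separated mode
      members <- log10(pmax(v, 1)) > valley & v > 0
      share <- mean(members)
      ok <- share < max_frac
      if (ok) flagged <- flagged | members
      thresholds[[length(thresholds) + 1]] <- tibble(
        step = "detect_multiplets", quantity = quantity,
        threshold = valley, mode = x_mode, share = share, applied = ok
      )
    }
  }

  thr <- if (length(thresholds)) list_rbind(thresholds) else
    tibble(step = character(), quantity = character(), threshold = numeric(),
           mode = numeric(), share = numeric(), applied = logical())
  report <- new_qc_report(
    barcodes = tibble(
      barcode = colnames(m), kept = !flagged,
      reason = if_else(flagged, "multiplet", NA_character_)
    ),
    genes = empty_gene_report(),
    thresholds = thr
  )
  list(counts = m[, !flagged, drop = FALSE], report = report)
}

#' Run the full droplet QC pipeline
#'
#' Applies [filter_barcodes()], then [filter_genes()], then
#' [detect_multiplets()] and merges the three reports.
#'
#' @param m a raw count matrix.
#' @param umi_x0,gene_x0 local-minimum search lower bounds.
#' @param ratio,max_frac,ratio_scale multiplet rule parameters.
#' @return list with `counts` and `report`.
#' @export
run_droplet_qc <- function(m, umi_x0 = 2, gene_x0 = 3,
                           ratio = 1.5, max_frac = 0.05,
                           ratio_scale = "linear") {
  s1 <- filter_barcodes(m, x0 = umi_x0)
  s2 <- filter_genes(s1$counts, x0 = gene_x0)
  s3 <- detect_multiplets(s2$counts, ratio = ratio, max_frac = max_frac,
                          ratio_scale = ratio_scale)
  barcodes <- s1$report$barcodes
  mult <- s3$report$barcodes
  idx <- match(mult$barcode, barcodes$barcode)
  barcodes$kept[idx] <- mult$kept
  barcodes$reason[idx] <- mult$reason
  report <- new_qc_report(
    barcodes = barcodes,
    genes = s2$report$genes,
    thresholds = bind_rows(s1$report$thresholds, s2$report$thresholds,
                           s3$report$thresholds)
  )
  list(counts = s3$counts, report = report)
}
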