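#' Build a synthetic reference cell-type TPM profile
#'
#' Emulates a sorted-cell-type reference expression compendium in transcripts
#' per million: each cell type gets `markers_per_type` dedicated marker genes
#' whose TPM exceeds every other type's by at least `specificity_factor`;
#' every column sums to one million. Each type receives the same number of
#' markers at the same raw level, so column normalization preserves the
#' planted specificity ratios exactly.
#'
#' @param cell_types character vector of at least two cell-type names.
#' @param genes character vector of gene identifiers.
#' @param specificity_factor minimum fold by which a marker's own-type TPM
#'   exceeds the runner-up type.
#' @param markers_per_type dedicated markers per type (ignored when
#'   `marker_genes` is given).
#' @param marker_genes optional named list, cell type -> character vector of
#'   its marker genes (mutually disjoint, all present in `genes`); defaults
#'   to a random disjoint assignment.
#' @param seed integer seed (baseline jitter only).
#' @return list of class `reference_profile` with `tpm` (genes x types
#'   matrix, columns summing to 1e6) and `markers` (tibble `gene`,
#'   `cell_type`).
#' @export
make_reference_profiles <- function(cell_types, genes,
                                    specificity_factor = 4,
                                    markers_per_type = 5,
                                    marker_genes = NULL,
                                    seed = 1L) {
  if (length(cell_types) < 2) abort("need at least 2 reference cell types")
  set.seed(seed)

  n_g <- length(genes)
  n_t <- length(cell_types)

  if (is.null(marker_genes)) {
    if (n_g < n_t * markers_per_type) {
      abort("not enough genes for the requested markers")
    }
    idx <- matrix(sample.int(n_g, n_t * markers_per_type),
                  nrow = markers_per_type)
    marker_genes <- lapply(seq_len(n_t), function(j) genes[idx[, j]])
    names(marker_genes) <- cell_types
  } else {
    stopifnot(setequal(names(marker_genes), cell_types))
    all_mk <- unlist(marker_genes)
    if (anyDuplicated(all_mk) || !all(all_mk %in% genes)) {
      abort("marker_genes must be disjoint and present in `genes`")
    }
  }

  base <- 100
  tpm <- matrix(base, nrow = n_g, ncol = n_t,
                dimnames = list(genes, cell_types))
  # 5% headroom keeps the planted ratio strictly above the factor; equal raw
  # marker mass per column keeps normalization from distorting the ratios
  n_mk <- lengths(marker_genes)[cell_types]
  if (length(unique(n_mk)) > 1) {
    warn("unequal marker counts per type: specificity ratios shift slightly")
  }
  for (ct in cell_types) {
    tpm[marker_genes[[ct]], ct] <- base * specificity_factor * 1.05
  }
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6

  structure(list(
    tpm = tpm,
    markers = tibble(
      gene = unlist(marker_genes, use.names = FALSE),
      cell_type = rep(cell_types, times = n_mk)
    )
  ), class = "reference_profile")
}
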