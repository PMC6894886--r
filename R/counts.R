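#' Gene-by-barcode UMI count matrices
#'
#' Throughout the package a UMI count matrix is a sparse
#' [`Matrix::dgCMatrix`] with genes as rows and droplet barcodes as columns,
#' both carried as `dimnames`. `as_count_matrix()` validates and coerces any
#' matrix-like input into this canonical form.
#'
#' @param x a matrix or Matrix with genes in rows, barcodes in columns;
#'   `dimnames` must be set, unique and free of `NA`.
#' @return a `dgCMatrix` of non-negative integer counts.
#' @examples
#' m <- as_count_matrix(matrix(c(0, 1, 2, 3), 2,
#'   dimnames = list(c("g1", "g2"), c("bc1", "bc2"))))
#' barcode_totals(m)
#' @export
as_count_matrix <- function(x) {
  m <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("count matrix must carry gene rownames and barcode colnames")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("duplicate gene or barcode identifiers")
  }
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    abort("counts must be non-negative integers")
  }
  m
}

#' Per-barcode and per-gene summaries
#'
#' `barcode_totals()` returns the total UMIs per barcode (`U_c`),
#' `barcode_gene_counts()` the number of genes detected per barcode (`G_c`),
#' and `gene_detection()` the number of barcodes in which each gene is
#' detected (`D_g`). These are the quantities whose log10 distributions drive
#' the droplet QC rules.
#'
#' @param m a count matrix (genes x barcodes).
#' @return a named numeric vector.
#' @export
barcode_totals <- function(m) Matrix::colSums(m)

#' @rdname barcode_totals
#' @export
barcode_gene_counts <- function(m) Matrix::colSums(m > 0)

#' @rdname barcode_totals
#' @export
gene_detection <- function(m) Matrix::rowSums(m > 0)

#' Read and write MatrixMarket count triplets
#'
#' The on-disk interchange format is the 10x-style triplet: `matrix.mtx`
#' (MatrixMarket coordinate integer), `features.tsv` (gene ids) and
#' `barcodes.tsv`, all uncompressed in one directory. Counts round-trip
#' bit-exactly.
#'
#' @param m a count matrix.
#' @param dir directory to write to / read from (created if missing).
#' @return `write_count_mtx()` returns `dir` invisibly; `read_count_mtx()`
#'   returns a count matrix.
#' @export
write_count_mtx <- function(m, dir) {
  m <- as_count_matrix(m)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_count_mtx
#' @export
read_count_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(
    readLines(file.path(dir, "features.tsv")),
    readLines(file.path(dir, "barcodes.tsv"))
  )
  as_count_matrix(m)
}
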