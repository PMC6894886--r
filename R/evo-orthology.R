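#' Read a 12-column BLAST tabular hit file
#'
#' Standard outfmt-6 columns: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path TSV file without header.
#' @return tibble with the 12 standard columns.
#' @export
read_blast_tab <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore"),
    col_types = "ccdiiiiiiidd", progress = FALSE
  )
}

# default form -> gene mapping: strip a trailing -T<k> / -P<k> isoform tag
strip_form <- function(x) sub("-[TP][0-9]+$", "", x)

#' One-to-one orthologs by reciprocal best hits
#'
#' Filters both directional hit tables to `evalue < e_max` and
#' `pident > id_min` (strict, so a hit at exactly `id_min` is excluded),
#' aggregates transcript/protein forms to genes (best bitscore, ties broken
#' by e-value then identity), and retains gene pairs that are each other's
#' best hit in both directions.
#'
#' @param hits_ab,hits_ba BLAST tabular tibbles (A queries vs B, and the
#'   reverse).
#' @param form_to_gene function mapping a form identifier to its gene id
#'   (default strips a trailing `-T<k>`/`-P<k>` isoform suffix).
#' @param e_max,id_min hit retention thresholds.
#' @return tibble of unordered ortholog pairs: `gene_a`, `gene_b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba,
                                 form_to_gene = strip_form,
                                 e_max = 0.1, id_min = 80) {
  best_per_gene <- function(hits) {
    hits <- filter(hits, .data$evalue < e_max, .data$pident > id_min)
    if (nrow(hits) == 0) {
      return(tibble(qgene = character(), sgene = character(),
                    bitscore = numeric(), evalue = numeric(),
                    pident = numeric()))
    }
    hits |>
      mutate(qgene = form_to_gene(.data$qseqid),
             sgene = form_to_gene(.data$sseqid)) |>
      group_by(.data$qgene, .data$sgene) |>
      summarise(bitscore = max(.data$bitscore),
                evalue = min(.data$evalue),
                pident = max(.data$pident), .groups = "drop") |>
      group_by(.data$qgene) |>
      arrange(dplyr::desc(.data$bitscore), .data$evalue,
              dplyr::desc(.data$pident), .data$sgene, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
  }
  fwd <- best_per_gene(hits_ab)
  rev <- best_per_gene(hits_ba)
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  inner_join(
    select(fwd, gene_a = "qgene", gene_b = "sgene"),
    select(rev, gene_b = "qgene", gene_a = "sgene"),
    by = c("gene_a", "gene_b")
  ) |>
    arrange(.data$gene_a)
}

#' Fold annotated pseudogenes into family orthogroups
#'
#' Any annotated pseudogene whose transcript hits any protein-coding member
#' of a family orthogroup (at `evalue < e_max`, `pident > id_min`) joins
#' that family. A pseudogene hitting several families is assigned to the
#' family of its best e-value hit; exact ties are broken by identity and
#' flagged.
#'
#' @param orthogroups tibble assigning protein-coding genes to families:
#'   columns `gene_id`, `family`.
#' @param pseudo_hits BLAST tabular tibble with pseudogene forms as queries
#'   and protein-coding forms as subjects.
#' @param form_to_gene,e_max,id_min as in [reciprocal_best_hits()].
#' @return tibble: `gene_id` (pseudogene), `family`, `evalue`, `pident`,
#'   `tie` (logical).
#' @export
augment_orthogroups <- function(orthogroups, pseudo_hits,
                                form_to_gene = strip_form,
                                e_max = 0.1, id_min = 80) {
  hits <- pseudo_hits |>
    filter(.data$evalue < e_max, .data$pident > id_min) |>
    mutate(gene_id = form_to_gene(.data$qseqid),
           sgene = form_to_gene(.data$sseqid)) |>
    inner_join(select(orthogroups, sgene = "gene_id", "family"),
               by = "sgene")
  if (nrow(hits) == 0) {
    return(tibble(gene_id = character(), family = character(),
                  evalue = numeric(), pident = numeric(), tie = logical()))
  }
  hits |>
    group_by(.data$gene_id, .data$family) |>
    summarise(evalue = min(.data$evalue), pident = max(.data$pident),
              .groups = "drop") |>
    group_by(.data$gene_id) |>
    arrange(.data$evalue, dplyr::desc(.data$pident), .data$family,
            .by_group = TRUE) |>
    mutate(tie = dplyr::n() > 1 &
             .data$evalue[1] == dplyr::nth(.data$evalue, 2, default = Inf) &
             .data$pident[1] == dplyr::nth(.data$pident, 2, default = -Inf)) |>
    slice(1) |>
    ungroup()
}
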