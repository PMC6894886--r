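overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1  # 1-based inclusive

# merge interval-overlapping genomic hits sharing a (species, scaffold,
# family); the merged hit keeps the best-evidence domain confirmation
merge_family_hits <- function(hits) {
  hits |>
    group_by(.data$species, .data$scaffold, .data$q_family) |>
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::IRanges(start = df$start, end = df$end)
      red <- IRanges::reduce(ir)
      ov <- IRanges::findOverlaps(ir, red)
      df$merged <- S4Vectors::subjectHits(ov)
      df |>
        group_by(.data$merged) |>
        summarise(
          start = min(.data$start), end = max(.data$end),
          pident = max(.data$pident),
          dom_evalue = min(.data$dom_evalue),
          dom_pident = .data$dom_pident[which.min(.data$dom_evalue)],
          n_hits = dplyr::n(),
          .groups = "drop"
        ) |>
        select(-"merged")
    }) |>
    ungroup() |>
    rename(family = "q_family")
}

#' Detect putative (unannotated) pseudogenes from genomic homology hits
#'
#' Five-stage pipeline over EST-vs-genome homology hits:
#' 1. keep hits with identity of at least `id_min` (default 40%);
#' 2. merge interval-overlapping hits whose queries share a gene family
#'    (union of intervals);
#' 3. keep merged hits whose conserved-domain confirmation passes
#'    `e-value < dom_e_max` **and** `identity > dom_id_min`;
#' 4. restrict to the family's locus scaffolds;
#' 5. drop hits overlapping any annotated gene (protein-coding or
#'    pseudogene) on the same scaffold.
#'
#' Surviving intervals are emitted as putative pseudogenes of the query
#' family.
#'
#' @param genomic_hits tibble with `qseqid`, `q_family`, `species`,
#'   `scaffold`, `start`, `end`, `pident`, and the merged-hit domain
#'   confirmation columns `dom_evalue`, `dom_pident`. Coordinates are
#'   1-based inclusive; rows lacking them are a parse error.
#' @param annotations gene records (`species`, `gene_id`, `family`,
#'   `biotype`, `scaffold`, `start`, `end`).
#' @param locus_scaffolds tibble (`family`, `scaffold`) giving each
#'   family's locus scaffolds; derived from `annotations` when `NULL`.
#' @param id_min,dom_e_max,dom_id_min stage thresholds.
#' @return gene-record tibble of putative pseudogenes (biotype
#'   `"putative_pseudogene"`).
#' @export
detect_putative_pseudogenes <- function(genomic_hits, annotations,
                                        locus_scaffolds = NULL,
                                        id_min = 40, dom_e_max = 0.1,
                                        dom_id_min = 60) {
  req <- c("qseqid", "q_family", "species", "scaffold", "start", "end",
           "pident", "dom_evalue", "dom_pident")
  if (!all(req %in% names(genomic_hits))) {
    abort(paste("genomic hits missing columns:",
                paste(setdiff(req, names(genomic_hits)), collapse = ", ")))
  }
  if (anyNA(genomic_hits$start) || anyNA(genomic_hits$end)) {
    abort("genomic hits lacking coordinates")
  }
  if (is.null(locus_scaffolds)) {
    locus_scaffolds <- distinct(annotations, .data$family, .data$scaffold)
  }

  merged <- genomic_hits |>
    filter(.data$pident >= id_min) |>
    merge_family_hits() |>
    filter(.data$dom_evalue < dom_e_max, .data$dom_pident > dom_id_min) |>
    inner_join(locus_scaffolds, by = c("family", "scaffold"))

  if (nrow(merged) == 0) {
    return(tibble(species = character(), gene_id = character(),
                  symbol = character(), family = character(),
                  biotype = character(), scaffold = character(),
                  start = integer(), end = integer()))
  }

  covered <- purrr::pmap_lgl(
    merged[, c("species", "scaffold", "start", "end")],
    function(species, scaffold, start, end) {
      ann <- annotations[annotations$species == species &
                           annotations$scaffold == scaffold, ]
      any(overlaps(start, end, ann$start, ann$end))
    }
  )

  merged[!covered, ] |>
    mutate(
      gene_id = sprintf("%s_%s_psi_%s_%d", .data$species, .data$family,
                        .data$scaffold, .data$start),
      symbol = NA_character_,
      biotype = "putative_pseudogene"
    ) |>
    select("species", "gene_id", "symbol", "family", "biotype",
           "scaffold", "start", "end")
}

#' Benchmark the pseudogene search's false-positive rate
#'
#' Among merged genomic hits that cover annotated genes, counts — per query
#' family and searched genome — the share whose covered gene belongs to a
#' *different* family than the query. Families at or above `flag_threshold`
#' (default 5%) are flagged; putative pseudogene calls for flagged families
#' should not be interpreted (as happens for the immunoglobulin-domain
#' families whose defining domain is shared).
#'
#' @param genomic_hits,annotations,id_min as in
#'   [detect_putative_pseudogenes()].
#' @param flag_threshold FP fraction at which a family is flagged.
#' @return tibble: `family`, `species`, `n_covering`, `fp_fraction` (`NA`
#'   when no hit covers an annotated gene), `flagged`.
#' @export
benchmark_false_positives <- function(genomic_hits, annotations,
                                      id_min = 40, flag_threshold = 0.05) {
  merged <- genomic_hits |>
    filter(.data$pident >= id_min) |>
    merge_family_hits()

  hit_fp <- purrr::pmap(
    merged[, c("species", "scaffold", "start", "end", "family")],
    function(species, scaffold, start, end, family) {
      ann <- annotations[annotations$species == species &
                           annotations$scaffold == scaffold, ]
      cov <- overlaps(start, end, ann$start, ann$end)
      if (!any(cov)) return(NULL)
      tibble(family = family, species = species,
             fp = !any(ann$family[cov] == family))
    }
  ) |> list_rbind()

  grid <- distinct(merged, .data$family, .data$species)
  stats <- if (!is.null(hit_fp) && nrow(hit_fp)) {
    hit_fp |>
      group_by(.data$family, .data$species) |>
      summarise(n_covering = dplyr::n(), fp_fraction = mean(.data$fp),
                .groups = "drop")
  } else {
    tibble(family = character(), species = character(),
           n_covering = integer(), fp_fraction = numeric())
  }
  grid |>
    left_join(stats, by = c("family", "species")) |>
    mutate(
      n_covering = dplyr::coalesce(.data$n_covering, 0L),
      flagged = !is.na(.data$fp_fraction) &
        .data$fp_fraction >= flag_threshold
    )
}

#' Compile a species-by-family phyletic pattern
#'
#' Counts protein-coding genes (P), annotated pseudogenes (Psi) and putative
#' pseudogenes (psi) per species and family. Putative pseudogene counts are
#' forced to zero for families in `exclude_putative` (by default the
#' domain-sharing LILR and KIR families, whose genomic hits cannot be
#' attributed reliably). Species or families with no records get explicit
#' zeros.
#'
#' @param annotations gene records, including putative-pseudogene rows from
#'   [detect_putative_pseudogenes()].
#' @param species,families levels to tabulate (defaults: those present).
#' @param exclude_putative families whose psi counts are zeroed.
#' @return tibble: `species`, `family`, `protein_coding`,
#'   `annotated_pseudogene`, `putative_pseudogene`, `total`.
#' @export
compile_phyletic_pattern <- function(annotations,
                                     species = NULL, families = NULL,
                                     exclude_putative = c("LILR", "KIR")) {
  if (is.null(species)) species <- sort(unique(annotations$species))
  if (is.null(families)) families <- sort(unique(annotations$family))

  counts <- annotations |>
    filter(.data$species %in% !!species, .data$family %in% families) |>
    count(.data$species, .data$family, .data$biotype)

  tidyr::expand_grid(species = species, family = families) |>
    left_join(
      tidyr::pivot_wider(counts, names_from = "biotype",
                         values_from = "n", values_fill = 0L),
      by = c("species", "family")
    ) |>
    mutate(across(dplyr::any_of(c("protein_coding", "annotated_pseudogene",
                                  "putative_pseudogene")),
                  ~ dplyr::coalesce(.x, 0L))) |>
    (\(df) {
      for (col in c("protein_coding", "annotated_pseudogene",
                    "putative_pseudogene")) {
        if (!col %in% names(df)) df[[col]] <- 0L
      }
      df
    })() |>
    mutate(
      putative_pseudogene = if_else(.data$family %in% exclude_putative,
                                    0L, .data$putative_pseudogene),
      total = .data$protein_coding + .data$annotated_pseudogene +
        .data$putative_pseudogene
    ) |>
    select("species", "family", "protein_coding", "annotated_pseudogene",
           "putative_pseudogene", "total")
}
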