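#' Simulate an ISH puncta-bin cell-count table
#'
#' Each cell is positive for a probe with probability
#' `plogis(baseline + effect * I(species != baseline_species))`; a positive
#' cell draws `1 + Geometric(geom_prob)` puncta, binned into 1..9 and "10+"
#' (ten bins). The output mirrors the per-sample puncta-bin cell-count
#' tables produced by automated ISH image analysis.
#'
#' @param n_samples samples (slides) per species.
#' @param cells_per_sample DAPI-positive cells scored per sample.
#' @param probe_effects named numeric: probe -> log-odds shift of positivity
#'   in the non-baseline species.
#' @param baseline log-odds that a baseline-species cell is positive.
#' @param species character vector of two species, baseline first.
#' @param geom_prob success probability of the geometric puncta distribution.
#' @param seed integer seed.
#' @return a tibble with `species`, `sample`, `probe`, `bin` (factor
#'   `"1"`..`"9"`, `"10+"`), `cells` (count in that bin) and `total_cells`
#'   (DAPI total for the sample); all ten bins present for every
#'   species/sample/probe.
#' @export
simulate_puncta_table <- function(n_samples = 4,
                                  cells_per_sample = 1000,
                                  probe_effects = c(Cd3e = 0),
                                  baseline = -1,
                                  species = c("mouse", "naked mole-rat"),
                                  geom_prob = 0.4,
                                  seed = 1L) {
  stopifnot(length(species) == 2, n_samples >= 1, cells_per_sample >= 1)
  if (is.null(names(probe_effects)) || any(!is.finite(probe_effects))) {
    abort("probe_effects must be a named vector of finite log-odds")
  }
  set.seed(seed)

  bins <- puncta_bins()
  rows <- list()
  for (sp in species) {
    shift <- if (sp == species[1]) 0 else 1
    for (s in seq_len(n_samples)) {
      for (pr in names(probe_effects)) {
        p_pos <- plogis(baseline + probe_effects[[pr]] * shift)
        pos <- rbinom(1, cells_per_sample, p_pos)
        puncta <- 1L + rgeom(pos, geom_prob)
        binned <- factor(ifelse(puncta >= 10, "10+", as.character(puncta)),
                         levels = bins)
        tab <- table(binned)
        rows[[length(rows) + 1]] <- tibble(
          species = sp,
          sample = paste0(sp, "_s", s),
          probe = pr,
          bin = bins,
          cells = as.integer(tab[bins]),
          total_cells = cells_per_sample
        )
      }
    }
  }
  out <- list_rbind(rows)
  out$bin <- factor(out$bin, levels = bins)
  out
}

#' Puncta bin labels (1..9 and "10+")
#' @return character vector of the ten bin labels.
#' @export
puncta_bins <- function() c(as.character(1:9), "10+")
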