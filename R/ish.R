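#' Binarize a puncta table at a bin threshold
#'
#' For puncta bin `b` (2..10), cells with at least `b` puncta are positive
#' and all remaining DAPI-counted cells (fewer puncta, including zero) are
#' negative; bin 10 selects only the "10+" bin. Counts are aggregated per
#' species and sample.
#'
#' @param table a puncta table as produced by [simulate_puncta_table()]
#'   (columns `species`, `sample`, `probe`, `bin`, `cells`, `total_cells`).
#' @param probe probe to binarize.
#' @param b bin threshold in `2:10`.
#' @return tibble: `species`, `sample`, `positive`, `negative`.
#' @export
binarize_at_bin <- function(table, probe, b) {
  stopifnot(b %in% 2:10)
  tb <- filter(table, .data$probe == !!probe)
  if (nrow(tb) == 0) abort(sprintf("probe %s absent from table", probe))
  bin_num <- match(as.character(tb$bin), puncta_bins())
  if (anyNA(bin_num)) abort("unrecognized puncta bin label")
  tb |>
    mutate(bin_num = bin_num) |>
    group_by(.data$species, .data$sample) |>
    summarise(
      positive = sum(.data$cells[.data$bin_num >= b]),
      negative = dplyr::first(.data$total_cells) -
        sum(.data$cells[.data$bin_num >= b]),
      .groups = "drop"
    )
}

#' Species effect on positivity at one puncta bin
#'
#' Two-category multinomial (logistic) regression of cell positivity on
#' species, pooled over samples within species, with the baseline species'
#' log-odds as reference: the effect is the log-odds difference of
#' positivity in the other species. When any pooled cell of the 2x2 table
#' is zero, a 0.5 continuity correction is applied and flagged.
#'
#' @param counts output of [binarize_at_bin()].
#' @param baseline baseline species (default `"mouse"`).
#' @return tibble: `effect`, `se`, `corrected`.
#' @export
species_effect_at_bin <- function(counts, baseline = "mouse") {
  species <- unique(counts$species)
  if (length(species) != 2 || !baseline %in% species) {
    abort("need exactly 2 species including the baseline")
  }
  pooled <- counts |>
    group_by(.data$species) |>
    summarise(positive = sum(.data$positive),
              negative = sum(.data$negative), .groups = "drop") |>
    arrange(.data$species != baseline)  # baseline first
  cc <- as.matrix(pooled[, c("positive", "negative")])
  corrected <- any(cc == 0)
  if (corrected) cc <- cc + 0.5
  effect <- unname(log(cc[2, 1] / cc[2, 2]) - log(cc[1, 1] / cc[1, 2]))
  se <- unname(sqrt(sum(1 / cc)))  # Woolf
  tibble(effect = effect, se = se, corrected = corrected)
}

#' Combine per-bin species effects into one z-statistic
#'
#' Propagates the uncertainty of choosing any particular puncta bin by
#' averaging the per-bin effects (bins 2..10) and dividing the mean by a
#' standard error to form a z-statistic, from which a two-sided normal
#' p-value follows.
#'
#' The per-bin effects come from binarizing the *same* cells at nine
#' thresholds and are therefore strongly positively correlated, so the
#' naive `sd(effects)/sqrt(n)` drastically understates the sampling error
#' of their mean (it measures only the bin-to-bin differences, not the
#' shared component). The default therefore takes the mean of the per-bin
#' regression standard errors, which is the correct limit under perfect
#' correlation and conservative otherwise. `se_method = "sd"` gives the
#' naive between-bin estimate and `"invvar"` the inverse-variance
#' (independence) combination, both anticonservative here.
#'
#' When the chosen SE is zero the z is signed infinite and p underflows to
#' the smallest positive double.
#'
#' @param effects numeric vector of per-bin effects (finite entries used).
#' @param ses per-bin standard errors aligned to `effects` (required for
#'   `"propagated"` and `"invvar"`).
#' @param se_method `"propagated"` (default), `"sd"` or `"invvar"`.
#' @return tibble: `mean_effect`, `se`, `z`, `p`, `n_bins`.
#' @export
combine_bins <- function(effects, ses = NULL,
                         se_method = c("propagated", "sd", "invvar")) {
  se_method <- match.arg(se_method)
  ok <- is.finite(effects)
  if (se_method != "sd") {
    if (is.null(ses)) abort("`ses` is required for this se_method")
    stopifnot(length(ses) == length(effects))
    ok <- ok & is.finite(ses)
    ses <- ses[ok]
  }
  effects <- effects[ok]
  if (length(effects) < 2) {
    abort("need at least 2 bins with finite effects")
  }
  m <- mean(effects)
  se <- switch(se_method,
    propagated = mean(ses),
    sd = sd(effects) / sqrt(length(effects)),
    invvar = 1 / sqrt(sum(1 / ses^2))
  )
  z <- if (se == 0) sign(m) * Inf else m / se
  p <- 2 * pnorm(-abs(z))
  if (p == 0) p <- .Machine$double.xmin
  tibble(mean_effect = m, se = se, z = z, p = p,
         n_bins = length(effects))
}

#' Full ISH species-effect analysis per probe
#'
#' Runs [binarize_at_bin()] and [species_effect_at_bin()] for every bin
#' 2..10 and combines them with [combine_bins()].
#'
#' @param table a puncta table.
#' @param baseline baseline species.
#' @param se_method passed to [combine_bins()].
#' @return a `combined_effect` tibble, one row per probe: `probe`,
#'   `mean_effect`, `se`, `z`, `p`, `n_bins`, with the per-bin effects
#'   attached as attribute `"bins"`.
#' @export
ish_species_effects <- function(table, baseline = "mouse",
                                se_method = "propagated") {
  probes <- unique(table$probe)
  bin_rows <- list()
  out <- map(probes, function(pr) {
    per_bin <- map(2:10, function(b) {
      e <- species_effect_at_bin(binarize_at_bin(table, pr, b),
                                 baseline = baseline)
      bin_rows[[length(bin_rows) + 1]] <<-
        mutate(e, probe = pr, bin = b)
      e
    }) |> list_rbind()
    mutate(combine_bins(per_bin$effect, per_bin$se, se_method = se_method),
           probe = pr)
  }) |> list_rbind() |>
    select("probe", dplyr::everything())
  attr(out, "bins") <- list_rbind(bin_rows)
  class(out) <- c("combined_effect", class(out))
  out
}

#' @export
tidy.combined_effect <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.combined_effect <- function(x, ...) {
  tibble(n_probes = nrow(x),
         n_significant = sum(x$p < 0.05))
}
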