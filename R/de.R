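#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (via [stats::p.adjust()]). `NA`/`NaN` p-values propagate unchanged.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values (q-values), same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05))  # all 0.05
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

glmer_quiet <- function(expr) {
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(expr, error = function(e) NULL),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  list(fit = fit, converged = converged && !is.null(fit))
}

wald_row <- function(fit, term) {
  s <- coef(summary(fit))
  i <- grep(term, rownames(s))[1]
  c(effect = s[i, 1], se = s[i, 2],
    p = 2 * pnorm(-abs(s[i, 1] / s[i, 2])))
}

#' Expression-induction component of the hurdle model
#'
#' Fits a logistic mixed-effects regression of the binarized outcome
#' (expressed / not expressed per cell) on condition, with a random
#' intercept per sample and the control condition as baseline
#' (Laplace-approximated ML via [lme4::glmer()]). The effect is the
#' log-odds change in the probability of expressing the gene. On
#' non-convergence the fit falls back to a fixed-effects GLM with sample as
#' a covariate; on complete separation to the Haldane-corrected (add 0.5)
#' 2x2 log odds ratio with Woolf standard error. Both fallbacks are
#' flagged.
#'
#' @param y binary 0/1 expression indicator per cell.
#' @param condition factor with the control level first.
#' @param sample sample (replicate) identifier per cell.
#' @return one-row tibble: `effect`, `se`, `p`, `converged`, `fallback`.
#' @export
fit_induction_model <- function(y, condition, sample) {
  condition <- droplevels(as.factor(condition))
  sample <- as.factor(sample)
  if (nlevels(condition) < 2) abort("both conditions must be present")
  if (nlevels(sample) < 2) abort("need at least 2 samples")
  if (all(y == y[1])) {
    return(tibble(effect = NA_real_, se = NA_real_, p = NA_real_,
                  converged = FALSE, fallback = "degenerate"))
  }

  # aggregate to binomial counts per sample x condition (same likelihood)
  agg <- tibble(y = y, condition = condition, sample = sample) |>
    group_by(.data$condition, .data$sample) |>
    summarise(succ = sum(.data$y), fail = sum(1 - .data$y),
              .groups = "drop")

  res <- glmer_quiet(lme4::glmer(
    cbind(succ, fail) ~ condition + (1 | sample),
    data = agg, family = binomial()
  ))
  fallback <- NA_character_
  fit <- res$fit
  if (!res$converged) {
    fit <- tryCatch(
      glm(cbind(succ, fail) ~ condition + sample, data = agg,
          family = binomial()),
      error = function(e) NULL
    )
    fallback <- "glm"
  }
  est <- if (!is.null(fit)) wald_row(fit, "^condition") else
    c(effect = NA, se = NA, p = NA)

  if (is.null(fit) || !is.finite(est["se"]) || est["se"] > 10) {
    # complete separation: Haldane-corrected 2x2 log odds ratio
    t2 <- agg |>
      group_by(.data$condition) |>
      summarise(succ = sum(.data$succ), fail = sum(.data$fail),
                .groups = "drop")
    cc <- as.matrix(t2[, c("succ", "fail")]) + 0.5
    effect <- log(cc[2, 1] / cc[2, 2]) - log(cc[1, 1] / cc[1, 2])
    se <- sqrt(sum(1 / cc))
    return(tibble(effect = effect, se = se,
                  p = 2 * pnorm(-abs(effect / se)),
                  converged = FALSE, fallback = "separation"))
  }
  tibble(effect = unname(est["effect"]), se = unname(est["se"]),
         p = unname(est["p"]), converged = res$converged,
         fallback = fallback)
}

#' Expression-level component of the hurdle model
#'
#' Fits a gamma mixed-effects regression with log link to the expression
#' values of the cells in which the gene is expressed, with condition as
#' fixed effect (control baseline) and a per-sample random intercept. The
#' effect is the natural-log fold change in expression level among
#' expressing cells. Requires at least 2 expressing cells per condition,
#' otherwise the component is reported absent.
#'
#' @param y positive expression values of expressing cells only.
#' @param condition,sample aligned factors, as in [fit_induction_model()].
#' @return one-row tibble: `effect`, `se`, `p`, `converged`, `fallback`.
#' @export
fit_level_model <- function(y, condition, sample) {
  condition <- droplevels(as.factor(condition))
  sample <- as.factor(sample)
  if (any(y <= 0)) abort("level model takes positive values only")
  if (nlevels(condition) < 2 || any(table(condition) < 2)) {
    return(tibble(effect = NA_real_, se = NA_real_, p = NA_real_,
                  converged = FALSE, fallback = "insufficient_expressing"))
  }
  dat <- tibble(y = y, condition = condition, sample = sample)
  res <- glmer_quiet(lme4::glmer(
    y ~ condition + (1 | sample), data = dat,
    family = Gamma(link = "log")
  ))
  fallback <- NA_character_
  fit <- res$fit
  if (!res$converged) {
    fit <- tryCatch(
      glm(y ~ condition + sample, data = dat, family = Gamma(link = "log")),
      error = function(e) NULL
    )
    fallback <- "glm"
  }
  if (is.null(fit)) {
    return(tibble(effect = NA_real_, se = NA_real_, p = NA_real_,
                  converged = FALSE, fallback = "failed"))
  }
  est <- wald_row(fit, "^condition")
  tibble(effect = unname(est["effect"]), se = unname(est["se"]),
         p = unname(est["p"]), converged = res$converged,
         fallback = fallback)
}

#' Hurdle differential expression across conditions
#'
#' For each gene (optionally within each matched cell type), decomposes the
#' condition effect into an expression-induction component
#' ([fit_induction_model()] on the binarized counts) and an
#' expression-level component ([fit_level_model()] on depth-scaled values of
#' expressing cells), then adjusts p-values (Benjamini-Hochberg) across
#' genes within each cell type and component.
#'
#' @param counts genes x cells count matrix spanning both conditions.
#' @param meta tibble with one row per cell: `barcode`, `condition`
#'   (control level first), `sample`, and optionally `cell_type`.
#' @param genes genes to test (default: all rows).
#' @param scaled optional depth-scaled matrix for the level component;
#'   computed with [depth_scale()] when missing.
#' @return a `hurdle_effect` tibble: `gene`, `cell_type`, induction
#'   `ind_effect`/`ind_se`/`ind_p`/`ind_q`, level
#'   `lev_effect`/`lev_se`/`lev_p`/`lev_q`, cell tallies and fit flags.
#' @export
hurdle_de <- function(counts, meta, genes = NULL, scaled = NULL) {
  counts <- as_count_matrix(counts)
  stopifnot(all(c("barcode", "condition", "sample") %in% names(meta)))
  meta <- meta[match(colnames(counts), meta$barcode), ]
  if (anyNA(meta$barcode)) abort("meta must cover every column of counts")
  if (is.null(genes)) genes <- rownames(counts)
  if (is.null(scaled)) {
    # cells expressing none of the assayed genes carry no level information;
    # scale the positive-total cells and leave all-zero columns at zero
    u <- barcode_totals(counts)
    scaled <- counts
    pos <- u > 0
    scaled[, pos] <- depth_scale(counts[, pos, drop = FALSE],
                                 target = median(u[pos]))
  }
  if (!"cell_type" %in% names(meta)) meta$cell_type <- "all"
  condition <- droplevels(as.factor(meta$condition))
  control <- levels(condition)[1]

  rows <- list()
  for (ct in unique(meta$cell_type)) {
    in_ct <- meta$cell_type == ct
    cond_ct <- droplevels(condition[in_ct])
    if (nlevels(cond_ct) < 2) {
      warn(sprintf("cell type %s missing a condition; skipped", ct))
      next
    }
    cc <- counts[, in_ct, drop = FALSE]
    sc <- scaled[, in_ct, drop = FALSE]
    samp <- meta$sample[in_ct]
    for (g in genes) {
      y_bin <- as.integer(cc[g, ] > 0)
      ind <- fit_induction_model(y_bin, cond_ct, samp)
      on <- y_bin == 1
      enough <- nlevels(droplevels(cond_ct[on])) == 2 &&
        all(table(droplevels(cond_ct[on])) >= 2)
      lev <- if (enough) {
        fit_level_model(as.numeric(sc[g, on]), cond_ct[on], samp[on])
      } else {
        tibble(effect = NA_real_, se = NA_real_, p = NA_real_,
               converged = FALSE, fallback = "insufficient_expressing")
      }
      rows[[length(rows) + 1]] <- tibble(
        gene = g, cell_type = ct,
        ind_effect = ind$effect, ind_se = ind$se, ind_p = ind$p,
        ind_fallback = ind$fallback,
        lev_effect = lev$effect, lev_se = lev$se, lev_p = lev$p,
        lev_fallback = lev$fallback,
        n_control = sum(cond_ct == control),
        n_treated = sum(cond_ct != control),
        n_expressing = sum(on)
      )
    }
  }
  out <- list_rbind(rows) |>
    group_by(.data$cell_type) |>
    mutate(ind_q = bh_adjust(.data$ind_p), lev_q = bh_adjust(.data$lev_p)) |>
    ungroup()
  class(out) <- c("hurdle_effect", class(out))
  out
}

#' Multinomial test of cell-type proportion shifts
#'
#' Fits a baseline-category multinomial logit of cluster membership on
#' condition (no random effect) and reports, per non-baseline cluster, the
#' log-odds condition effect with Wald standard error, p and BH-adjusted p.
#' When a cluster is absent from one condition a 0.5 pseudo-count is added
#' to every cell of the cluster-by-condition table (Haldane continuity).
#'
#' @param clusters cluster labels per cell.
#' @param condition condition per cell (control level first).
#' @param baseline baseline cluster (default: first level).
#' @return tibble: `cluster`, `effect` (log-odds vs baseline cluster),
#'   `se`, `p`, `q`.
#' @export
test_proportions <- function(clusters, condition, baseline = NULL) {
  clusters <- as.factor(clusters)
  condition <- droplevels(as.factor(condition))
  if (nlevels(clusters) < 2) abort("need at least 2 clusters")
  if (nlevels(condition) < 2) abort("both conditions must be present")
  if (!is.null(baseline)) clusters <- stats::relevel(clusters, baseline)

  tab <- as.data.frame(table(cluster = clusters, condition = condition))
  if (any(tab$Freq == 0)) tab$Freq <- tab$Freq + 0.5

  fit <- nnet::multinom(cluster ~ condition, data = tab,
                        weights = tab$Freq, trace = FALSE)
  s <- summary(fit)
  co <- s$coefficients
  se <- s$standard.errors
  if (is.null(dim(co))) {  # two clusters: vectors
    co <- matrix(co, nrow = 1, dimnames = list(levels(clusters)[2], names(co)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(co))
  }
  j <- grep("^condition", colnames(co))[1]
  out <- tibble(
    cluster = rownames(co),
    effect = co[, j],
    se = se[, j]
  ) |>
    mutate(p = 2 * pnorm(-abs(.data$effect / .data$se)),
           q = bh_adjust(.data$p))
  out
}

#' Preranked gene-set enrichment by the weighted running sum
#'
#' Classic weighted Kolmogorov-Smirnov enrichment: genes are ordered by a
#' signed ranking statistic (by default built upstream as
#' `sign(effect) * -log10(p)`), the running sum increments by
#' `|statistic|` (normalized) on set members and decrements uniformly off
#' members, and the enrichment score is the maximum deviation from zero.
#' Significance comes from gene-label permutations: the two-sided p is the
#' fraction of permutations whose `|ES|` reaches the observed one.
#' Adjusted q-values (BH across sets) are computed per call — run one call
#' per cell type to match per-cell-type adjustment.
#'
#' @param stats named numeric vector of signed ranking statistics (names
#'   are gene ids); ties broken by name order for determinism.
#' @param gene_sets named list of character vectors.
#' @param n_perm permutations.
#' @param min_size sets with fewer ranked members are skipped.
#' @param seed integer seed.
#' @return a `gsea_result` tibble: `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (list column of gene ids).
#' @export
preranked_gsea <- function(stats, gene_sets, n_perm = 1000, min_size = 5,
                           seed = 1L) {
  if (is.null(names(stats))) abort("stats must be named by gene")
  set.seed(seed)
  ord <- order(stats, names(stats), decreasing = TRUE)
  stats <- stats[ord]
  genes <- names(stats)
  n <- length(genes)

  keep <- vapply(gene_sets, function(s) sum(genes %in% s) >= min_size,
                 logical(1))
  if (!any(keep)) abort("no gene set with enough ranked members")
  gene_sets <- gene_sets[keep]

  rows <- imap(gene_sets, function(set, name) {
    hit <- genes %in% set
    obs <- running_sum_es(stats, hit)
    nh <- sum(hit)
    perm <- vapply(seq_len(n_perm), function(i) {
      h <- rep(FALSE, n)
      h[sample.int(n, nh)] <- TRUE
      running_sum_es(stats, h)$es
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(obs$es))) / (n_perm + 1)
    tibble(
      set = name, size = nh, es = obs$es,
      nes = obs$es / mean(abs(perm)),
      p = p,
      leading_edge = list(obs$leading_edge)
    )
  }) |> list_rbind()

  rows$q <- bh_adjust(rows$p)
  out <- select(rows, "set", "size", "es", "nes", "p", "q", "leading_edge")
  class(out) <- c("gsea_result", class(out))
  out
}

# weighted KS running sum over a ranked list; hit is a logical mask
running_sum_es <- function(stats, hit) {
  w <- abs(stats[hit])
  if (sum(w) == 0) w <- rep(1, sum(hit))
  inc <- numeric(length(stats))
  inc[hit] <- w / sum(w)
  inc[!hit] <- -1 / sum(!hit)
  rs <- cumsum(inc)
  i_max <- which.max(abs(rs))
  es <- rs[i_max]
  leading <- if (es >= 0) {
    names(stats)[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    idx <- seq(i_max + 1, length(stats))
    names(stats)[idx][hit[idx]]
  }
  list(es = es, leading_edge = leading)
}

#' Build the signed GSEA ranking statistic
#'
#' The published ranking is "by the p-value of the estimated effect"; a
#' two-sided enrichment needs a sign, so the statistic used is
#' `sign(effect) * -log10(p)`.
#'
#' @param effect estimated effects.
#' @param p their p-values.
#' @param genes gene names.
#' @return named numeric vector suitable for [preranked_gsea()].
#' @export
gsea_rank_stat <- function(effect, p, genes) {
  setNames(sign(effect) * -log10(pmax(p, 1e-300)), genes)
}
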