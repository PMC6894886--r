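test_that("BH adjustment matches the hand-computed example and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(41)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(is.na(bh_adjust(c(0.5, NaN))[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("condition simulator honours its contracts", {
  expect_error(condition_sim_config(n_samples_per_condition = 1), "2 samples")
  expect_error(condition_sim_config(pi0 = 1), "pi0")
  expect_error(condition_sim_config(delta = Inf), "finite")
  # delta on the log-odds scale is recovered empirically
  cond <- simulate_condition_effects(condition_sim_config(
    n_genes = 50, n_cells_per_condition = 1000,
    sample_random_intercept_sd = 0, delta = 1.5, pi0 = 0.3, seed = 42
  ))
  frac <- function(cols) Matrix::rowMeans(cond$counts[, cols] > 0)
  trt <- cond$cells$condition == "treated"
  lo <- qlogis(frac(trt)) - qlogis(frac(!trt))
  expect_gte(mean(abs(lo - 1.5) <= 0.3), 0.9)
  # no-random-effect case: per-sample fractions exchangeable within condition
  ctrl_samples <- unique(cond$cells$sample[!trt])
  fr <- sapply(ctrl_samples, function(s)
    mean(cond$counts[1, cond$cells$sample == s] > 0))
  expect_lt(diff(range(fr)), 0.15)
})

test_that("null induction model is calibrated and p-values near-uniform", {
  cond <- simulate_condition_effects(condition_sim_config(
    n_genes = 100, n_cells_per_condition = 300,
    sample_random_intercept_sd = 0, delta = 0, beta = 0, seed = 43
  ))
  cells <- cond$cells
  p <- vapply(rownames(cond$counts), function(g) {
    fit_induction_model(as.integer(cond$counts[g, ] > 0),
                        cells$condition, cells$sample)$p
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.1)
  # KS against uniform: Wald p on discrete data is only asymptotically
  # uniform, so test at the 1% level
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("induction effect is recovered and degenerate outcomes flagged", {
  cond <- simulate_condition_effects(condition_sim_config(
    n_genes = 25, n_cells_per_condition = 1000,
    sample_random_intercept_sd = 0, delta = 1.5, pi0 = 0.3, seed = 44
  ))
  est <- vapply(rownames(cond$counts), function(g) {
    fit_induction_model(as.integer(cond$counts[g, ] > 0),
                        cond$cells$condition, cond$cells$sample)$effect
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.5), 0.3)
  # all-expressed outcome is degenerate
  r <- fit_induction_model(rep(1L, 40), rep(c("control", "treated"), 20),
                           rep(c("s1", "s2", "s3", "s4"), 10))
  expect_equal(r$fallback, "degenerate")
  expect_error(fit_induction_model(rep(0:1, 20), rep("control", 40),
                                   rep(c("s1", "s2"), 20)), "both conditions")
})

test_that("level model recovers beta and reports absence honestly", {
  cond <- simulate_condition_effects(condition_sim_config(
    n_genes = 25, n_cells_per_condition = 800,
    sample_random_intercept_sd = 0, beta = 0.7, pi0 = 0.8, seed = 45
  ))
  est <- vapply(rownames(cond$counts), function(g) {
    on <- as.numeric(cond$counts[g, ]) > 0
    fit_level_model(as.numeric(cond$counts[g, on]),
                    cond$cells$condition[on], cond$cells$sample[on])$effect
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.7), 0.15)
  # one expressing cell in a condition: absent with reason
  r <- fit_level_model(c(2.5, 3, 4, 1.2),
                       c("treated", "control", "control", "control"),
                       c("s1", "s2", "s3", "s4"))
  expect_equal(r$fallback, "insufficient_expressing")
  expect_true(is.na(r$effect))
  expect_error(fit_level_model(c(-1, 2), c("a", "b"), c("s1", "s2")),
               "positive")
})

test_that("hurdle components decouple and mixed matches fixed at sd = 0", {
  cond <- simulate_condition_effects(condition_sim_config(
    n_genes = 30, n_cells_per_condition = 800,
    sample_random_intercept_sd = 0,
    delta = 1.2, beta = 0, pi0 = 0.4, seed = 46
  ))
  de <- hurdle_de(cond$counts, cond$cells, scaled = cond$counts)
  # induction planted, level centered at zero
  expect_gt(mean(de$ind_effect), 0.9)
  expect_lt(abs(mean(de$lev_effect, na.rm = TRUE)), 0.1)
  # mixed-model estimate agrees with a plain fixed-effect GLM
  g <- rownames(cond$counts)[1]
  y <- as.integer(cond$counts[g, ] > 0)
  mixed <- fit_induction_model(y, cond$cells$condition, cond$cells$sample)
  fixed <- glm(y ~ condition, family = binomial(),
               data = data.frame(y = y, condition = cond$cells$condition))
  expect_lt(abs(mixed$effect - unname(coef(fixed)[2])), 0.05)
})

test_that("hurdle table adjusts within cell type and flags missing ones", {
  cond <- simulate_condition_effects(condition_sim_config(
    n_genes = 10, n_cells_per_condition = 200,
    delta = 0, beta = 0, seed = 47
  ))
  meta <- cond$cells
  meta$cell_type <- rep(c("T", "B"), length.out = nrow(meta))
  de <- hurdle_de(cond$counts, meta, scaled = cond$counts)
  expect_setequal(unique(de$cell_type), c("T", "B"))
  expect_true(all(de$ind_q >= de$ind_p, na.rm = TRUE))
  # a cell type present in only one condition is skipped with a warning
  meta2 <- meta
  meta2$cell_type[meta2$condition == "treated"] <- "T"
  expect_warning(hurdle_de(cond$counts, meta2, genes = rownames(cond$counts)[1],
                           scaled = cond$counts), "missing a condition")
})

test_that("proportion test equals the closed-form 2x2 log odds ratio", {
  clusters <- rep(rep(c("c1", "c2"), 2), c(260, 740, 180, 820))
  condition <- rep(c("control", "treated"), c(1000, 1000))
  res <- test_proportions(clusters, condition, baseline = "c2")
  expect_equal(res$cluster, "c1")
  expect_equal(res$effect, log((180 / 820) / (260 / 740)), tolerance = 0.01)
  # equal proportions: effect ~ 0, p ~ 1
  eq <- test_proportions(rep(c("c1", "c2", "c1", "c2"), c(300, 300, 300, 300)),
                         rep(c("control", "treated"), c(600, 600)))
  expect_lt(max(abs(eq$effect)), 1e-4)
  expect_gt(min(eq$p), 0.95)
})

test_that("a strong planted proportion shift is overwhelming", {
  set.seed(48)
  n <- 2000
  ctrl <- sample(c("target", "rest"), n, TRUE, prob = c(0.05, 0.95))
  trt <- sample(c("target", "rest"), n, TRUE, prob = c(0.25, 0.75))
  res <- test_proportions(c(ctrl, trt),
                          rep(c("control", "treated"), each = n),
                          baseline = "rest")
  expect_lt(res$q[res$cluster == "target"], 1e-10)
  # absent-in-one-condition cluster is handled by continuity correction
  res2 <- test_proportions(
    rep(c("a", "b", "a"), c(500, 30, 530)),
    rep(c("control", "treated"), c(530, 530))
  )
  expect_true(all(is.finite(res2$effect)))
})

test_that("running-sum ES matches a direct loop and fgsea on a toy list", {
  set.seed(49)
  stats <- setNames(rnorm(20, sd = 2), paste0("g", 1:20))
  set <- paste0("g", sample(20, 6))
  ours <- preranked_gsea(stats, list(s = set), n_perm = 200, min_size = 5,
                         seed = 1)
  expect_equal(ours$es, direct_es(stats, set), tolerance = 1e-12)
  skip_if_not_installed("fgsea")
  fg <- suppressWarnings(fgsea::fgsea(list(s = set), stats,
                                      nPermSimple = 200))
  expect_equal(ours$es, fg$ES, tolerance = 1e-9)
})

test_that("extreme and null gene sets behave as expected", {
  set.seed(50)
  stats <- setNames(sort(rnorm(100), decreasing = TRUE), paste0("g", 1:100))
  top <- names(stats)[1:10]
  res <- preranked_gsea(stats, list(top = top), n_perm = 500, seed = 2)
  expect_gt(res$es, 0)
  expect_lte(res$p, 1 / 501 * 1.01)
  expect_true(all(res$leading_edge[[1]] %in% top))
  # sets below min_size are skipped; all-small errors
  expect_error(preranked_gsea(stats, list(tiny = names(stats)[1:2])),
               "enough ranked members")
  # null sets: permutation p approximately uniform
  set.seed(51)
  ps <- vapply(1:60, function(i) {
    s <- sample(names(stats), 10)
    preranked_gsea(stats, list(s = s), n_perm = 200, seed = i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the signed ranking statistic encodes direction and strength", {
  rs <- gsea_rank_stat(c(2, -1), c(0.01, 0.001), c("a", "b"))
  expect_equal(unname(rs), c(2, -3))
  expect_gt(rs["a"], 0)
  expect_lt(rs["b"], 0)
})
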