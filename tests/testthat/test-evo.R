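test_that("noiseless homology tables yield the planted ortholog map", {
  ht <- simulate_homology_tables(identity_noise = 0, seed = 71)
  rbh <- reciprocal_best_hits(ht$hits_ab, ht$hits_ba)
  truth <- dplyr::arrange(
    dplyr::select(ht$truth$orthologs, gene_a, gene_b), gene_a
  )
  expect_equal(dplyr::arrange(rbh, gene_a), truth)
  # symmetry: swapping the two tables gives the same unordered pairs
  rev <- reciprocal_best_hits(ht$hits_ba, ht$hits_ab)
  expect_setequal(paste(rbh$gene_a, rbh$gene_b),
                  paste(rev$gene_b, rev$gene_a))
  # empty input gives an empty result
  empty <- ht$hits_ab[0, ]
  expect_equal(nrow(reciprocal_best_hits(empty, empty)), 0)
})

test_that("identity and e-value thresholds are strict at the boundary", {
  hit <- tibble::tibble(
    qseqid = "a-T1", sseqid = "b-T1", pident = 80, length = 100L,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L, sstart = 1L,
    send = 100L, evalue = 1e-5, bitscore = 200
  )
  back <- dplyr::mutate(hit, qseqid = "b-T1", sseqid = "a-T1")
  expect_equal(nrow(reciprocal_best_hits(hit, back)), 0)  # 80 not > 80
  hit$pident <- 80.1
  back$pident <- 80.1
  expect_equal(nrow(reciprocal_best_hits(hit, back)), 1)
  hit$evalue <- 0.1
  expect_equal(nrow(reciprocal_best_hits(hit, back)), 0)  # 0.1 not < 0.1
})

test_that("annotated pseudogenes join the family of their best hit", {
  og <- tibble::tibble(gene_id = c("klra1", "klrb1"),
                       family = c("KLRA", "KLRB"))
  hits <- tibble::tibble(
    qseqid = c("psi1-T1", "psi1-T1", "psi2-T1"),
    sseqid = c("klra1-T1", "klrb1-T1", "klra1-T1"),
    pident = c(92, 85, 75), evalue = c(1e-20, 1e-10, 1e-30),
    bitscore = c(500, 300, 100)
  )
  aug <- augment_orthogroups(og, hits)
  expect_equal(aug$family[aug$gene_id == "psi1"], "KLRA")
  # psi2 fails the identity threshold entirely
  expect_false("psi2" %in% aug$gene_id)
})

test_that("pseudogene pipeline merges, confirms, restricts and ignores", {
  ann <- tibble::tibble(
    species = "sp", gene_id = "klra1", symbol = "Klra1", family = "KLRA",
    biotype = "protein_coding", scaffold = "NKC", start = 10000L,
    end = 12000L
  )
  hits <- tibble::tibble(
    qseqid = c("q1", "q2", "q3", "q4", "q5"),
    q_family = "KLRA",
    species = "sp",
    scaffold = c("NKC", "NKC", "NKC", "elsewhere", "NKC"),
    start = c(100L, 300L, 10500L, 100L, 5000L),
    end = c(400L, 600L, 11000L, 400L, 5300L),
    pident = c(55, 50, 70, 55, 30),
    dom_evalue = c(1e-5, 1e-6, 1e-9, 1e-5, 1e-5),
    dom_pident = c(70, 72, 80, 70, 70)
  )
  psi <- detect_putative_pseudogenes(hits, ann)
  # q1+q2 merge to [100, 600]; q3 overlaps the annotated gene; q4 is off
  # locus; q5 fails the 40% identity stage
  expect_equal(nrow(psi), 1)
  expect_equal(psi$start, 100L)
  expect_equal(psi$end, 600L)
  expect_equal(psi$biotype, "putative_pseudogene")
  # domain failure removes the call
  weak <- dplyr::mutate(hits, dom_pident = 50)
  expect_equal(nrow(detect_putative_pseudogenes(weak, ann)), 0)
  # missing coordinates are a parse error
  broken <- hits
  broken$start[1] <- NA
  expect_error(detect_putative_pseudogenes(broken, ann), "coordinates")
})

test_that("merging is idempotent", {
  hits <- tibble::tibble(
    qseqid = c("q1", "q2"), q_family = "KLRA", species = "sp",
    scaffold = "NKC", start = c(100L, 300L), end = c(400L, 600L),
    pident = c(55, 50), dom_evalue = c(1e-5, 1e-6), dom_pident = c(70, 72)
  )
  m1 <- crossimmune:::merge_family_hits(hits)
  m2 <- crossimmune:::merge_family_hits(
    dplyr::mutate(m1, qseqid = "merged", q_family = family)
  )
  expect_equal(m2$start, m1$start)
  expect_equal(m2$end, m1$end)
  expect_equal(nrow(m2), nrow(m1))
})

test_that("false-positive benchmark recovers the realized confusion", {
  ht <- simulate_homology_tables(
    genes_per_family = 150, annotated_pseudo_per_family = 0,
    pseudogene_fraction = 0, confusion = c(LILR = 0.2, KIR = 0.2),
    seed = 72
  )
  bm <- benchmark_false_positives(ht$genomic_hits, ht$annotations)
  truth <- ht$truth$confusion_realized |>
    dplyr::mutate(frac = n_confused / n_hits)
  m <- dplyr::inner_join(bm, truth, by = c("family", "species"))
  expect_true(all(abs(m$fp_fraction - m$frac) <= 0.02))
  # pure families report zero and are unflagged
  clean <- dplyr::filter(m, !family %in% c("LILR", "KIR"))
  expect_true(all(clean$fp_fraction == 0))
  expect_false(any(clean$flagged))
  # the confounded pair is flagged at its 20% planted confusion
  conf <- dplyr::filter(m, family %in% c("LILR", "KIR"))
  expect_true(all(conf$flagged))
})

test_that("phyletic pattern counts biotypes and zeroes excluded families", {
  ht <- simulate_homology_tables(seed = 73)
  psi <- detect_putative_pseudogenes(ht$genomic_hits, ht$annotations)
  all_ann <- dplyr::bind_rows(ht$annotations, psi)
  pat <- compile_phyletic_pattern(all_ann)
  expect_true(all(pat$total == pat$protein_coding +
                    pat$annotated_pseudogene + pat$putative_pseudogene))
  expect_true(all(pat$putative_pseudogene[pat$family %in%
                                            c("LILR", "KIR")] == 0))
  # direct count check for one cell
  klra <- dplyr::filter(pat, species == "mouse", family == "KLRA")
  expect_equal(klra$protein_coding,
               nrow(dplyr::filter(ht$annotations, species == "mouse",
                                  family == "KLRA",
                                  biotype == "protein_coding")))
  # empty annotation set gives explicit zeros
  empty <- compile_phyletic_pattern(ht$annotations[0, ],
                                    species = "mouse", families = "KLRA")
  expect_equal(empty$total, 0L)
  # CSV round trip conserves totals
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(pat, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$total, pat$total)
})

test_that("constant tip counts reconstruct with certainty", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  anc <- sankoff_ancestral(tree, c(A = 2, B = 2, C = 2, D = 2))
  expect_equal(anc$min_cost, 0)
  expect_true(all(anc$map$map_state == 2))
  expect_true(all(anc$map$probability == 1))
})

test_that("the balanced 0/0/3/3 quartet has four co-optimal root states", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  anc <- sankoff_ancestral(tree, c(A = 0, B = 0, C = 3, D = 3))
  expect_equal(anc$min_cost, 3)
  root <- dplyr::filter(anc$states, node == 5)
  expect_setequal(root$state[root$optimal], 0:3)
  expect_equal(root$probability[root$optimal], rep(0.25, 4))
})

test_that("single-edge path metric and size guards hold in brute force", {
  tree <- ape::read.tree(text = "(A,B);")
  bf <- brute_force_parsimony(tree, c(A = 3, B = 1))
  expect_equal(bf$min_cost, 2)
  const <- brute_force_parsimony(tree, c(A = 2, B = 2))
  expect_equal(const$min_cost, 0)
  big <- ape::rtree(12)
  expect_error(
    brute_force_parsimony(big, setNames(rep(7L, 12), big$tip.label),
                          s_max = 7),
    "too large"
  )
})

test_that("Sankoff DP agrees with exhaustive enumeration on random trees", {
  set.seed(74)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    tree <- ape::rtree(n)
    counts <- setNames(sample(0:4, n, replace = TRUE), tree$tip.label)
    anc <- sankoff_ancestral(tree, counts, s_max = 4)
    bf <- brute_force_parsimony(tree, counts, s_max = 4)
    expect_equal(anc$min_cost, bf$min_cost)
    # per-node, per-state optimality flags agree with the enumeration
    for (v in colnames(bf$assignments)) {
      opt_states <- sort(unique(bf$assignments[, v]))
      ours <- dplyr::filter(anc$states, node == as.integer(v), optimal)
      expect_equal(sort(ours$state), opt_states)
      # probabilities equal enumeration marginals
      marg <- table(factor(bf$assignments[, v], levels = 0:4)) /
        nrow(bf$assignments)
      full <- dplyr::filter(anc$states, node == as.integer(v))
      expect_equal(full$probability, as.numeric(marg), tolerance = 1e-12)
    }
  }
})

test_that("minimum cost is invariant to re-rooting", {
  set.seed(75)
  for (i in 1:20) {
    tree <- ape::rtree(6)
    counts <- setNames(sample(0:4, 6, replace = TRUE), tree$tip.label)
    c1 <- sankoff_ancestral(tree, counts, s_max = 4)$min_cost
    tree2 <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[1],
                       resolve.root = TRUE)
    c2 <- sankoff_ancestral(tree2, counts, s_max = 4)$min_cost
    expect_equal(c1, c2)
  }
})

test_that("simulated gene-count histories are labelled and reproducible", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  frozen <- simulate_gene_count_history(tree, 0, 0, 5, seed = 1)
  expect_true(all(frozen$node_counts$count == 5))
  h1 <- simulate_gene_count_history(tree, 0.5, 0.5, 2, seed = 7)
  h2 <- simulate_gene_count_history(tree, 0.5, 0.5, 2, seed = 7)
  expect_identical(h1$tip_counts, h2$tip_counts)
  expect_false(anyNA(h1$node_counts$count))
  expect_error(simulate_gene_count_history(tree, -1, 0, 2), "non-negative")
})

test_that("low-rate histories are recovered by parsimony at most nodes", {
  set.seed(76)
  tree <- ape::rtree(6)
  tree$edge.length <- rep(1, nrow(tree$edge))
  hit <- 0; tot <- 0
  for (r in 1:60) {
    h <- simulate_gene_count_history(tree, 0.08, 0.08, 2, seed = r)
    if (max(h$tip_counts) == min(h$tip_counts)) next
    anc <- sankoff_ancestral(tree, h$tip_counts,
                             s_max = max(h$tip_counts, 2))
    truth <- h$node_counts$count[anc$map$node]
    hit <- hit + sum(anc$map$map_state == truth)
    tot <- tot + nrow(anc$map)
  }
  expect_gte(hit / tot, 0.8)
})

test_that("Newick and BLAST tabular round trips work", {
  tree <- ape::rtree(8)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, f)
  back <- ape::read.tree(f)
  expect_equal(back$tip.label, tree$tip.label)
  ht <- simulate_homology_tables(seed = 77)
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ht$hits_ab, tf, col_names = FALSE)
  hits <- read_blast_tab(tf)
  expect_equal(nrow(hits), nrow(ht$hits_ab))
  expect_equal(hits$pident, ht$hits_ab$pident)
})
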