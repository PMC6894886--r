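#' Simulate gene-count evolution along a phylogeny
#'
#' Evolves a gene-family size along a rooted tree by a birth-death jump
#' process: on a branch of length `t`, gains (count `n -> n + 1`) arrive at
#' rate `gain_rate` and losses (`n -> n - 1`, only while `n > 0`) at rate
#' `loss_rate`, simulated event by event. Every node — tips and ancestors —
#' is labelled with its true count, providing ground truth for parsimony
#' reconstruction.
#'
#' @param tree an [ape::phylo] rooted tree with positive branch lengths.
#' @param gain_rate,loss_rate non-negative event rates per unit branch
#'   length.
#' @param root_count non-negative integer count at the root.
#' @param seed integer seed.
#' @return list with `tip_counts` (named integer vector over tip labels) and
#'   `node_counts` (tibble `node`, `count` over all nodes in `tree`'s
#'   internal numbering).
#' @export
simulate_gene_count_history <- function(tree, gain_rate, loss_rate,
                                        root_count, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (gain_rate < 0 || loss_rate < 0) {
    abort("invalid config: rates must be non-negative")
  }
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    abort("invalid config: tree must have positive branch lengths")
  }
  set.seed(seed)

  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_nodes <- n_tip + tree$Nnode
  count <- rep(NA_integer_, n_nodes)
  count[root] <- as.integer(root_count)

  evolve_branch <- function(n, len) {
    t <- 0
    repeat {
      rate <- gain_rate + if (n > 0) loss_rate else 0
      if (rate <= 0) return(n)
      t <- t + stats::rexp(1, rate)
      if (t > len) return(n)
      if (runif(1) < gain_rate / rate) n <- n + 1L else n <- n - 1L
    }
  }

  # parents precede children in a preorder over edges
  ord <- order(tree$edge[, 1])
  edges <- tree$edge[ord, , drop = FALSE]
  lens <- tree$edge.length[ord]
  for (i in seq_len(nrow(edges))) {
    parent <- edges[i, 1]; child <- edges[i, 2]
    count[child] <- evolve_branch(count[parent], lens[i])
  }

  list(
    tip_counts = setNames(count[seq_len(n_tip)], tree$tip.label),
    node_counts = tibble(node = seq_len(n_nodes), count = count)
  )
}

#' Simulate homology hit tables, annotations and planted pseudogenes
#'
#' Builds a two-species toy comparative-genomics dataset in the shapes the
#' orthology and pseudogene-discovery pipeline consumes: 12-column BLAST
#' tabular hit tables in both directions between transcript forms, a gene
#' annotation table (species, family, biotype, scaffold, coordinates), a
#' table of genomic homology hits with per-hit domain confirmation, and the
#' planted truth. True orthologs are reciprocal best hits by construction;
#' decayed (unannotated) family copies are planted as intergenic intervals
#' with identities in the 45-60% band; a configurable fraction of
#' genomic hits lands on annotated genes of a *different* family to emulate
#' domain-sharing confusion (as between the immunoglobulin-domain families).
#'
#' @param species character vector of two species names.
#' @param families named list: family name -> locus name (`"LRC"`, `"NKC"`
#'   or `"MHC"`); scaffolds are `<species>_<locus>`.
#' @param genes_per_family protein-coding genes per family per species.
#' @param annotated_pseudo_per_family annotated pseudogenes per family per
#'   species.
#' @param pseudogene_fraction decayed unannotated copies planted per family
#'   per species, as a fraction of `genes_per_family`.
#' @param confusion named numeric: family -> fraction of its genomic hits
#'   that land on annotated genes of the partner family listed in
#'   `confusion_partner`.
#' @param confusion_partner named character: family -> confounding family.
#' @param identity_noise sd of Gaussian noise added to hit identities.
#' @param seed integer seed.
#' @return list with `hits_ab`, `hits_ba` (BLAST tabular tibbles),
#'   `annotations` (gene records), `genomic_hits` (intervals with `q_family`,
#'   `dom_evalue`, `dom_pident`), and `truth` (`orthologs`, `pseudogenes`).
#' @export
simulate_homology_tables <- function(species = c("mouse", "nakedmolerat"),
                                     families = list(
                                       KLRA = "NKC", KLRB = "NKC",
                                       KLRD = "NKC", `MHC-I` = "MHC",
                                       LILR = "LRC", KIR = "LRC"
                                     ),
                                     genes_per_family = 4,
                                     annotated_pseudo_per_family = 1,
                                     pseudogene_fraction = 0.5,
                                     confusion = c(LILR = 0.3, KIR = 0.3),
                                     confusion_partner = c(LILR = "KIR",
                                                           KIR = "LILR"),
                                     identity_noise = 0,
                                     seed = 1L) {
  stopifnot(length(species) == 2, length(families) >= 1)
  set.seed(seed)
  fam_names <- names(families)

  jitter_id <- function(x) {
    pmin(100, pmax(0, x + rnorm(length(x), 0, identity_noise)))
  }

  # --- annotated gene records -------------------------------------------
  gene_len <- 2000L
  spacing <- 10000L
  n_tot <- genes_per_family + annotated_pseudo_per_family
  n_decayed <- round(pseudogene_fraction * genes_per_family)
  # block large enough that annotated genes and planted decayed copies of
  # one family never reach the next family's coordinates
  block <- spacing * (n_tot + n_decayed + 10L)
  ann <- list()
  for (sp in species) {
    for (f in fam_names) {
      n_p <- genes_per_family
      n_psi <- annotated_pseudo_per_family
      starts <- spacing * (seq_len(n_tot) - 1L) +
        block * (match(f, fam_names) - 1L) + 1L
      ann[[paste(sp, f)]] <- tibble(
        species = sp,
        gene_id = sprintf("%s_%s_g%02d", sp, f, seq_len(n_tot)),
        symbol = sprintf("%s%d", gsub("-", "", f), seq_len(n_tot)),
        family = f,
        biotype = c(rep("protein_coding", n_p),
                    rep("annotated_pseudogene", n_psi)),
        scaffold = paste0(sp, "_", families[[f]]),
        start = starts,
        end = starts + gene_len - 1L
      )
    }
  }
  annotations <- list_rbind(ann)

  # --- pairwise transcript hits (two forms per protein-coding gene) -----
  coding <- filter(annotations, .data$biotype == "protein_coding")
  a_genes <- filter(coding, .data$species == species[1])
  b_genes <- filter(coding, .data$species == species[2])
  hit_rows <- list()
  orth_pairs <- list()
  for (f in fam_names) {
    qa <- filter(a_genes, .data$family == f)
    qb <- filter(b_genes, .data$family == f)
    n <- min(nrow(qa), nrow(qb))
    grid <- tidyr::expand_grid(i = seq_len(nrow(qa)), j = seq_len(nrow(qb)))
    is_orth <- grid$i == grid$j & grid$i <= n
    hit_rows[[f]] <- tibble(
      qseqid = paste0(qa$gene_id[grid$i], "-T1"),
      sseqid = paste0(qb$gene_id[grid$j], "-T1"),
      pident = jitter_id(ifelse(is_orth, 92, 83)),
      length = gene_len, mismatch = 50L, gapopen = 2L,
      qstart = 1L, qend = gene_len, sstart = 1L, send = gene_len,
      evalue = ifelse(is_orth, 1e-80, 1e-30),
      bitscore = ifelse(is_orth, 900, 400)
    )
    orth_pairs[[f]] <- tibble(
      gene_a = qa$gene_id[grid$i[is_orth]],
      gene_b = qb$gene_id[grid$j[is_orth]],
      family = f
    )
  }
  ab <- list_rbind(hit_rows)
  # reverse direction: swap query/subject
  ba <- mutate(ab,
    tmp = .data$qseqid, qseqid = .data$sseqid, sseqid = .data$tmp
  ) |> select(-"tmp")

  # --- genomic (EST-vs-genome style) hits -------------------------------
  gh <- list()
  add_gh <- function(qseqid, q_family, sp, scaffold, start, end, pident,
                     dom_evalue, dom_pident, covers = NA_character_) {
    gh[[length(gh) + 1]] <<- tibble(
      qseqid = qseqid, q_family = q_family, species = sp,
      scaffold = scaffold, start = as.integer(start), end = as.integer(end),
      pident = jitter_id(pident), dom_evalue = dom_evalue,
      dom_pident = jitter_id(dom_pident), covers = covers
    )
  }

  pseudo_truth <- list()
  confusion_realized <- list()
  for (sp in species) {
    sp_ann <- filter(annotations, .data$species == sp)
    for (f in fam_names) {
      fam_ann <- filter(sp_ann, .data$family == f)
      scaf <- fam_ann$scaffold[1]
      query <- sprintf("%s_%s_g01-T1",
                       setdiff(species, sp)[1], f)
      # self hits over annotated genes (true-family, for benchmarking)
      conf_frac <- if (f %in% names(confusion)) confusion[[f]] else 0
      partner <- if (f %in% names(confusion_partner))
        confusion_partner[[f]] else NA_character_
      p_ann <- if (is.na(partner)) fam_ann[0, ] else
        filter(sp_ann, .data$family == partner)
      confuse <- !is.na(partner) & runif(nrow(fam_ann)) < conf_frac
      # cap at the number of distinct partner genes so confused hits never
      # merge with one another (keeps the planted FP fraction exact)
      if (sum(confuse) > nrow(p_ann)) {
        confuse[confuse][seq_len(sum(confuse) - nrow(p_ann))] <- FALSE
      }
      conf_targets <- if (any(confuse))
        sample.int(nrow(p_ann), sum(confuse)) else integer(0)
      n_confused <- sum(confuse)
      ci <- 0L
      for (i in seq_len(nrow(fam_ann))) {
        target <- if (confuse[i]) {
          ci <- ci + 1L
          p_ann[conf_targets[ci], ]
        } else fam_ann[i, ]
        add_gh(query, f, sp, target$scaffold[1], target$start[1],
               target$end[1], 70, 1e-10, 75, covers = target$gene_id[1])
      }
      confusion_realized[[length(confusion_realized) + 1]] <- tibble(
        species = sp, family = f, n_hits = nrow(fam_ann),
        n_confused = n_confused
      )
      # decayed, unannotated copies: intergenic intervals
      if (n_decayed > 0) {
        base <- max(fam_ann$end) + spacing
        for (d in seq_len(n_decayed)) {
          s0 <- base + (d - 1L) * spacing
          add_gh(query, f, sp, scaf, s0, s0 + 1200L, 52, 1e-6, 72)
          pseudo_truth[[length(pseudo_truth) + 1]] <- tibble(
            species = sp, family = f, scaffold = scaf,
            start = as.integer(s0), end = as.integer(s0 + 1200L)
          )
        }
      }
    }
  }

  list(
    hits_ab = ab,
    hits_ba = ba,
    annotations = annotations,
    genomic_hits = list_rbind(gh),
    truth = list(
      orthologs = list_rbind(orth_pairs),
      pseudogenes = if (length(pseudo_truth)) list_rbind(pseudo_truth) else
        tibble(species = character(), family = character(),
               scaffold = character(), start = integer(), end = integer()),
      confusion = confusion,
      confusion_realized = list_rbind(confusion_realized)
    )
  )
}
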