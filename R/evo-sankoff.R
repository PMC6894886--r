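#' Sankoff maximum-parsimony ancestral gene counts
#'
#' Reconstructs ancestral gene-family sizes on a rooted phylogeny by the
#' Sankoff dynamic program with the linear cost `c(i, j) = |i - j|`
#' (cost proportional to the change in gene number; the proportionality
#' constant does not affect the optimum). States run over `0..s_max`.
#'
#' Per internal node, each state's probability is the fraction of globally
#' minimum-cost full assignments in which the node takes that state,
#' computed exactly by an inside-outside (up-down) pass over optimal-
#' assignment counts; `prob_method = "states"` instead spreads probability
#' uniformly over the node's co-optimal states. The MAP state is the most
#' probable one and always attains the global minimum cost.
#'
#' @param tree an [ape::phylo] tree; if unrooted it is rooted at `outgroup`
#'   when given, else midpoint-rooted, with a warning. Branch lengths are
#'   ignored (parsimony).
#' @param tip_counts named integer vector of gene counts covering every tip
#'   label.
#' @param s_max largest state considered; defaults to the maximum tip count.
#' @param outgroup optional tip label used to root an unrooted tree.
#' @param prob_method `"assignments"` (default) or `"states"`.
#' @return an `ancestral_states` list:
#'   * `min_cost`: the global minimum total cost;
#'   * `states`: tibble `node`, `state`, `cost` (minimal subtree+outside
#'     cost when the node takes the state), `optimal`, `probability`;
#'   * `map`: tibble `node`, `map_state`, `probability` per internal node;
#'   * `tree`: the (possibly re-rooted) tree.
#' @export
sankoff_ancestral <- function(tree, tip_counts, s_max = NULL,
                              outgroup = NULL,
                              prob_method = c("assignments", "states")) {
  prob_method <- match.arg(prob_method)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    if (!is.null(outgroup)) {
      warn("unrooted tree: rooting at the supplied outgroup")
      tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    } else {
      warn("unrooted tree: midpoint rooting")
      tree <- phytools::midpoint.root(tree)
    }
  }
  missing <- setdiff(tree$tip.label, names(tip_counts))
  if (length(missing)) {
    abort(paste("tips without counts:", paste(missing, collapse = ", ")))
  }
  counts <- tip_counts[tree$tip.label]
  if (is.null(s_max)) s_max <- max(counts)
  if (any(counts > s_max)) abort("a tip count exceeds s_max")
  states <- 0:s_max
  n_state <- length(states)
  cost_mat <- abs(outer(states, states, "-"))

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])

  # inside pass: subtree cost C and optimal-assignment counts N
  C <- matrix(Inf, n_node, n_state)
  N <- matrix(0, n_node, n_state)
  C[cbind(seq_len(n_tip), counts + 1L)] <- 0
  N[cbind(seq_len(n_tip), counts + 1L)] <- 1

  # postorder over internal nodes: deepest first
  depth <- node_depths(tree)
  internal <- order(depth[(n_tip + 1):n_node], decreasing = TRUE) + n_tip
  for (v in internal) {
    Cv <- rep(0, n_state)
    Nv <- rep(1, n_state)
    for (ch in children[[as.character(v)]]) {
      trans <- sweep(cost_mat, 2, C[ch, ], "+")     # [s, t]
      m <- apply(trans, 1, min)
      cnt <- vapply(seq_len(n_state), function(s) {
        sum(N[ch, trans[s, ] == m[s]])
      }, numeric(1))
      Cv <- Cv + m
      Nv <- Nv * cnt
    }
    C[v, ] <- Cv
    N[v, ] <- Nv
  }
  min_cost <- min(C[root, ])

  # outside pass: cost O and counts K of everything outside the subtree
  O <- matrix(Inf, n_node, n_state)
  K <- matrix(0, n_node, n_state)
  O[root, ] <- 0
  K[root, ] <- 1
  preorder <- internal[rev(seq_along(internal))]
  for (v in preorder) {
    kids <- children[[as.character(v)]]
    # sibling contributions: M_w(s) = min_t (|s-t| + C_w(t)), counts likewise
    M <- lapply(kids, function(w) {
      trans <- sweep(cost_mat, 2, C[w, ], "+")
      m <- apply(trans, 1, min)
      cnt <- vapply(seq_len(n_state), function(s) {
        sum(N[w, trans[s, ] == m[s]])
      }, numeric(1))
      list(min = m, cnt = cnt)
    })
    for (ci in seq_along(kids)) {
      ch <- kids[ci]
      sib_min <- rep(0, n_state)
      sib_cnt <- rep(1, n_state)
      for (wi in seq_along(kids)) {
        if (wi == ci) next
        sib_min <- sib_min + M[[wi]]$min
        sib_cnt <- sib_cnt * M[[wi]]$cnt
      }
      base_cost <- O[v, ] + sib_min        # [s]
      base_cnt <- K[v, ] * sib_cnt
      tot <- sweep(cost_mat, 1, base_cost, "+")   # [s, t]
      O[ch, ] <- apply(tot, 2, min)
      K[ch, ] <- vapply(seq_len(n_state), function(t) {
        sum(base_cnt[tot[, t] == O[ch, t]])
      }, numeric(1))
    }
  }

  full_cost <- C + O
  opt <- abs(full_cost - min_cost) < 1e-9
  prob <- matrix(0, n_node, n_state)
  if (prob_method == "assignments") {
    w <- N * K * opt
    prob <- w / pmax(rowSums(w), .Machine$double.xmin)
  } else {
    prob <- opt / rowSums(opt)
  }

  states_tbl <- tibble(
    node = rep(seq_len(n_node), each = n_state),
    state = rep(states, n_node),
    cost = as.vector(t(full_cost)),
    optimal = as.vector(t(opt)),
    probability = as.vector(t(prob))
  )
  internal_nodes <- (n_tip + 1):n_node
  map_tbl <- states_tbl |>
    filter(.data$node %in% internal_nodes) |>
    group_by(.data$node) |>
    arrange(dplyr::desc(.data$probability), .data$state, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("node", map_state = "state", "probability")

  structure(list(min_cost = min_cost, states = states_tbl,
                 map = map_tbl, tree = tree),
            class = "ancestral_states")
}

node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  depth <- rep(NA_integer_, n_node)
  depth[n_tip + 1L] <- 0L
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  repeat {
    todo <- is.na(depth[edges[, 2]])
    ready <- todo & !is.na(depth[edges[, 1]])
    if (!any(ready)) break
    depth[edges[ready, 2]] <- depth[edges[ready, 1]] + 1L
  }
  depth
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("<ancestral_states> min cost:", x$min_cost, "\n")
  print(x$map)
  invisible(x)
}

#' @export
tidy.ancestral_states <- function(x, ...) x$states

#' @export
glance.ancestral_states <- function(x, ...) {
  tibble(min_cost = x$min_cost,
         n_internal = nrow(x$map),
         n_ambiguous = sum(x$map$probability < 1))
}

#' Exhaustive parsimony oracle
#'
#' Enumerates every assignment of states `0..s_max` to the internal nodes
#' and returns the exact minimum total cost under `c(i, j) = |i - j|` along
#' with all optimal assignments. A deliberate size guard refuses more than
#' 8 internal nodes or `s_max > 6`.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param tip_counts named counts per tip.
#' @param s_max largest state (default: max tip count).
#' @return list: `min_cost`, `assignments` (matrix, one row per optimal
#'   assignment, columns named by internal node number).
#' @export
brute_force_parsimony <- function(tree, tip_counts, s_max = NULL) {
  stopifnot(inherits(tree, "phylo"))
  counts <- tip_counts[tree$tip.label]
  if (anyNA(counts)) abort("tips without counts")
  if (is.null(s_max)) s_max <- max(counts)
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  if (n_int > 8 || s_max > 6) abort("instance too large for brute force")

  grid <- as.matrix(expand.grid(rep(list(0:s_max), n_int)))
  colnames(grid) <- as.character((n_tip + 1):(n_tip + n_int))
  state_of <- function(node) {
    ifelse(node <= n_tip, counts[node], NA)
  }
  total <- rep(0, nrow(grid))
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    sp <- grid[, as.character(p)]
    sc <- if (ch <= n_tip) rep(counts[ch], nrow(grid)) else
      grid[, as.character(ch)]
    total <- total + abs(sp - sc)
  }
  min_cost <- min(total)
  list(min_cost = min_cost,
       assignments = grid[total == min_cost, , drop = FALSE])
}
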