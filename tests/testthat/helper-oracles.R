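# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# brute-force SNN: Jaccard of k-NN sets (self included) from raw coordinates
brute_snn <- function(coords, k, prune) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  nb <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k)])
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- length(intersect(nb[[i]], nb[[j]])) /
        length(union(nb[[i]], nb[[j]]))
      if (w >= prune) {
        out[[length(out) + 1]] <- data.frame(i = i, j = j, w = w)
      }
    }
  }
  do.call(rbind, out)
}

# direct, loop-written weighted KS enrichment score for a ranked list
direct_es <- function(stats, set) {
  ord <- order(stats, names(stats), decreasing = TRUE)
  hit <- names(stats)[ord] %in% set
  s <- as.numeric(stats[ord])
  nr <- sum(abs(s[hit]))
  nm <- sum(!hit)
  run <- 0
  best <- 0
  for (i in seq_along(s)) {
    run <- if (hit[i]) run + abs(s[i]) / nr else run - 1 / nm
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exact two-component normal mixture density and its interior minimum
mixture_valley <- function(w1, m1, s1, w2, m2, s2) {
  dens <- function(x) w1 * dnorm(x, m1, s1) + w2 * dnorm(x, m2, s2)
  optimize(dens, interval = c(m1, m2))$minimum
}
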