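# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most literal formulation of each definition and
# share no code with the package internals.

# Literal RSCU: loop over synonymous families, X_i / ((1/n) * sum(X)).
oracle_rscu <- function(counts, ct = codon_table()) {
  out <- numeric(64)
  names(out) <- ct$codons
  for (a in unique(ct$aa)) {
    fam <- ct$codons[ct$aa == a]
    n <- length(fam)
    tot <- sum(counts[fam])
    for (cd in fam) {
      out[cd] <- if (tot > 0) counts[[cd]] / ((1 / n) * tot) else 0
    }
  }
  out
}

# Literal CAI, product form: (prod r_i)^(1/L) over every codon occurrence,
# excluding Met, Trp and stops; r_i from the gene's own RSCU / family max.
oracle_cai <- function(counts, ct = codon_table()) {
  rscu <- oracle_rscu(counts, ct)
  r_prod <- 1
  L <- 0
  for (cd in ct$codons) {
    a <- ct$aa[[cd]]
    if (a %in% c("M", "W", "*")) next
    x <- counts[[cd]]
    if (x == 0) next
    fam <- ct$codons[ct$aa == a]
    r <- rscu[[cd]] / max(rscu[fam])
    r_prod <- r_prod * r^x
    L <- L + x
  }
  r_prod^(1 / L)
}

# Pairwise AUC: fraction of positive-negative pairs ranked correctly,
# ties counting one half.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Average precision by explicit threshold sweep over distinct scores.
oracle_ap <- function(y, s) {
  th <- sort(unique(s), decreasing = TRUE)
  prev_r <- 0
  ap <- 0
  for (t in th) {
    pred <- s >= t
    tp <- sum(pred & y == 1)
    r <- tp / sum(y == 1)
    p <- tp / sum(pred)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# All-pairs BFS with shortest-path counting, for betweenness/closeness
# oracles on small graphs. `adj` is a list of integer neighbor vectors.
bfs_counts <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

oracle_betweenness <- function(adj) {
  n <- length(adj)
  bfs <- lapply(seq_len(n), function(s) bfs_counts(adj, s))
  bc <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    dst <- bfs[[s]]$dist[t]
    if (is.infinite(dst)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == dst)
        bc[v] <- bc[v] + bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / bfs[[s]]$sigma[t]
    }
  }
  bc
}

oracle_closeness <- function(adj) {
  n <- length(adj)
  vapply(seq_len(n), function(s) {
    d <- bfs_counts(adj, s)$dist
    (n - 1) / sum(d[-s])
  }, numeric(1))
}

# Random CDS of `n_codons` codons drawn uniformly over all 64.
random_cds <- function(n_codons, ct = codon_table()) {
  paste(sample(ct$codons, n_codons, replace = TRUE), collapse = "")
}

# Random connected Erdos-Renyi graph with named nodes v1..vn.
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

adj_list_of <- function(g) lapply(igraph::as_adj_list(g), as.integer)

# Small cohort + sequence features, shared by several tests.
tiny_cohort <- function(n = 60, seed = 42, ...) {
  simulate_cohort(sim_params(n_genes = n, seed = seed, ...))
}
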