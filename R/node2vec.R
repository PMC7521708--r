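# Node embeddings from biased random walks: second-order (p, q) walk
# generation and a skip-gram-with-negative-sampling trainer (C++ core).
# Walks play the role of sentences; nodes the role of words; the learned
# input vectors are the per-gene network features.

#' Parameters for random-walk node embedding
#'
#' Walk-bias parameters follow the node2vec formulation: at a step from
#' `prev` to a neighbor `x` of the current node, the unnormalized weight is
#' `1/p` if `x == prev`, 1 if `x` is adjacent to `prev`, and `1/q`
#' otherwise. Defaults are the reference configuration (p = q = 1, 10 walks
#' of length 80 per node, window 10, 5 negative samples, 5 epochs, 64
#' dimensions).
#'
#' @param p Return parameter (> 0).
#' @param q In-out parameter (> 0).
#' @param walks_per_node,walk_length Walk corpus size controls.
#' @param dimensions Embedding dimensionality (64 in replication mode).
#' @param window Skip-gram context window.
#' @param epochs Training passes over the corpus.
#' @param negative_samples Negative samples per positive pair.
#' @param learning_rate Initial SGD learning rate (linearly decayed).
#' @param seed Seed for walk generation and training (single-worker,
#'   deterministic).
#' @return Object of class `node2vec_params`.
#' @export
node2vec_params <- function(p = 1, q = 1, walks_per_node = 10L,
                            walk_length = 80L, dimensions = 64L,
                            window = 10L, epochs = 5L,
                            negative_samples = 5L, learning_rate = 0.025,
                            seed = 1L) {
  if (p <= 0 || q <= 0) stopf("`p` and `q` must be positive")
  stopifnot(is_count(walks_per_node), is_count(walk_length),
            is_count(dimensions), is_count(window), is_count(epochs),
            is_count(negative_samples), learning_rate > 0)
  structure(list(p = p, q = q, walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 dimensions = as.integer(dimensions),
                 window = as.integer(window), epochs = as.integer(epochs),
                 negative_samples = as.integer(negative_samples),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "node2vec_params")
}

#' Second-order walk step distribution
#'
#' Probability of each neighbor of `cur` as the next walk node, given the
#' previous node `prev`: unnormalized weights `1/p` for returning to `prev`,
#' 1 for neighbors adjacent to `prev`, `1/q` for neighbors at distance 2
#' from `prev`; the first step (`prev = NULL`) is uniform over neighbors.
#'
#' @param g An [igraph::graph].
#' @param prev Previous node name, or `NULL` at the first step.
#' @param cur Current node name.
#' @param p,q Bias parameters.
#' @return Named probability vector over the neighbors of `cur`, summing
#'   to 1.
#' @export
step_distribution <- function(g, prev, cur, p = 1, q = 1) {
  nb <- names(igraph::neighbors(g, cur))
  if (!length(nb)) stopf("node %s is isolated", cur)
  if (is.null(prev)) {
    w <- rep(1, length(nb))
  } else {
    prev_nb <- names(igraph::neighbors(g, prev))
    w <- ifelse(nb == prev, 1 / p, ifelse(nb %in% prev_nb, 1, 1 / q))
  }
  stats::setNames(w / sum(w), nb)
}

# Adjacency in flat (CSR-like) form for fast vectorized walking.
flat_adjacency <- function(g) {
  al <- lapply(igraph::as_adj_list(g), as.integer)
  deg <- lengths(al)
  list(flat = unlist(al, use.names = FALSE), deg = deg,
       offset = c(0L, cumsum(deg)), al = al,
       names = igraph::V(g)$name)
}

#' Generate a biased random-walk corpus
#'
#' Starts `walks_per_node` walks at every node (node visitation order
#' reshuffled per pass from the seeded stream), each of `walk_length` nodes.
#' With `p = q = 1` steps are uniform over neighbors and the generation is
#' vectorized across walks; general (p, q) walks follow
#' [step_distribution()] exactly.
#'
#' @param g A connected [igraph::graph].
#' @param params A [node2vec_params()].
#' @return List of character vectors (walks over node names), of length
#'   `walks_per_node * vcount(g)`; class `walk_corpus`.
#' @export
generate_walks <- function(g, params = node2vec_params()) {
  stopifnot(inherits(params, "node2vec_params"))
  adj <- flat_adjacency(g)
  n <- igraph::vcount(g)
  if (any(adj$deg == 0)) stopf("graph has isolated nodes; filter first")
  len <- params$walk_length
  with_seed_(derive_seed(params$seed, 11L), {
    walks <- vector("list", params$walks_per_node * n)
    k <- 0L
    for (pass in seq_len(params$walks_per_node)) {
      starts <- sample.int(n)
      if (params$p == 1 && params$q == 1) {
        W <- matrix(0L, nrow = n, ncol = len)
        W[, 1] <- starts
        cur <- starts
        for (t in seq_len(len - 1L)) {
          pick <- adj$offset[cur] + 1L +
            as.integer(floor(stats::runif(n) * adj$deg[cur]))
          cur <- adj$flat[pick]
          W[, t + 1L] <- cur
        }
        for (i in seq_len(n)) walks[[k + i]] <- adj$names[W[i, ]]
        k <- k + n
      } else {
        for (s in starts) {
          wk <- integer(len)
          wk[1] <- s
          wk[2] <- adj$al[[s]][sample.int(adj$deg[s], 1L)]
          if (len > 2) for (t in 3:len) {
            prev <- wk[t - 2L]; cur <- wk[t - 1L]
            nb <- adj$al[[cur]]
            w <- ifelse(nb == prev, 1 / params$p,
                        ifelse(nb %in% adj$al[[prev]], 1, 1 / params$q))
            wk[t] <- nb[sample.int(length(nb), 1L, prob = w)]
          }
          k <- k + 1L
          walks[[k]] <- adj$names[wk]
        }
      }
    }
    structure(walks, class = "walk_corpus")
  })
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling (word2vec objective): walks are treated
#' as sentences and co-occurrence within `window` (with the usual random
#' window shrinking) is maximized. Negative targets are drawn from the
#' unigram distribution raised to 0.75. Single-threaded and fully
#' deterministic given `params$seed`.
#'
#' @param corpus A `walk_corpus` (list of node-name vectors).
#' @param params A [node2vec_params()].
#' @return Numeric matrix nodes x `dimensions` (rownames = node names).
#' @export
train_embeddings <- function(corpus, params = node2vec_params()) {
  stopifnot(inherits(params, "node2vec_params"))
  if (!length(corpus)) stopf("empty walk corpus")
  vocab <- sort(unique(unlist(corpus, use.names = FALSE)))
  tokens <- match(unlist(corpus, use.names = FALSE), vocab) - 1L
  starts <- c(0L, cumsum(lengths(corpus)))
  emb <- sgns_train(tokens, starts, length(vocab), params$dimensions,
                    params$window, params$epochs, params$negative_samples,
                    params$learning_rate, derive_seed(params$seed, 13L))
  rownames(emb) <- vocab
  colnames(emb) <- paste0("emb", seq_len(ncol(emb)))
  emb
}

#' Embed a network end to end
#'
#' Convenience wrapper: [generate_walks()] then [train_embeddings()]. Any
#' network node absent from the corpus (impossible when walks start at every
#' node) would be absent from the matrix.
#'
#' @inheritParams generate_walks
#' @return Embedding matrix as from [train_embeddings()].
#' @export
node2vec_embed <- function(g, params = node2vec_params()) {
  train_embeddings(generate_walks(g, params), params)
}

#' Read / write embeddings in word2vec text format
#'
#' Header line `"<n> <dim>"`, then one line per node: identifier followed by
#' the vector components.
#'
#' @param emb Embedding matrix (rownames = identifiers).
#' @param path File path.
#' @return `read_embeddings()` returns the matrix; `write_embeddings()` the
#'   path, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb), ncol(emb)), con)
  writeLines(paste(rownames(emb),
                   apply(emb, 1, function(r) paste(format(r, digits = 17),
                                                   collapse = " "))),
             con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " +")
  ids <- vapply(parts, `[`, character(1), 1)
  emb <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  if (nrow(emb) != hdr[1] || ncol(emb) != hdr[2])
    stopf("embedding file header does not match contents")
  rownames(emb) <- ids
  colnames(emb) <- paste0("emb", seq_len(ncol(emb)))
  emb
}
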