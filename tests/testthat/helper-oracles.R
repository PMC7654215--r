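# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive re-implementations (enumeration, brute force, direct
# arithmetic) kept separate from the package's own code paths.

# --- brute-force betweenness ------------------------------------------------
# All-pairs BFS on an edge list (character endpoints), counting shortest
# paths directly; betweenness(v) = sum over unordered pairs s != t != v of
# sigma_st(v) / sigma_st.  No igraph involved.
oracle_centrality <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges[, 1], edges[, 2])))
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- idx[[edges[r, 1]]]; b <- idx[[edges[r, 2]]]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  dist <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sig[s, s] <- 1
    frontier <- s; d <- 0
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[s, w])) {
          dist[s, w] <- d + 1
          nxt <- union(nxt, w)
        }
        if (dist[s, w] == d + 1) sig[s, w] <- sig[s, w] + sig[s, v]
      }
      frontier <- nxt; d <- d + 1
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t]) {
        btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
      }
    }
  }
  deg <- vapply(adj, length, 1L)
  data.frame(node = nodes, degree = deg, betweenness = btw,
             stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random simple graph as an interaction table (confidence 1)
random_graph_table <- function(n_nodes, p_edge, node_prefix = "N") {
  nodes <- sprintf("%s%02d", node_prefix, seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(nrow(pairs), 2)] <- TRUE
  suppressMessages(hbscreen::interaction_table(
    pairs[keep, 1], pairs[keep, 2], rep(1, sum(keep))))
}

# --- rank product -----------------------------------------------------------
oracle_rank_product <- function(mat) {
  ranks <- sapply(seq_len(ncol(mat)), function(j)
    rank(-mat[, j], ties.method = "average"))
  apply(ranks, 1, function(r) prod(r)^(1 / length(r)))
}

# exhaustive null for a 3-gene, 2-sample matrix: all (3!)^2 joint
# within-sample label permutations; returns the pooled null rp values and
# the per-permutation tail-count distribution for each observed value.
oracle_rp_exhaustive <- function(mat) {
  stopifnot(nrow(mat) == 3, ncol(mat) == 2)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  r <- sapply(1:2, function(j) rank(-mat[, j], ties.method = "average"))
  pool <- list(); counts <- list()
  obs <- oracle_rank_product(mat)
  per_perm <- matrix(0, nrow = 36, ncol = 3)
  i <- 0
  for (p1 in 1:6) for (p2 in 1:6) {
    i <- i + 1
    rp <- sqrt(r[perms[p1, ], 1] * r[perms[p2, ], 2])
    pool[[i]] <- rp
    per_perm[i, ] <- vapply(obs, function(o) sum(rp <= o), 0)
  }
  list(pool = unlist(pool), per_perm = per_perm, obs = obs)
}

# --- hypergeometric enrichment ----------------------------------------------
# exhaustive enumeration of all draws of size n from a population of size N
# containing K successes: P(X >= k)
oracle_hyper_upper <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  succ <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% succ))
  mean(hits >= k)
}

# --- permutation logrank ----------------------------------------------------
oracle_perm_logrank <- function(times, events, group, n_perm, seed = 1) {
  obs <- hbscreen::logrank_test(times, events, group)$chi2
  set.seed(seed)
  more <- 0L
  for (i in seq_len(n_perm)) {
    g <- sample(group)
    chi <- hbscreen::logrank_test(times, events, g)$chi2
    if (chi >= obs - 1e-12) more <- more + 1L
  }
  (1 + more) / (1 + n_perm)
}

# random tree on n nodes (uniform attachment), as edge matrix
random_tree_edges <- function(n, prefix = "T") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  parent <- vapply(2:n, function(i) sample.int(i - 1, 1), 1L)
  cbind(nodes[parent], nodes[2:n])
}
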