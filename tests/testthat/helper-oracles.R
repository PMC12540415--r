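# Independent brute-force oracles for the graph measures, used to validate
# the Dijkstra/Brandes implementations on small graphs. All of these
# enumerate rather than traverse: betweenness and closeness come from
# exhaustive simple-path enumeration, distances for global efficiency from
# Floyd-Warshall, and modularity from the pairwise double sum.

# Enumerate every simple path between all pairs on an edgewise distance
# matrix (Inf = absent edge) and record, per unordered pair: the shortest
# distance, the number of shortest paths, and how many pass through each
# interior node.
oracle_enumerate <- function(D, tol = 1e-9) {
  n <- nrow(D)
  best <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  through <- array(0, c(n, n, n))
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      dists <- numeric(0)
      interiors <- list()
      dfs <- function(cur, visited, d) {
        if (cur == t) {
          dists[length(dists) + 1] <<- d
          interiors[[length(dists)]] <<- setdiff(visited, c(s, t))
          return(invisible())
        }
        for (v in which(is.finite(D[cur, ]) & D[cur, ] > 0)) {
          if (!(v %in% visited)) dfs(v, c(visited, v), d + D[cur, v])
        }
      }
      dfs(s, s, 0)
      if (!length(dists)) next
      mn <- min(dists)
      sel <- which(dists <= mn + tol)
      best[s, t] <- best[t, s] <- mn
      sigma[s, t] <- sigma[t, s] <- length(sel)
      for (p in sel) {
        inner <- interiors[[p]]
        through[s, t, inner] <- through[s, t, inner] + 1
      }
    }
  }
  diag(best) <- 0
  list(dist = best, sigma = sigma, through = through)
}

oracle_betweenness <- function(net) {
  D <- to_distance(net)
  n <- nrow(D)
  en <- oracle_enumerate(D)
  raw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (en$sigma[s, t] == 0) next
      raw <- raw + en$through[s, t, ] / en$sigma[s, t]
    }
  }
  raw / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(net) {
  D <- to_distance(net)
  n <- nrow(D)
  en <- oracle_enumerate(D)
  vapply(seq_len(n), function(u) {
    d <- en$dist[u, -u]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / sum(d[is.finite(d)])) * (r / (n - 1))
  }, numeric(1))
}

oracle_floyd_warshall <- function(D) {
  n <- nrow(D)
  d <- D
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

oracle_efficiency <- function(net) {
  d <- oracle_floyd_warshall(to_distance(net))
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# Pairwise modularity double sum over ordered pairs (including i = j, whose
# adjacency term is zero but whose null-model term is not).
oracle_modularity_pairwise <- function(W, membership, gamma) {
  m2 <- sum(W)
  k <- rowSums(W)
  same <- outer(membership, membership, `==`)
  sum((W - gamma * outer(k, k) / m2) * same) / m2
}

# Random weighted graph for oracle comparisons: possibly disconnected.
random_test_network <- function(n, edge_prob = 0.6) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (stats::runif(1) < edge_prob) {
        w[i, j] <- w[j, i] <- stats::runif(1, 0.2, 1)
      }
    }
  }
  functional_network(w)
}
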