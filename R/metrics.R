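# Single-source shortest paths on an edgewise distance matrix (Inf = no
# edge), with shortest-path counting and predecessor lists as needed for
# Brandes-style betweenness accumulation. Equal-length path multiplicity is
# counted exactly, with a small tolerance for floating-point ties.
.sssp <- function(D, s, tol = 1e-10) {
  n <- nrow(D)
  dist <- rep(Inf, n)
  dist[s] <- 0
  sigma <- numeric(n)
  sigma[s] <- 1
  preds <- vector("list", n)
  done <- logical(n)
  visit_order <- integer(n)
  n_done <- 0L
  repeat {
    cand <- dist
    cand[done] <- Inf
    u <- which.min(cand)
    if (!is.finite(cand[u])) break
    done[u] <- TRUE
    n_done <- n_done + 1L
    visit_order[n_done] <- u
    du <- D[u, ]
    nb <- which(!done & is.finite(du) & du > 0)
    for (v in nb) {
      alt <- dist[u] + du[v]
      if (alt < dist[v] - tol) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (alt <= dist[v] + tol) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds,
       order = visit_order[seq_len(n_done)])
}

# All-pairs shortest distances (row u = distances from node u).
.all_distances <- function(D) {
  n <- nrow(D)
  out <- matrix(Inf, n, n)
  for (s in seq_len(n)) out[s, ] <- .sssp(D, s)$dist
  dimnames(out) <- dimnames(D)
  out
}

.metric_result <- function(values, node_ids, raw = NULL) {
  names(values) <- node_ids
  res <- list(values = values, mean = mean(values), max = max(values))
  if (!is.null(raw)) {
    names(raw) <- node_ids
    res$raw <- raw
  }
  res
}

#' Betweenness centrality of a weighted network
#'
#' For each node `v`, the fraction of all shortest paths between node pairs
#' that traverse `v`: the sum over unordered pairs `s != t` (both different
#' from `v`) of `sigma(s,t|v) / sigma(s,t)`, where `sigma(s,t)` counts
#' shortest paths between `s` and `t` on the distance-transformed graph (see
#' [to_distance()]) and `sigma(s,t|v)` those passing through `v`. Pairs with
#' no path contribute 0. Computed by Dijkstra traversals with predecessor
#' counting and Brandes dependency accumulation. The normalized value divides
#' by `(n-1)(n-2)/2`, the number of pairs a node could mediate, so results
#' lie in `[0, 1]`.
#'
#' @param net a [functional_network()] with at least 3 nodes.
#' @return A list with `values` (named, normalized), `raw` (unnormalized pair
#'   fractions), `mean` and `max` of the normalized values.
#' @export
betweenness <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  n <- length(net$node_ids)
  if (n < 3) {
    stop("betweenness is undefined for networks with fewer than 3 nodes")
  }
  D <- to_distance(net)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sp <- .sssp(D, s)
    delta <- numeric(n)
    for (w in rev(sp$order)) {
      coef <- (1 + delta[w]) / sp$sigma[w]
      for (v in sp$preds[[w]]) {
        delta[v] <- delta[v] + sp$sigma[v] * coef
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  raw <- bc / 2  # undirected: each pair accumulated from both endpoints
  .metric_result(raw / ((n - 1) * (n - 2) / 2), net$node_ids, raw = raw)
}

#' Closeness centrality of a weighted network
#'
#' For node `u` with `r_u` reachable nodes at distances `d(v, u)`, closeness
#' is `r_u / sum(d(v, u))`, the reciprocal of the average shortest-path
#' distance to the nodes that can actually be reached. On a disconnected
#' graph this per-component value is additionally multiplied by
#' `r_u / (n - 1)` (the Wasserman-Faust correction), penalizing nodes that
#' reach only a small component; on a connected graph the correction factor
#' is 1 and the classical `(n-1) / sum(d)` form is recovered. Isolated nodes
#' score 0.
#'
#' @param net a [functional_network()].
#' @param dist optional precomputed all-pairs distance matrix (rows =
#'   sources), as produced internally; supplied by callers that already ran
#'   the shortest-path sweep.
#' @return A list with named `values`, `mean` and `max`.
#' @export
closeness <- function(net, dist = NULL) {
  stopifnot(inherits(net, "functional_network"))
  n <- length(net$node_ids)
  if (is.null(dist)) dist <- .all_distances(to_distance(net))
  vals <- vapply(seq_len(n), function(u) {
    d <- dist[u, -u]
    reach <- is.finite(d)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / sum(d[reach])) * (r / (n - 1))
  }, numeric(1))
  .metric_result(vals, net$node_ids)
}

#' Degree centrality (node strength) of a weighted network
#'
#' The strength of each node (sum of its edge weights) divided by `n - 1`.
#' On a binary graph this reduces to the classical degree centrality.
#'
#' @param net a [functional_network()].
#' @return A list with named `values`, `mean` and `max`.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  n <- length(net$node_ids)
  if (n < 2) stop("degree centrality needs at least 2 nodes")
  .metric_result(rowSums(net$weights) / (n - 1), net$node_ids)
}

#' Global efficiency of a weighted network
#'
#' The average over all ordered node pairs of the reciprocal shortest-path
#' distance, `E_g = (1 / (n (n - 1))) * sum_{i != j} 1 / d_ij`; unreachable
#' pairs contribute 0.
#'
#' @inheritParams closeness
#' @return A single number.
#' @export
global_efficiency <- function(net, dist = NULL) {
  stopifnot(inherits(net, "functional_network"))
  n <- length(net$node_ids)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  if (is.null(dist)) dist <- .all_distances(to_distance(net))
  inv <- 1 / dist
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Per-node centrality table with network-level summaries
#'
#' Computes betweenness, closeness and degree centrality for every node of a
#' network, sharing a single shortest-path sweep, and attaches the
#' network-level mean and max of each measure.
#'
#' @param net a [functional_network()].
#' @return A data frame of class `centrality_table` with columns `node_id`,
#'   `betweenness`, `betweenness_raw`, `closeness`, `degree`; the attribute
#'   `summary` holds a data frame of per-measure mean and max, and
#'   `global_efficiency` holds the network's global efficiency.
#' @export
centrality_table <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  D <- to_distance(net)
  dist <- .all_distances(D)
  bt <- betweenness(net)
  cl <- closeness(net, dist = dist)
  dg <- degree_centrality(net)
  eff <- global_efficiency(net, dist = dist)
  out <- data.frame(node_id = net$node_ids,
                    betweenness = unname(bt$values),
                    betweenness_raw = unname(bt$raw),
                    closeness = unname(cl$values),
                    degree = unname(dg$values),
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- data.frame(
    measure = c("betweenness", "closeness", "degree"),
    mean = c(bt$mean, cl$mean, dg$mean),
    max = c(bt$max, cl$max, dg$max),
    stringsAsFactors = FALSE
  )
  attr(out, "global_efficiency") <- eff
  class(out) <- c("centrality_table", "data.frame")
  out
}
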