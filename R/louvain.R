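# Modularity on a working adjacency matrix that may carry self-loops on its
# diagonal (aggregated super-node graphs). Communities are given as an
# integer membership vector. Uses the community-sum form
#   Q = sum_c [ L_c / m - gamma * (k_c / (2m))^2 ]
# with m the total edge weight, L_c the intra-community weight and k_c the
# community strength.
.modularity_w <- function(W, membership, gamma) {
  m2 <- sum(W)  # = 2m (each off-diagonal edge counted twice, self-loops once
  # per direction in aggregated graphs, where diag already holds 2 * L_c)
  if (m2 <= 0) stop("modularity is undefined for a network with no edges (m = 0)")
  k <- rowSums(W)
  comms <- unique(membership)
  q <- 0
  for (cmm in comms) {
    idx <- membership == cmm
    l2 <- sum(W[idx, idx, drop = FALSE])  # 2 * L_c
    kc <- sum(k[idx])
    q <- q + l2 / m2 - gamma * (kc / m2)^2
  }
  q
}

#' Modularity of a partition
#'
#' Weighted modularity with resolution parameter `gamma`, computed in the
#' community-sum form `Q = sum_c [L_c/m - gamma (k_c / (2m))^2]`, where `m`
#' is the total edge weight of the network, `L_c` the total intra-community
#' weight and `k_c` the summed strength of community `c`. This equals the
#' pairwise form `(1/2m) sum_ij (A_ij - gamma k_i k_j / (2m)) delta(c_i,c_j)`.
#'
#' @param net a [functional_network()].
#' @param partition a `partition` object from [louvain()], or a membership
#'   vector (one community id per node, in node order or named by node id).
#' @param gamma resolution parameter (> 0); larger values favor smaller
#'   communities.
#' @return The modularity Q as a single number.
#' @export
modularity <- function(net, partition, gamma = 1) {
  stopifnot(inherits(net, "functional_network"))
  if (gamma <= 0) stop("gamma must be > 0")
  membership <- if (inherits(partition, "partition")) {
    partition$membership
  } else {
    partition
  }
  n <- length(net$node_ids)
  if (!is.null(names(membership))) {
    if (!setequal(names(membership), net$node_ids)) {
      stop("partition must cover exactly the network's nodes")
    }
    membership <- membership[net$node_ids]
  }
  if (length(membership) != n || anyNA(membership)) {
    stop("partition must assign every node to exactly one community")
  }
  .modularity_w(net$weights, as.integer(factor(membership)), gamma)
}

# One level of Louvain local moves on a working matrix W (self-loops allowed
# on the diagonal). Returns the membership found. Moves are accepted while
# the best candidate community improves Q by more than `eps`, with ties
# broken toward the lowest community id; node visit order is pre-shuffled by
# the caller.
.louvain_one_level <- function(W, gamma, ord, eps = 1e-7) {
  n <- nrow(W)
  memb <- seq_len(n)
  k <- rowSums(W)
  m2 <- sum(W)
  sigma_tot <- k  # per (singleton) community strength
  repeat {
    n_moves <- 0L
    for (i in ord) {
      ci <- memb[i]
      wi <- W[i, ]
      wi[i] <- 0
      # strength from i to each community with any connection, plus both the
      # current community and the singleton option
      kic_all <- rowsum(wi, memb)
      cand <- as.integer(rownames(kic_all))
      keep <- kic_all[, 1] > 0 | cand == ci
      cand <- cand[keep]
      kic <- kic_all[keep, 1]
      # remove i from its community before evaluating gains
      sigma_tot[ci] <- sigma_tot[ci] - k[i]
      gain <- 2 * kic / m2 - 2 * gamma * k[i] * sigma_tot[cand] / m2^2
      cur <- gain[cand == ci]
      best <- which.max(gain)  # candidates sorted by id: first max = lowest id
      if (gain[best] > cur + eps && cand[best] != ci) {
        memb[i] <- cand[best]
        n_moves <- n_moves + 1L
      }
      sigma_tot[memb[i]] <- sigma_tot[memb[i]] + k[i]
    }
    if (n_moves == 0L) break
  }
  memb
}

#' Louvain community detection
#'
#' Standard two-phase Louvain maximization of the resolution-parameterized
#' modularity on the network's edge weights: repeated single-node moves to
#' the neighboring community with the largest positive modularity gain
#' (accepted while the gain exceeds 1e-7, ties broken toward the lowest
#' community id), followed by aggregation of communities into super-nodes
#' with self-loops, until no further improvement. The node visit order is
#' shuffled deterministically from `seed`, so results are reproducible per
#' seed.
#'
#' @param net a [functional_network()] with at least one edge.
#' @param gamma resolution parameter (> 0).
#' @param seed integer seed controlling the node visit order.
#' @return An object of class `partition`: a list with `membership` (named
#'   integer vector, community ids 1..k in order of first appearance),
#'   `n_communities`, `Q` (modularity of the final partition at `gamma`),
#'   `gamma` and `q_trace` (modularity after each aggregation level;
#'   non-decreasing).
#' @export
louvain <- function(net, gamma = 1, seed = 1L) {
  stopifnot(inherits(net, "functional_network"))
  if (gamma <= 0) stop("gamma must be > 0")
  if (sum(net$weights) <= 0) {
    stop("louvain requires a network with at least one positive edge (m = 0)")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  n <- length(net$node_ids)
  W <- net$weights
  flat <- seq_len(n)  # membership of original nodes among current super-nodes
  q_trace <- numeric(0)
  repeat {
    ord <- sample.int(nrow(W))
    memb <- .louvain_one_level(W, gamma, ord)
    memb <- as.integer(factor(memb))
    flat <- memb[flat]
    q_trace <- c(q_trace, .modularity_w(net$weights, flat, gamma))
    if (max(memb) == nrow(W)) break  # no merge happened: done
    # aggregate communities into super-nodes; diagonal collects 2 * L_c
    W <- rowsum(t(rowsum(W, memb)), memb)
  }
  membership <- as.integer(factor(flat, levels = unique(flat)))
  names(membership) <- net$node_ids
  structure(
    list(membership = membership, n_communities = max(membership),
         Q = q_trace[length(q_trace)], gamma = gamma, q_trace = q_trace),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", x$n_communities, " communities, Q = ",
      format(x$Q, digits = 4), " (gamma = ", x$gamma, ")\n", sep = "")
  invisible(x)
}
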