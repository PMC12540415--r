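#' Weighted functional connectivity network
#'
#' Container for a per-animal, per-condition functional network: a symmetric
#' nonnegative weight matrix with zero diagonal over the retained ROIs,
#' together with the weight-to-distance convention used by all path-based
#' measures.
#'
#' @param weights symmetric nonnegative numeric matrix with zero diagonal; at
#'   least 2 nodes.
#' @param node_ids node identifiers; defaults to the rownames of `weights`.
#' @param distance_rule how an edge weight `w > 0` maps to a path distance:
#'   `"inverse_weight"` (`d = 1/w`, the default, common in weighted
#'   brain-network analysis) or `"one_minus_weight"` (`d = 1 - w`). Absent
#'   edges (`w = 0`) have infinite distance.
#' @param animal_id,condition provenance labels.
#' @param n_clipped number of negative-correlation edges clipped to zero
#'   during construction (0 when built directly).
#' @return An object of class `functional_network`.
#' @export
functional_network <- function(weights, node_ids = NULL,
                               distance_rule = c("inverse_weight",
                                                 "one_minus_weight"),
                               animal_id = "animal_1", condition = "V",
                               n_clipped = 0L) {
  distance_rule <- match.arg(distance_rule)
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  n <- nrow(weights)
  if (n < 2 || ncol(weights) != n) {
    stop("weights must be a square matrix with at least 2 nodes")
  }
  if (anyNA(weights)) stop("weights contain missing values")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (max(abs(weights - t(weights))) > 1e-12) stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  if (is.null(node_ids)) {
    node_ids <- rownames(weights)
    if (is.null(node_ids)) node_ids <- sprintf("node_%03d", seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n || anyDuplicated(node_ids)) {
    stop("node_ids must be unique and match the matrix dimension")
  }
  dimnames(weights) <- list(node_ids, node_ids)
  structure(
    list(weights = weights, node_ids = node_ids,
         distance_rule = distance_rule, animal_id = as.character(animal_id),
         condition = condition, n_clipped = as.integer(n_clipped)),
    class = "functional_network"
  )
}

#' @export
print.functional_network <- function(x, ...) {
  n <- length(x$node_ids)
  n_edges <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("<functional_network> ", n, " nodes, ", n_edges, " weighted edges",
      " (", x$n_clipped, " negative edges clipped)\n", sep = "")
  cat("  animal: ", x$animal_id, " | condition: ", x$condition,
      " | distance rule: ", x$distance_rule, "\n", sep = "")
  invisible(x)
}

#' Build a functional network from processed traces
#'
#' Computes the pairwise correlation between the processed traces of every
#' ROI pair over the full time series, clips negative correlations to zero
#' (path-based measures require nonnegative weights), and zeroes weights
#' below `threshold`. With the default `threshold = 0` the graph is fully
#' weighted; near-zero connections stay in the network rather than being
#' pruned.
#'
#' @param trace a [trace_matrix()] at stage `smoothed` or `normalized` with
#'   at least 2 ROIs and 3 frames. Because the correlation is invariant to
#'   per-ROI affine rescaling, either stage yields the same network.
#' @param threshold weights strictly below this value are set to 0 (default
#'   0).
#' @param distance_rule see [functional_network()].
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return A [functional_network()].
#' @export
build_network <- function(trace, threshold = 0,
                          distance_rule = c("inverse_weight",
                                            "one_minus_weight"),
                          method = c("pearson", "spearman")) {
  stopifnot(inherits(trace, "trace_matrix"))
  method <- match.arg(method)
  distance_rule <- match.arg(distance_rule)
  .require_stage(trace, c("smoothed", "normalized"), "build_network")
  if (nrow(trace$values) < 2) stop("build_network needs at least 2 ROIs")
  if (ncol(trace$values) < 3) stop("build_network needs at least 3 frames")
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  sds <- apply(trace$values, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("ROI(s) with zero temporal variance (should have been excluded by ",
         "QC): ", paste(trace$roi_ids[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(trace$values), method = method)
  w <- pmax(r, 0)
  n_clipped <- sum(r[upper.tri(r)] < 0)
  w[w < threshold] <- 0
  diag(w) <- 0
  w <- (w + t(w)) / 2  # enforce exact symmetry against round-off
  functional_network(w, node_ids = trace$roi_ids,
                     distance_rule = distance_rule,
                     animal_id = trace$animal_id, condition = trace$condition,
                     n_clipped = n_clipped)
}

#' Distance matrix of a functional network
#'
#' Applies the network's weight-to-distance rule edgewise: `d = 1/w` under
#' `inverse_weight` (default) or `d = 1 - w` under `one_minus_weight`, with
#' `d = Inf` for absent edges (`w = 0`). Shortest-path computations treat
#' `Inf` as unreachable. The diagonal is 0.
#'
#' @param net a [functional_network()].
#' @return Numeric matrix of edgewise distances.
#' @export
to_distance <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  w <- net$weights
  d <- switch(net$distance_rule,
              inverse_weight = ifelse(w > 0, 1 / w, Inf),
              one_minus_weight = ifelse(w > 0, 1 - w, Inf))
  diag(d) <- 0
  dimnames(d) <- dimnames(w)
  d
}
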