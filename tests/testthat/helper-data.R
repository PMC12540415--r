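# Shared fixtures built in code.

# A toy trace matrix at an arbitrary stage.
toy_trace <- function(values, stage = "smoothed", frame_rate = 10,
                      condition = "V", ...) {
  m <- as.matrix(values)
  rownames(m) <- NULL  # rbind() names rows after its arguments
  trace_matrix(m, frame_rate = frame_rate,
               condition = condition, stage = stage, ...)
}

# Star network: node 1 is the center, connected to `n_leaves` leaves with
# unit weights (unit distances under the 1/w rule).
star_network <- function(n_leaves = 4) {
  n <- n_leaves + 1
  w <- matrix(0, n, n)
  w[1, -1] <- w[-1, 1] <- 1
  functional_network(w)
}

complete_network <- function(n, weight = 1) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  functional_network(w)
}

# Two disjoint unit-weight triangles (nodes 1:3 and 4:6).
two_triangles <- function() {
  w <- matrix(0, 6, 6)
  tri <- function(idx) {
    for (i in idx) for (j in idx) if (i != j) w[i, j] <<- 1
  }
  tri(1:3)
  tri(4:6)
  functional_network(w)
}

# Small synthetic study used by several tests: fast but structurally
# complete (full trial grid, artifacts, both regimes).
small_synth_config <- function(seed = 1, n_animals = 1, n_neurons = 40,
                               n_repeats = 3, ...) {
  synth_config(n_animals = n_animals, n_neurons = n_neurons,
               n_repeats = n_repeats, seed = seed, ...)
}
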