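test_that("betweenness and closeness take their closed-form values on canonical graphs", {
  star <- star_network(4)
  bt <- betweenness(star)
  expect_equal(unname(bt$values), c(1, 0, 0, 0, 0))
  expect_equal(unname(bt$raw[1]), 6)
  expect_equal(bt$max, 1)

  cl <- closeness(star_network(4))
  expect_equal(unname(cl$values[1]), 1)
  expect_equal(unname(cl$values[2]), 4 / 7)

  cm <- complete_network(5)
  expect_equal(unname(betweenness(cm)$values), rep(0, 5))
  expect_equal(unname(closeness(cm)$values), rep(1, 5))

  expect_error(betweenness(functional_network(rbind(c(0, 1), c(1, 0)))),
               "fewer than 3")
})

test_that("degree centrality is strength over n - 1", {
  expect_equal(unname(degree_centrality(complete_network(4))$values),
               rep(1, 4))
  w <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))
  dg <- degree_centrality(functional_network(w))
  expect_equal(unname(dg$values), c(0.5, 0.5, 0))
  expect_equal(unname(dg$values[3]), 0)
})

test_that("global efficiency matches closed forms", {
  expect_equal(global_efficiency(complete_network(6)), 1)
  # 3-node path with unit edge distances
  w <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(global_efficiency(functional_network(w)), 5 / 6)
  empty <- functional_network(matrix(0, 4, 4))
  expect_equal(global_efficiency(empty), 0)
})

test_that("centralities match exhaustive path-enumeration oracles on random graphs", {
  set.seed(100)
  for (i in 1:30) {
    net <- random_test_network(sample(3:8, 1))
    expect_equal(unname(betweenness(net)$values), oracle_betweenness(net),
                 tolerance = 1e-9)
    expect_equal(unname(closeness(net)$values), oracle_closeness(net),
                 tolerance = 1e-9)
    expect_equal(global_efficiency(net), oracle_efficiency(net),
                 tolerance = 1e-12)
  }
})

test_that("modularity takes its closed-form values and matches the pairwise form", {
  tri <- two_triangles()
  memb <- c(1, 1, 1, 2, 2, 2)
  names(memb) <- tri$node_ids
  expect_equal(modularity(tri, memb, gamma = 1), 0.5)
  one <- rep(1, 6)
  names(one) <- tri$node_ids
  expect_equal(modularity(tri, one, gamma = 1), 0)

  set.seed(7)
  for (i in 1:25) {
    net <- random_test_network(sample(4:8, 1))
    if (sum(net$weights) == 0) next
    memb <- sample(1:3, length(net$node_ids), replace = TRUE)
    g <- runif(1, 0.5, 2)
    expect_equal(modularity(net, memb, g),
                 oracle_modularity_pairwise(net$weights, memb, g),
                 tolerance = 1e-12)
  }

  expect_error(modularity(functional_network(matrix(0, 3, 3)), c(1, 1, 1)),
               "m = 0")
  expect_error(modularity(tri, memb, gamma = 0), "gamma")
  expect_error(modularity(tri, c(1, 1)), "every node")
})

test_that("Louvain recovers planted communities and their modularity", {
  tri <- two_triangles()
  part <- louvain(tri, gamma = 1, seed = 1)
  expect_equal(part$n_communities, 2)
  expect_equal(unname(part$membership[1:3]), rep(part$membership[[1]], 3))
  expect_equal(unname(part$membership[4:6]), rep(part$membership[[4]], 3))
  expect_equal(part$Q, 0.5)

  # planted two-block weighted network, strong contrast
  set.seed(20)
  for (seed in 1:5) {
    n <- 12
    blocks <- rep(1:2, each = n / 2)
    w <- matrix(0.05, n, n)
    w[blocks == 1, blocks == 1] <- 0.9
    w[blocks == 2, blocks == 2] <- 0.9
    w <- w * matrix(runif(n * n, 0.9, 1.1), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    part <- louvain(functional_network(w), gamma = 1, seed = seed)
    expect_equal(part$n_communities, 2)
    expect_equal(length(unique(part$membership[blocks == 1])), 1)
    expect_equal(length(unique(part$membership[blocks == 2])), 1)
  }

  expect_error(louvain(tri, gamma = -1), "gamma")
  expect_error(louvain(functional_network(matrix(0, 3, 3))), "m = 0")
})

test_that("Louvain is deterministic per seed and its recorded Q never decreases", {
  set.seed(33)
  for (i in 1:5) {
    net <- random_test_network(8)
    if (sum(net$weights) == 0) next
    p1 <- louvain(net, seed = 9)
    p2 <- louvain(net, seed = 9)
    expect_identical(p1$membership, p2$membership)
    expect_true(all(diff(p1$q_trace) >= -1e-12))
    # the returned Q matches an independent evaluation of the partition
    expect_equal(p1$Q, modularity(net, p1$membership, gamma = 1),
                 tolerance = 1e-12)
  }
})

test_that("partition quality is stable across seeds on synthetic networks", {
  cfg <- small_synth_config(seed = 6)
  ds <- generate_dataset(cfg)
  pre <- preprocess_traces(ds$traces$animal_01$V, ds$traces$animal_01$VT)
  net <- build_network(pre$V)
  qs <- vapply(1:10, function(s) louvain(net, seed = s)$Q, numeric(1))
  expect_lt(max(qs) - min(qs), 0.02)
})

test_that("metrics respond correctly to weight rescaling and isolated nodes", {
  set.seed(44)
  net <- random_test_network(7)
  w3 <- functional_network(net$weights * 3)
  expect_equal(betweenness(net)$values, betweenness(w3)$values,
               tolerance = 1e-12)
  expect_equal(order(closeness(net)$values), order(closeness(w3)$values))
  expect_equal(louvain(net, seed = 2)$membership,
               louvain(w3, seed = 2)$membership)
  expect_equal(louvain(net, seed = 2)$Q, louvain(w3, seed = 2)$Q,
               tolerance = 1e-12)
  # under d = 1/w, scaling weights by c scales efficiency by c
  expect_equal(global_efficiency(w3), 3 * global_efficiency(net),
               tolerance = 1e-12)

  # an isolated extra node can only lower mean closeness and efficiency
  n <- length(net$node_ids)
  w_iso <- rbind(cbind(net$weights, 0), 0)
  iso <- functional_network(w_iso)
  expect_lt(closeness(iso)$mean, closeness(net)$mean)
  expect_lt(global_efficiency(iso), global_efficiency(net))
})

test_that("centrality tables aggregate per-node measures with their summaries", {
  net <- star_network(4)
  ct <- centrality_table(net)
  expect_s3_class(ct, "centrality_table")
  expect_equal(nrow(ct), 5)
  summ <- attr(ct, "summary")
  expect_equal(summ$max[summ$measure == "betweenness"], 1)
  expect_true(all(summ$mean <= summ$max))
  expect_true(all(ct$betweenness >= 0 & ct$betweenness <= 1))
  expect_equal(attr(ct, "global_efficiency"),
               global_efficiency(net))
})
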