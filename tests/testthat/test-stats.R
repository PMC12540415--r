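test_that("the signed-rank test is exact on enumerable cases", {
  # 11 one-signed differences: W = 66, p = 2 / 2^11
  res <- wilcoxon_signed_rank((1:11) + 10, 1:11)
  expect_equal(res$statistic, 66)
  expect_equal(res$p_value, 2 / 2048)
  expect_equal(res$method, "exact")

  # a single nonzero pair is degenerate
  x <- c(1, 2, 3)
  y <- c(1, 2, 5)
  expect_error(wilcoxon_signed_rank(x, y), "no nonzero pairs")
  expect_error(wilcoxon_signed_rank(1:4, 1:3), "equal length")

  # symmetry under argument swap
  set.seed(1)
  a <- rnorm(9)
  b <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signed_rank(b, a)$p_value)
})

test_that("exact p-values agree with the reference implementation without ties", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the large-sample approximation tracks the exact distribution", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(10:15, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    p_exact <- wilcoxon_signed_rank(x, y)$p_value
    p_approx <- wilcoxon_signed_rank(x, y, exact_limit = 0)$p_value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("midranks handle ties and zero differences are dropped", {
  x <- c(3, 3, 5, 1, 2)
  y <- c(1, 1, 1, 1, 2)  # diffs 2, 2, 4, 0, 0
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$n, 3)
  expect_equal(res$n_dropped, 2)
  expect_equal(res$statistic, 1.5 + 1.5 + 3)
})

test_that("condition comparisons report direction, significance and degeneracies", {
  mv <- data.frame(animal_id = sprintf("a%02d", 1:11),
                   metric_up = (1:11) + 5, metric_down = 1:11,
                   metric_flat = rep(2, 11))
  mvt <- data.frame(animal_id = sprintf("a%02d", 1:11),
                    metric_up = 1:11, metric_down = (1:11) + 2,
                    metric_flat = rep(2, 11))
  cmp <- compare_conditions(mv, mvt)
  expect_s3_class(cmp, "group_comparison")
  expect_equal(nrow(cmp), 3)
  up <- cmp[cmp$metric == "metric_up", ]
  expect_equal(up$direction, "V_greater")
  expect_equal(up$p_value, 2 / 2048)
  expect_true(up$significant)
  down <- cmp[cmp$metric == "metric_down", ]
  expect_equal(down$direction, "VT_greater")
  expect_true(down$significant)
  flat <- cmp[cmp$metric == "metric_flat", ]
  expect_false(flat$significant)
  expect_equal(flat$flag, "all_differences_zero")
  expect_true(is.na(flat$p_value))
})

test_that("top-k selection is deterministic under ties and validates sizes", {
  net <- complete_network(8)  # all centralities tied
  ct <- centrality_table(net)
  amps <- setNames(rep(1, 8), ct$node_id)
  res <- top_k_response_analysis(ct, amps, k = 3)
  # ties broken toward the lower node id
  expect_equal(res$top_ids[1], paste(sort(ct$node_id)[1:3], collapse = ","))
  # fully tied amplitudes: no hierarchy
  expect_equal(res$p_value, rep(1, 3))
  expect_false(any(res$significant))

  expect_error(top_k_response_analysis(ct, amps, k = 8), "more than 8 nodes")
  bad <- setNames(rep(1, 8), paste0("x", 1:8))
  expect_error(top_k_response_analysis(ct, bad, k = 3), "cover exactly")
})

test_that("centrality-response correlations flag degenerate inputs and detect linearity", {
  net <- star_network(6)
  ct <- centrality_table(net)
  amps <- setNames(2 * ct$closeness, ct$node_id)
  res <- centrality_response_correlation(ct, amps)
  expect_equal(res$r[res$centrality == "closeness"], 1, tolerance = 1e-12)

  const <- setNames(rep(3, nrow(ct)), ct$node_id)
  res2 <- centrality_response_correlation(ct, const)
  expect_true(all(!res2$defined))
  expect_true(all(is.na(res2$r)))

  # independent (permuted) amplitudes on many nodes: no significant link
  set.seed(8)
  fake <- data.frame(node_id = sprintf("n%03d", 1:150),
                     betweenness = runif(150), betweenness_raw = runif(150),
                     closeness = runif(150), degree = runif(150))
  class(fake) <- c("centrality_table", "data.frame")
  amps3 <- setNames(sample(fake$closeness), fake$node_id)
  res3 <- centrality_response_correlation(fake, amps3)
  expect_true(all(abs(res3$r) < 0.2))
  expect_true(all(res3$p_value > 0.01))
})
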