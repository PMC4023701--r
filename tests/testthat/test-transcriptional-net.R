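test_that("mutual information is symmetric, non-negative and rank-invariant", {
  set.seed(20)
  x <- rnorm(300); y <- 0.7 * x + rnorm(300)
  expect_identical(pairwise_mi(x, y), pairwise_mi(y, x))
  expect_gte(pairwise_mi(x, y), 0)
  expect_equal(pairwise_mi(x, rnorm(300)) >= 0, TRUE)
  # strictly monotone transforms leave the rank-binned estimate unchanged
  expect_identical(pairwise_mi(x, y), pairwise_mi(exp(x), y))
  expect_identical(pairwise_mi(x, y), pairwise_mi(x, y^3 + 5 * y))
  expect_equal(pairwise_mi(rep(1, 50), rnorm(50)), 0)
  expect_error(pairwise_mi(1:10, 1:9), "equal length")
})

test_that("MI is near zero for independent pairs and matches the Gaussian
           closed form for correlated ones", {
  set.seed(21)
  mis <- replicate(10, pairwise_mi(rnorm(2000), rnorm(2000)))
  expect_lte(max(mis), 0.05)
  rho <- 0.8
  truth <- -0.5 * log2(1 - rho^2)
  mi <- mean(replicate(5, {
    x <- rnorm(5000)
    pairwise_mi(x, rho * x + sqrt(1 - rho^2) * rnorm(5000))
  }))
  expect_lt(abs(mi - truth), 0.1)
})

test_that("MI threshold is seeded, calibrated, and vanishing as alpha -> 1", {
  spec <- tiny_spec(n_genes = 60, n_tf = 0, targets_per_tf = 0, n_pairs = 0,
                    effect_size = 0, seed = 31)
  em <- generate_expression(spec)$expression
  thr1 <- mi_threshold(em, n_perm = 200, alpha = 0.05, seed = 4)
  thr2 <- mi_threshold(em, n_perm = 200, alpha = 0.05, seed = 4)
  expect_identical(thr1, thr2)
  expect_lte(mi_threshold(em, n_perm = 200, alpha = 0.999, seed = 4),
             mi_threshold(em, n_perm = 200, alpha = 0.05, seed = 4))
  expect_lte(mi_threshold(em, n_perm = 200, alpha = 0.999, seed = 4), 0.05)
  expect_error(mi_threshold(em, n_perm = 50), ">= 100")
  expect_error(mi_threshold(em, n_perm = 200, alpha = 1.5), "alpha")
  # on null data the exceedance rate of true pairs is close to alpha
  thr <- mi_threshold(em, n_perm = 1000, alpha = 0.10, seed = 5)
  v <- em$values
  set.seed(6)
  pairs <- t(replicate(400, sample.int(nrow(v), 2)))
  exceed <- mean(vapply(seq_len(400), function(i)
    pairwise_mi(v[pairs[i, 1], ], v[pairs[i, 2], ]) > thr, logical(1)))
  expect_lt(abs(exceed - 0.10), 0.06)
})

test_that("DPI pruning removes the weakest triangle edge, respects
           tolerance, and is idempotent", {
  tri <- data.frame(a = c("A", "B", "A"), b = c("B", "C", "C"),
                    mi = c(1.0, 0.9, 0.5))
  pruned <- dpi_prune(tri, tolerance = 0)
  expect_setequal(paste(pruned$a, pruned$b), c("A B", "B C"))
  expect_equal(nrow(dpi_prune(tri, tolerance = 1)), 3)
  # tolerance rescues a borderline edge: 0.5 > 0.9 * (1 - 0.5)
  expect_equal(nrow(dpi_prune(tri, tolerance = 0.5)), 3)
  set.seed(22)
  n <- 12
  full <- expand.grid(i = 1:n, j = 1:n)
  full <- full[full$i < full$j, ]
  edges <- data.frame(a = paste0("n", full$i), b = paste0("n", full$j),
                      mi = runif(nrow(full)))
  once <- dpi_prune(edges, tolerance = 0.1)
  expect_identical(dpi_prune(once, tolerance = 0.1), once)
})

test_that("DPI prunes the indirect edge of a simulated Markov chain", {
  set.seed(23)
  x <- rnorm(5000)
  y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(5000)
  z <- 0.9 * y + sqrt(1 - 0.81) * rnorm(5000)
  edges <- data.frame(a = c("X", "Y", "X"), b = c("Y", "Z", "Z"),
                      mi = c(pairwise_mi(x, y), pairwise_mi(y, z),
                             pairwise_mi(x, z)))
  pruned <- dpi_prune(edges, tolerance = 0)
  expect_setequal(paste(pruned$a, pruned$b), c("X Y", "Y Z"))
})

test_that("network inference recovers planted TF-target edges", {
  spec <- cohort_spec(n_genes = 250, n_tf = 20, targets_per_tf = 10,
                      n_pairs = 0, seed = 33)
  sim <- generate_expression(spec)
  em_a <- subset_expression(sim$expression,
                            samples = a_samples(sim$expression))
  expect_equal(nrow(infer_network(em_a, character(0))$edges), 0)
  net <- infer_network(em_a, sim$truth$tf_set, n_perm = 1000, seed = 1)
  net2 <- infer_network(em_a, sim$truth$tf_set, n_perm = 1000, seed = 1)
  expect_identical(net$edges, net2$edges)
  planted <- unlist(mapply(paste, names(sim$truth$tf_targets),
                           sim$truth$tf_targets))
  pred <- paste(net$edges$tf, net$edges$target)
  tp <- sum(pred %in% planted)
  expect_gte(tp / length(pred), 0.8)     # precision
  expect_gte(tp / length(planted), 0.6)  # recall
})

test_that("network comparison is plain node-set algebra", {
  mk <- function(nodes) {
    tfs <- nodes[1]
    edges <- if (length(nodes) > 1)
      data.frame(tf = tfs, target = nodes[-1], mi = 1)
    else data.frame(tf = character(0), target = character(0), mi = numeric(0))
    transcriptional_network(edges, tf_set = tfs)
  }
  na <- mk(c("a", "b", "c"))
  nh <- mk(c("b", "c", "d"))
  d <- compare_networks(na, nh)
  expect_setequal(d$gained, "a")
  expect_setequal(d$lost, "d")
  expect_setequal(d$shared, c("b", "c"))
  same <- compare_networks(na, na)
  expect_length(same$gained, 0)
  expect_length(same$lost, 0)
  set.seed(24)
  for (i in 1:20) {
    a <- mk(sample(letters, sample(3:10, 1)))
    h <- mk(sample(letters, sample(3:10, 1)))
    d <- compare_networks(a, h)
    expect_equal(length(d$shared) + length(d$gained), length(a$nodes))
    expect_length(intersect(d$gained, d$lost), 0)
  }
})

test_that("resampling enrichment matches the hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  annotated <- universe[1:8]
  expect_equal(resampling_enrichment(universe, universe, universe,
                                     n_iter = 100, seed = 1)$p_value, 1)
  res <- resampling_enrichment(universe[9:13], annotated, universe,
                               n_iter = 500, seed = 2)
  expect_equal(res$p_value, 1) # observed overlap 0
  query <- c(universe[1:4], universe[15])
  res <- resampling_enrichment(query, annotated, universe,
                               n_iter = 4000, seed = 3)
  # oracle: P(overlap >= 4), overlap ~ Hypergeom(8 of 20, draw 5)
  p_exact <- sum(dhyper(4:5, 8, 12, 5))
  mc_sd <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_value - p_exact), 2 * mc_sd + 1 / 4001)
  expect_error(resampling_enrichment("x", "x", character(0)), "empty")
})

test_that("TF rank reproduces reference connection ratios", {
  expect_equal(tf_rank_score(9, 10), 0.900)
  expect_equal(tf_rank_score(4, 4), 1.000)
  expect_equal(tf_rank_score(0, 2), 0.000)
  expect_equal(tf_rank_score(143, 162), 0.883)
  expect_equal(tf_rank_score(106, 133), 0.797)
  expect_equal(tf_rank_score(129, 408), 0.316)
  expect_error(tf_rank_score(3, 0), "positive")

  net <- transcriptional_network(
    data.frame(tf = "TF1", target = paste0("t", 1:10), mi = 1),
    tf_set = "TF1")
  r <- rank_tf("TF1", net, deg_set = paste0("t", 1:9))
  expect_equal(r$connections, 10)
  expect_equal(r$deg_connections, 9)
  expect_equal(r$rank, 0.900)
})

test_that("TF rank p-value matches the hypergeometric tail and is seeded", {
  universe <- sprintf("g%02d", 1:20)
  net <- transcriptional_network(
    data.frame(tf = "TF1", target = universe[1:6], mi = 1),
    tf_set = "TF1")
  deg <- universe[c(1:4, 10:12)] # overlap 4 of 6 neighbors
  r1 <- tf_rank_pvalue("TF1", net, deg, universe, n_iter = 4000, seed = 9)
  r2 <- tf_rank_pvalue("TF1", net, deg, universe, n_iter = 4000, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  # oracle: X ~ Hypergeom(|deg|=7 of 20, draw 6 neighbors), P(X >= 4)
  p_exact <- sum(dhyper(4:6, 7, 13, 6))
  mc_sd <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(r1$p_value - p_exact), 3 * mc_sd + 1 / 4001)
  # rank 0 -> p = 1
  r0 <- tf_rank_pvalue("TF1", net, universe[10:12], universe,
                       n_iter = 200, seed = 9)
  expect_equal(r0$p_value, 1)
  expect_true(r1$p_value >= 1 / 4001 && r1$p_value <= 1)
})

test_that("empirical p-values are super-uniform under a random query", {
  set.seed(25)
  universe <- sprintf("g%03d", 1:60)
  annotated <- universe[1:20]
  ps <- vapply(1:40, function(i) {
    q <- sample(universe, 10)
    resampling_enrichment(q, annotated, universe, n_iter = 200,
                          seed = 100 + i)$p_value
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.15)
  expect_true(all(ps >= 1 / 201 & ps <= 1))
})

test_that("node topology equals a brute-force BFS oracle", {
  path <- transcriptional_network(
    data.frame(tf = c("a", "b"), target = c("b", "c"), mi = 1),
    tf_set = c("a", "b"))
  expect_equal(node_topology(path, "b"),
               list(eccentricity = 1, closeness = 1.0))
  expect_equal(node_topology(path, "a"),
               list(eccentricity = 2, closeness = 2 / 3))
  star <- transcriptional_network(
    data.frame(tf = "hub", target = paste0("leaf", 1:5), mi = 1),
    tf_set = "hub")
  expect_equal(node_topology(star, "hub")$eccentricity, 1)
  expect_equal(node_topology(star, "leaf1")$eccentricity, 2)

  set.seed(26)
  for (i in 1:30) {
    n <- 12
    g <- igraph::sample_gnm(n, 16)
    while (!igraph::is_connected(g)) g <- igraph::sample_gnm(n, 16)
    el <- igraph::as_edgelist(g)
    net <- list(edges = data.frame(a = paste0("v", el[, 1]),
                                   b = paste0("v", el[, 2])))
    nodes <- paste0("v", 1:n)
    for (v in sample(nodes, 3)) {
      d <- bfs_distances(net$edges, nodes, v)
      d <- d[names(d) != v]
      topo <- node_topology(net, v)
      expect_equal(topo$eccentricity, max(d))
      expect_equal(topo$closeness, (n - 1) / sum(d))
    }
  }
})

test_that("tf_rank_table ranks every connected TF with topology metrics", {
  net <- transcriptional_network(
    data.frame(tf = c("TF1", "TF1", "TF2", "TF2"),
               target = c("x", "y", "y", "z"), mi = 1),
    tf_set = c("TF1", "TF2", "TF3"))
  tab <- tf_rank_table(net, deg_set = c("x", "y"),
                       universe = c("TF1", "TF2", "x", "y", "z"),
                       n_iter = 100, seed = 1)
  expect_setequal(tab$tf, c("TF1", "TF2"))
  expect_equal(tab$rank[tab$tf == "TF1"], 1.0)
  expect_equal(tab$rank[tab$tf == "TF2"], 0.5)
  expect_true(all(tab$p_value >= 1 / 101 & tab$p_value <= 1))
})
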