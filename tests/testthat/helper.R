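# small cohort spec used across tests
tiny_spec <- function(...) {
  args <- list(n_patients = 10, n_healthy = 8, n_genes = 120, n_tf = 3,
               targets_per_tf = 5, n_pairs = 4, seed = 11)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# brute-force BFS shortest-path distances from `start` over an edge list
bfs_distances <- function(edges, nodes, start) {
  adj <- lapply(stats::setNames(nodes, nodes), function(n)
    unique(c(edges[[2]][edges[[1]] == n], edges[[1]][edges[[2]] == n])))
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[start] <- 0
  frontier <- start
  while (length(frontier)) {
    nxt <- character(0)
    for (f in frontier) for (nb in adj[[f]]) {
      if (dist[nb] > dist[f] + 1) {
        dist[nb] <- dist[f] + 1
        nxt <- c(nxt, nb)
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

# independent re-statement of the tri-tissue pattern rules, scalar form
pattern_oracle <- function(h, a, t, delta) {
  tl <- abs(a - t) <= delta && abs(a - h) > delta && abs(t - h) > delta &&
    sign(a - h) == sign(t - h)
  if (tl) return("tumor_like")
  if ((a - h > delta && a - t > delta) || (h - a > delta && t - a > delta))
    return("adjacent_specific")
  if ((h < a && a < t && a - h > delta && t - a > delta) ||
      (t < a && a < h && a - t > delta && h - a > delta))
    return("trend")
  "unclassified"
}

a_samples <- function(em) em$samples$sample_id[em$samples$tissue == "A"]
t_samples <- function(em) em$samples$sample_id[em$samples$tissue == "T"]
h_samples <- function(em) em$samples$sample_id[em$samples$tissue == "H"]
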