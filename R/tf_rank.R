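#' Resampling test for over-representation of an annotation in a gene set
#'
#' Empirical p-value for the overlap between a query gene set and an
#' annotated gene set: `|query|` genes are redrawn uniformly without
#' replacement from the universe `n_iter` times, and
#' `p = (1 + #{resampled overlap >= observed}) / (n_iter + 1)`. The add-one
#' convention keeps p strictly positive, with floor `1/(n_iter + 1)`.
#'
#' @param query_set Character vector, subset of `universe`.
#' @param annotated_set Character vector of annotated genes.
#' @param universe Character vector of all eligible genes.
#' @param n_iter Number of resamples (>= 100, default 1000).
#' @param seed Integer seed.
#' @return List with `p_value`, `observed` overlap, and `null_mean`.
#' @export
resampling_enrichment <- function(query_set, annotated_set, universe,
                                  n_iter = 1000, seed = 1L) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(query_set %in% universe))
    stop("'query_set' must be a subset of 'universe'", call. = FALSE)
  if (n_iter < 100) stop("'n_iter' must be >= 100", call. = FALSE)
  set.seed(seed)
  obs <- length(intersect(query_set, annotated_set))
  k <- length(query_set)
  hits <- vapply(seq_len(n_iter), function(b)
    length(intersect(sample(universe, k), annotated_set)), numeric(1))
  list(p_value = (1 + sum(hits >= obs)) / (n_iter + 1),
       observed = obs, null_mean = mean(hits))
}

# half-up rounding to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 3L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' TF rank score from connection counts
#'
#' The rank of a transcription factor is the fraction of the nodes linked
#' to it that are differentially expressed: `deg_connections /
#' connections`, displayed half-up rounded to 3 decimals.
#'
#' @param deg_connections Number of the TF's network neighbors that are DEG.
#' @param connections Total number of network neighbors (> 0).
#' @return Numeric rank(s) rounded half-up to 3 decimals.
#' @examples
#' tf_rank_score(9, 10)   # 0.900
#' tf_rank_score(143, 162) # 0.883
#' @export
tf_rank_score <- function(deg_connections, connections) {
  if (any(connections <= 0))
    stop("'connections' must be positive", call. = FALSE)
  if (any(deg_connections > connections))
    stop("'deg_connections' cannot exceed 'connections'", call. = FALSE)
  round_half_up(deg_connections / connections, 3L)
}

# distinct neighbors of `node` in the undirected view of the network
network_neighbors <- function(network, node) {
  e <- network$edges
  unique(c(e$target[e$tf == node], e$tf[e$target == node]))
}

#' Rank a transcription factor by its proportion of DEG targets
#'
#' Counts the TF's distinct neighbors in the undirected view of the
#' network (`connections`), the subset that are differentially expressed
#' (`deg_connections`), and their ratio (`rank`).
#'
#' @param tf TF gene symbol, present in the network.
#' @param network A `transcriptional_network`.
#' @param deg_set Character vector of DEG symbols.
#' @return List with `tf`, `connections`, `deg_connections`, `rank`
#'   (half-up, 3 decimals). A TF with zero neighbors is flagged
#'   `undefined = TRUE` and carries `rank = NA`.
#' @export
rank_tf <- function(tf, network, deg_set) {
  stopifnot(inherits(network, "transcriptional_network"))
  nb <- network_neighbors(network, tf)
  if (length(nb) == 0L)
    return(list(tf = tf, connections = 0L, deg_connections = 0L,
                rank = NA_real_, undefined = TRUE))
  deg_nb <- length(intersect(nb, deg_set))
  list(tf = tf, connections = length(nb), deg_connections = deg_nb,
       rank = tf_rank_score(deg_nb, length(nb)), undefined = FALSE)
}

#' Empirical p-value for a TF's rank score
#'
#' Null model: the DEG list is replaced by `|deg_set|` genes redrawn
#' uniformly without replacement from the universe, and the TF's rank is
#' recomputed; `p = (1 + #{null rank >= observed}) / (n_iter + 1)`.
#' Because the TF's neighborhood is fixed, the null overlap is
#' hypergeometric, which tests use as an independent oracle.
#'
#' @inheritParams rank_tf
#' @param universe Character vector of all eligible genes.
#' @param n_iter Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return List with the [rank_tf()] fields plus `p_value`.
#' @export
tf_rank_pvalue <- function(tf, network, deg_set, universe, n_iter = 1000,
                           seed = 1L) {
  r <- rank_tf(tf, network, deg_set)
  if (isTRUE(r$undefined))
    stop("TF '", tf, "' has no targets; rank undefined", call. = FALSE)
  set.seed(seed)
  nb <- network_neighbors(network, tf)
  k <- length(deg_set)
  # connections are fixed, so comparing overlap counts is equivalent to
  # comparing ranks and avoids display-rounding ties
  null_overlap <- vapply(seq_len(n_iter), function(b)
    length(intersect(nb, sample(universe, k))), numeric(1))
  r$p_value <- (1 + sum(null_overlap >= r$deg_connections)) / (n_iter + 1)
  r
}

#' Eccentricity and closeness centrality of a network node
#'
#' Both metrics are computed on the undirected view of the network, within
#' the node's connected component: eccentricity is the maximum shortest-path
#' length (hops) to any node of the component; closeness is
#' `(n_c - 1) / sum(shortest-path hops)` where `n_c` is the component size.
#' An isolated node has eccentricity 0 and closeness 0 by convention.
#'
#' @param network A `transcriptional_network` or any list with an `edges`
#'   data frame whose first two columns are node pairs.
#' @param node Node symbol.
#' @return List with `eccentricity` (integer hops) and `closeness` in
#'   \[0, 1\].
#' @export
node_topology <- function(network, node) {
  e <- network$edges
  nodes <- unique(c(as.character(e[[1]]), as.character(e[[2]]),
                    if (!is.null(network$nodes)) network$nodes))
  if (!node %in% nodes) stop("node '", node, "' not in network",
                             call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e[[1]]), to = as.character(e[[2]])),
    directed = FALSE, vertices = nodes)
  d <- igraph::distances(g, v = node, mode = "all")[1, ]
  d <- d[names(d) != node & is.finite(d)]
  if (length(d) == 0L) return(list(eccentricity = 0, closeness = 0))
  list(eccentricity = max(d), closeness = length(d) / sum(d))
}

#' Rank table for all TFs of a network
#'
#' Applies [rank_tf()], [tf_rank_pvalue()] and [node_topology()] to every
#' TF with at least one neighbor, optionally flagging membership of a
#' reference (e.g. healthy-mucosa) network.
#'
#' @param network A `transcriptional_network`.
#' @param deg_set Character vector of DEG symbols.
#' @param universe Gene universe for the resampling null.
#' @param reference_network Optional second network; adds an
#'   `in_reference_network` flag per TF.
#' @param n_iter,seed Passed to [tf_rank_pvalue()].
#' @return Data frame sorted by decreasing rank with columns `tf`,
#'   `connections`, `deg_connections`, `rank`, `p_value`, `eccentricity`,
#'   `closeness` (and `in_reference_network` when supplied).
#' @export
tf_rank_table <- function(network, deg_set, universe,
                          reference_network = NULL, n_iter = 1000,
                          seed = 1L) {
  tfs <- intersect(network$tf_set, network$nodes)
  tfs <- tfs[vapply(tfs, function(tf)
    length(network_neighbors(network, tf)) > 0L, logical(1))]
  rows <- lapply(seq_along(tfs), function(i) {
    r <- tf_rank_pvalue(tfs[i], network, deg_set, universe,
                        n_iter = n_iter, seed = seed + i)
    topo <- node_topology(network, tfs[i])
    data.frame(tf = r$tf, connections = r$connections,
               deg_connections = r$deg_connections, rank = r$rank,
               p_value = r$p_value, eccentricity = topo$eccentricity,
               closeness = topo$closeness, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tf = character(0), connections = integer(0),
                      deg_connections = integer(0), rank = numeric(0),
                      p_value = numeric(0), eccentricity = numeric(0),
                      closeness = numeric(0))
  if (!is.null(reference_network))
    out$in_reference_network <- out$tf %in% reference_network$nodes
  out[order(-out$rank, out$tf), , drop = FALSE]
}
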