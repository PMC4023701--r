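#' Select secreted/membrane seed genes for the crosstalk network
#'
#' Seeds are the union of genes up-regulated in adjacent mucosa (vs healthy)
#' and genes up-regulated in tumor (vs healthy) whose protein localization
#' is `secreted`, `membrane` or `both`. Genes up-regulated in both tissues
#' become a single seed with both tissues recorded. Genes missing from the
#' annotation raise a warning and are treated as localization `other`
#' (hence excluded).
#'
#' @param deg_a_up Symbols of genes up-regulated in adjacent mucosa.
#' @param deg_t_up Symbols of genes up-regulated in tumor.
#' @param annotation Data frame with columns `symbol` and `localization`
#'   (values in `secreted`, `membrane`, `both`, `other`).
#' @return Data frame with columns `symbol`, `localization`, `tissue_up`
#'   (comma-separated subset of `"A","T"`).
#' @export
select_seed_genes <- function(deg_a_up, deg_t_up, annotation) {
  stopifnot(all(c("symbol", "localization") %in% names(annotation)))
  genes <- union(deg_a_up, deg_t_up)
  loc <- annotation$localization[match(genes, annotation$symbol)]
  missing <- is.na(loc)
  if (any(missing)) {
    warning(sum(missing), " gene(s) missing from annotation, treated as ",
            "'other': ", paste(utils::head(genes[missing], 5),
                               collapse = ", "), call. = FALSE)
    loc[missing] <- "other"
  }
  tissue_up <- paste0(ifelse(genes %in% deg_a_up, "A", ""),
                      ifelse(genes %in% deg_a_up & genes %in% deg_t_up,
                             ",", ""),
                      ifelse(genes %in% deg_t_up, "T", ""))
  keep <- loc %in% c("secreted", "membrane", "both")
  data.frame(symbol = genes[keep], localization = loc[keep],
             tissue_up = tissue_up[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build the level-0 (direct interactions only) protein network
#'
#' Induced subgraph of the interactome on the seed genes: only edges with
#' both endpoints in the seed set are retained, and seeds left without any
#' edge are dropped, so every level-0 node has degree >= 1.
#'
#' @param seeds Data frame from [select_seed_genes()].
#' @param interactome Data frame with columns `gene_a`, `gene_b`
#'   (undirected edge list).
#' @return Object of class `ppi_network`: list with `nodes` (annotated seed
#'   rows), `edges`, `level = 0`.
#' @export
build_level0 <- function(seeds, interactome) {
  stopifnot(all(c("symbol", "localization", "tissue_up") %in% names(seeds)),
            all(c("gene_a", "gene_b") %in% names(interactome)))
  edges <- canonicalize_edges(interactome)
  keep <- edges$gene_a %in% seeds$symbol & edges$gene_b %in% seeds$symbol
  edges <- edges[keep, , drop = FALSE]
  used <- unique(c(edges$gene_a, edges$gene_b))
  structure(list(nodes = seeds[seeds$symbol %in% used, , drop = FALSE],
                 edges = edges, level = 0L),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network (level %d): %d nodes, %d edges\n",
              x$level, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

split_tissues <- function(s) {
  if (is.na(s) || s == "") character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
}

#' Classify protein-interaction edges into crosstalk directions
#'
#' For every edge of a level-0 network where one endpoint can act as the
#' secreted ligand (localization `secreted` or `both`) and the other as the
#' membrane receptor (`membrane` or `both`), one pair is emitted per valid
#' assignment of tissues drawn from each gene's `tissue_up` set. Directions
#' follow the tissue assignment: ligand in A with receptor in T is
#' **afferent** (adjacent mucosa signals the tumor), the converse is
#' **efferent**, and matching tissues are **autocrine_adjacent** or
#' **autocrine_tumor**. Duplicate (secreted gene, receptor gene, direction)
#' triples are collapsed. When the same physical edge supports both an
#' afferent and an efferent reading (both genes up in both tissues), its
#' pairs are flagged `ambiguous = TRUE` but keep their per-assignment
#' direction.
#'
#' @param network A `ppi_network` from [build_level0()] (annotated nodes).
#' @return Data frame with columns `secreted_gene`, `secreted_tissue`,
#'   `receptor_gene`, `receptor_tissue`, `direction`, `ambiguous`.
#' @export
classify_edges <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  ann <- network$nodes
  rows <- list()
  for (e in seq_len(nrow(network$edges))) {
    u <- network$edges$gene_a[e]
    v <- network$edges$gene_b[e]
    for (orient in list(c(u, v), c(v, u))) {
      s <- orient[1]; r <- orient[2]
      loc_s <- ann$localization[ann$symbol == s]
      loc_r <- ann$localization[ann$symbol == r]
      if (!loc_s %in% c("secreted", "both")) next
      if (!loc_r %in% c("membrane", "both")) next
      ts_all <- split_tissues(ann$tissue_up[ann$symbol == s])
      tr_all <- split_tissues(ann$tissue_up[ann$symbol == r])
      for (ts in ts_all) for (tr in tr_all) {
        dir <- if (ts == "A" && tr == "T") "afferent"
        else if (ts == "T" && tr == "A") "efferent"
        else if (ts == "A") "autocrine_adjacent" else "autocrine_tumor"
        rows[[length(rows) + 1L]] <- data.frame(
          secreted_gene = s, secreted_tissue = ts,
          receptor_gene = r, receptor_tissue = tr,
          direction = dir, edge = paste(min(u, v), max(u, v)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(secreted_gene = character(0),
                      secreted_tissue = character(0),
                      receptor_gene = character(0),
                      receptor_tissue = character(0),
                      direction = character(0), ambiguous = logical(0)))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$secreted_gene, out$receptor_gene,
                               out$direction)), , drop = FALSE]
  amb_edges <- intersect(out$edge[out$direction == "afferent"],
                         out$edge[out$direction == "efferent"])
  out$ambiguous <- out$edge %in% amb_edges &
    out$direction %in% c("afferent", "efferent")
  out$edge <- NULL
  rownames(out) <- NULL
  out
}

#' Summarize crosstalk pairs by direction and ligand family
#'
#' @param pairs Data frame from [classify_edges()] (or the packaged
#'   reference pair table run through [classify_reference_pairs()]).
#' @param family_prefixes Character vector of gene-symbol prefixes (e.g.
#'   `"SLIT"`); for each, pairs whose secreted gene starts with the prefix
#'   are counted per direction.
#' @return List with `direction_counts` (named vector over afferent,
#'   efferent, autocrine_adjacent, autocrine_tumor), `total`, and `family`
#'   (data frame `prefix`, `direction`, `n`; empty when no prefixes given).
#' @export
crosstalk_summary <- function(pairs, family_prefixes = character(0)) {
  dirs <- c("afferent", "efferent", "autocrine_adjacent", "autocrine_tumor")
  counts <- vapply(dirs, function(d) sum(pairs$direction == d), numeric(1))
  fam <- data.frame(prefix = character(0), direction = character(0),
                    n = numeric(0), stringsAsFactors = FALSE)
  for (pref in family_prefixes) {
    hit <- startsWith(pairs$secreted_gene, pref)
    for (d in dirs[vapply(dirs, function(d)
      any(pairs$direction == d), logical(1))]) {
      fam <- rbind(fam, data.frame(prefix = pref, direction = d,
                                   n = sum(hit & pairs$direction == d),
                                   stringsAsFactors = FALSE))
    }
  }
  list(direction_counts = counts, total = nrow(pairs), family = fam)
}

#' Build a level-1 network with bridge proteins
#'
#' Expands the seed set (e.g. membrane receptors plus AP-1 transcription
#' factors) with bridge proteins: non-seed interactome nodes adjacent to at
#' least two distinct seeds. Edges are all interactome edges among retained
#' nodes. Also reports which receptor seeds reach any TF seed via paths of
#' length <= 2 through retained nodes.
#'
#' @param seed_receptors,seed_tfs Character vectors of seed symbols
#'   (their union must be nonempty).
#' @param interactome Data frame with columns `gene_a`, `gene_b`.
#' @return Object of class `ppi_network` with `level = 1`, plus elements
#'   `bridge_nodes` and `reachable` (data frame `receptor`, `reaches_tf`).
#' @export
build_level1 <- function(seed_receptors, seed_tfs, interactome) {
  seeds <- union(seed_receptors, seed_tfs)
  if (length(seeds) == 0L) stop("seed set is empty", call. = FALSE)
  edges <- canonicalize_edges(interactome)
  touch <- edges$gene_a %in% seeds | edges$gene_b %in% seeds
  seed_nb <- rbind(
    data.frame(node = edges$gene_b[touch & edges$gene_a %in% seeds],
               seed = edges$gene_a[touch & edges$gene_a %in% seeds]),
    data.frame(node = edges$gene_a[touch & edges$gene_b %in% seeds],
               seed = edges$gene_b[touch & edges$gene_b %in% seeds]))
  seed_nb <- seed_nb[!seed_nb$node %in% seeds, , drop = FALSE]
  deg <- tapply(seed_nb$seed, seed_nb$node, function(s) length(unique(s)))
  bridges <- names(deg)[deg >= 2L]
  nodes <- union(seeds, bridges)
  kept <- edges[edges$gene_a %in% nodes & edges$gene_b %in% nodes, ,
                drop = FALSE]
  present <- intersect(nodes, unique(c(kept$gene_a, kept$gene_b)))

  # receptor -> TF reachability within <= 2 hops through retained nodes
  adj <- split(c(kept$gene_b, kept$gene_a), c(kept$gene_a, kept$gene_b))
  reaches <- vapply(seed_receptors, function(r) {
    nb <- adj[[r]]
    if (is.null(nb)) return(FALSE)
    if (any(nb %in% seed_tfs)) return(TRUE)
    any(unlist(adj[nb]) %in% seed_tfs)
  }, logical(1))
  structure(list(
    nodes = data.frame(symbol = present,
                       role = ifelse(present %in% bridges, "bridge",
                                     ifelse(present %in% seed_tfs, "tf",
                                            "receptor")),
                       stringsAsFactors = FALSE),
    edges = kept, level = 1L, bridge_nodes = intersect(bridges, present),
    reachable = data.frame(receptor = seed_receptors,
                           reaches_tf = unname(reaches),
                           stringsAsFactors = FALSE)),
    class = "ppi_network")
}

#' Classify a protein as epithelial or stromal
#'
#' Compares a gene's mean expression across sorted cell populations: it is
#' called `stromal` when the maximum of the fibroblast, endothelial and
#' leukocyte means exceeds the epithelial mean, `epithelial` otherwise
#' (ties resolve to epithelial).
#'
#' @param epithelial,fibroblast,endothelial,leukocyte Mean expression of
#'   the gene in each sorted population (all required, log2 units).
#' @return List with `label` (`"epithelial"` or `"stromal"`) and `margin`
#'   (stromal maximum minus epithelial mean; positive for stromal calls).
#' @export
compartment_classify <- function(epithelial, fibroblast, endothelial,
                                 leukocyte) {
  vals <- c(epithelial = epithelial, fibroblast = fibroblast,
            endothelial = endothelial, leukocyte = leukocyte)
  if (anyNA(vals) || length(vals) != 4L)
    stop("all four population means are required", call. = FALSE)
  stromal_max <- max(fibroblast, endothelial, leukocyte)
  list(label = if (stromal_max > epithelial) "stromal" else "epithelial",
       margin = stromal_max - epithelial)
}
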