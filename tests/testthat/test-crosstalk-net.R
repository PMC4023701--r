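ann_df <- function(symbol, localization, tissue_up) {
  data.frame(symbol = symbol, localization = localization,
             tissue_up = tissue_up, stringsAsFactors = FALSE)
}

ppi <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges, level = 0L),
            class = "ppi_network")
}

test_that("seed selection keeps secreted/membrane up-regulated genes", {
  ann <- ann_df(c("L1", "R1", "X1", "B1"),
                c("secreted", "membrane", "other", "both"),
                c("", "", "", ""))
  seeds <- select_seed_genes(deg_a_up = c("L1", "X1"),
                             deg_t_up = c("R1", "B1", "L1"),
                             annotation = ann)
  expect_setequal(seeds$symbol, c("L1", "R1", "B1"))
  expect_equal(seeds$tissue_up[seeds$symbol == "L1"], "A,T")
  expect_equal(seeds$tissue_up[seeds$symbol == "R1"], "T")
  expect_false("X1" %in% seeds$symbol) # localization "other"
  expect_warning(select_seed_genes("ZZ", character(0), ann), "missing")
})

test_that("disjoint category counts add up as in a two-tissue seed union", {
  adj <- c(sprintf("AS%03d", 1:111), sprintf("AM%03d", 1:213))
  tum <- c(sprintf("TS%03d", 1:250), sprintf("TM%03d", 1:192))
  ann <- ann_df(c(adj, tum),
                rep(c("secreted", "membrane", "secreted", "membrane"),
                    c(111, 213, 250, 192)),
                "")
  seeds <- select_seed_genes(adj, tum, ann)
  expect_equal(nrow(seeds), 766)
})

test_that("level-0 network is the induced subgraph with isolates dropped", {
  seeds <- ann_df(c("a", "b", "c"), rep("secreted", 3), "A")
  inter <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "x"))
  net <- build_level0(seeds, inter)
  expect_setequal(net$nodes$symbol, c("a", "b"))
  expect_equal(nrow(net$edges), 1)
  empty <- build_level0(seeds, data.frame(gene_a = "x", gene_b = "y"))
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)

  set.seed(30)
  pool <- sprintf("g%02d", 1:20)
  for (i in 1:25) {
    sd_genes <- sample(pool, 8)
    seeds <- ann_df(sd_genes, "membrane", "T")
    inter <- data.frame(gene_a = sample(pool, 15, TRUE),
                        gene_b = sample(pool, 15, TRUE))
    net <- build_level0(seeds, inter)
    # brute-force induced-subgraph oracle
    e <- inter[inter$gene_a != inter$gene_b, ]
    e <- e[e$gene_a %in% sd_genes & e$gene_b %in% sd_genes, ]
    key <- unique(paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b)))
    expect_setequal(paste(net$edges$gene_a, net$edges$gene_b), key)
    expect_setequal(net$nodes$symbol,
                    unique(c(e$gene_a, e$gene_b)))
  }
})

test_that("edge classification follows the tissue assignment rules", {
  nodes <- ann_df(c("SLIT2", "ROBO1", "IL8", "DARC", "VEGFA", "FLT1",
                    "S1", "S2"),
                  c("secreted", "membrane", "secreted", "membrane",
                    "secreted", "membrane", "secreted", "secreted"),
                  c("A", "T", "T", "A", "T", "T", "A", "A"))
  edges <- data.frame(gene_a = c("ROBO1", "DARC", "FLT1", "S1"),
                      gene_b = c("SLIT2", "IL8", "VEGFA", "S2"))
  pairs <- classify_edges(ppi(nodes, edges))
  get_dir <- function(s, r)
    pairs$direction[pairs$secreted_gene == s & pairs$receptor_gene == r]
  expect_equal(get_dir("SLIT2", "ROBO1"), "afferent")
  expect_equal(get_dir("IL8", "DARC"), "efferent")
  expect_equal(get_dir("VEGFA", "FLT1"), "autocrine_tumor")
  # two secreted-only genes never pair
  expect_false(any(pairs$secreted_gene %in% c("S1", "S2") |
                     pairs$receptor_gene %in% c("S1", "S2")))
  expect_true(all(!pairs$ambiguous))
})

test_that("dual-tissue genes yield one pair per assignment, flagged when
           both crosstalk readings exist", {
  nodes <- ann_df(c("L", "R"), c("secreted", "membrane"), c("A,T", "A,T"))
  pairs <- classify_edges(ppi(nodes, data.frame(gene_a = "L", gene_b = "R")))
  expect_equal(nrow(pairs), 4)
  expect_setequal(pairs$direction,
                  c("afferent", "efferent", "autocrine_adjacent",
                    "autocrine_tumor"))
  expect_true(all(pairs$ambiguous[pairs$direction %in%
                                    c("afferent", "efferent")]))
})

test_that("tissue swap maps afferent to efferent and swaps autocrine", {
  set.seed(31)
  for (i in 1:10) {
    n <- 12
    syms <- sprintf("n%02d", 1:n)
    nodes <- ann_df(syms,
                    sample(c("secreted", "membrane", "both"), n, TRUE),
                    sample(c("A", "T", "A,T"), n, TRUE))
    edges <- canonicalize_edges(
      data.frame(gene_a = sample(syms, 16, TRUE),
                 gene_b = sample(syms, 16, TRUE)))
    swap <- nodes
    swap$tissue_up <- vapply(strsplit(nodes$tissue_up, ","), function(x)
      paste(sort(ifelse(x == "A", "T", "A")), collapse = ","), "")
    c1 <- crosstalk_summary(classify_edges(ppi(nodes, edges)))
    c2 <- crosstalk_summary(classify_edges(ppi(swap, edges)))
    expect_equal(c1$direction_counts[["afferent"]],
                 c2$direction_counts[["efferent"]])
    expect_equal(c1$direction_counts[["efferent"]],
                 c2$direction_counts[["afferent"]])
    expect_equal(c1$direction_counts[["autocrine_adjacent"]],
                 c2$direction_counts[["autocrine_tumor"]])
    expect_equal(c1$direction_counts[["autocrine_tumor"]],
                 c2$direction_counts[["autocrine_adjacent"]])
  }
})

test_that("classified pairs never invent edges", {
  set.seed(32)
  syms <- sprintf("n%02d", 1:15)
  nodes <- ann_df(syms, sample(c("secreted", "membrane", "both"), 15, TRUE),
                  sample(c("A", "T"), 15, TRUE))
  edges <- canonicalize_edges(data.frame(gene_a = sample(syms, 25, TRUE),
                                         gene_b = sample(syms, 25, TRUE)))
  pairs <- classify_edges(ppi(nodes, edges))
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  got <- paste(pmin(pairs$secreted_gene, pairs$receptor_gene),
               pmax(pairs$secreted_gene, pairs$receptor_gene))
  expect_true(all(got %in% key))
})

test_that("level-1 expansion adds bridges and reports TF reachability", {
  inter <- data.frame(gene_a = c("R1", "x", "R2", "y"),
                      gene_b = c("x", "TF1", "y", "z"))
  net <- build_level1("R1", "TF1", inter)
  expect_true("x" %in% net$bridge_nodes)
  expect_true(net$reachable$reaches_tf[net$reachable$receptor == "R1"])

  # no node adjacent to 2 seeds -> induced subgraph on the seeds
  inter2 <- data.frame(gene_a = c("R1", "q"), gene_b = c("TF1", "w"))
  net2 <- build_level1("R1", "TF1", inter2)
  expect_length(net2$bridge_nodes, 0)
  expect_setequal(net2$nodes$symbol, c("R1", "TF1"))

  # randomized instances vs a brute-force path <= 2 oracle
  set.seed(33)
  for (i in 1:25) {
    pool <- sprintf("p%02d", 1:14)
    recs <- sample(pool, 3)
    tfs <- sample(setdiff(pool, recs), 2)
    inter <- canonicalize_edges(data.frame(gene_a = sample(pool, 20, TRUE),
                                           gene_b = sample(pool, 20, TRUE)))
    net <- build_level1(recs, tfs, inter)
    # oracle: adjacency over retained nodes (seeds + bridges)
    seeds <- union(recs, tfs)
    nb <- function(v, e) unique(c(e$gene_b[e$gene_a == v],
                                  e$gene_a[e$gene_b == v]))
    bridges <- Filter(function(v)
      length(intersect(nb(v, inter), seeds)) >= 2,
      setdiff(pool, seeds))
    retained <- union(seeds, bridges)
    e_kept <- inter[inter$gene_a %in% retained & inter$gene_b %in% retained, ]
    for (r in recs) {
      n1 <- nb(r, e_kept)
      reach <- any(n1 %in% tfs) ||
        any(unlist(lapply(n1, nb, e = e_kept)) %in% tfs)
      expect_equal(net$reachable$reaches_tf[net$reachable$receptor == r],
                   reach)
    }
    expect_setequal(net$bridge_nodes,
                    intersect(bridges, c(e_kept$gene_a, e_kept$gene_b)))
  }
})

test_that("compartment classification compares stromal max to epithelial", {
  expect_equal(compartment_classify(10, 5, 5, 5)$label, "epithelial")
  expect_equal(compartment_classify(6, 9, 4, 4)$label, "stromal")
  expect_equal(compartment_classify(5, 5, 5, 5)$label, "epithelial") # tie
  expect_error(compartment_classify(5, NA, 5, 5), "required")
  grid <- seq(4, 7, by = 1)
  cases <- expand.grid(e = grid, f = grid, en = grid, l = grid)
  got <- apply(cases, 1, function(r)
    compartment_classify(r[1], r[2], r[3], r[4])$label)
  want <- ifelse(pmax(cases$f, cases$en, cases$l) > cases$e,
                 "stromal", "epithelial")
  expect_identical(unname(got), want)
})

test_that("planted crosstalk directions are recovered with oracle DEG input", {
  spec <- tiny_spec(n_genes = 300, n_pairs = 10, seed = 41)
  sim <- generate_expression(spec)
  ann <- generate_annotation(spec, sim$truth)
  inter <- generate_interactome(spec, sim$truth)
  tu <- sim$truth$tissue_up
  a_up <- names(tu)[tu %in% c("A", "A,T")]
  t_up <- names(tu)[tu %in% c("T", "A,T")]
  seeds <- select_seed_genes(a_up, t_up, ann)
  pairs <- classify_edges(build_level0(seeds, inter))
  planted <- sim$truth$pairs
  found <- paste(pairs$secreted_gene, pairs$receptor_gene, pairs$direction)
  want <- paste(planted$ligand, planted$receptor, planted$direction)
  expect_gte(mean(want %in% found), 0.95)
})

test_that("crosstalk summary counts directions and ligand families", {
  empty <- crosstalk_summary(data.frame(secreted_gene = character(0),
                                        direction = character(0)))
  expect_equal(empty$total, 0)
  expect_true(all(empty$direction_counts == 0))

  cls <- classify_reference_pairs(crosstalk_reference_pairs())
  s <- crosstalk_summary(cls, family_prefixes = "SLIT")
  expect_equal(unname(s$direction_counts[c("afferent", "efferent")]),
               c(23, 61))
  expect_equal(s$total, 84)
  expect_equal(s$family$n[s$family$prefix == "SLIT" &
                            s$family$direction == "afferent"], 6)
})
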