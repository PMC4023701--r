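#' Generate a synthetic tri-tissue expression cohort with planted truth
#'
#' Simulates a log2 expression matrix under the cohort design described in
#' [cohort_spec()]: per-gene healthy baselines, pattern-dependent tissue
#' offsets, a per-gene patient random effect shared by each patient's paired
#' A and T samples, i.i.d. Gaussian noise, and an additive TF-to-target
#' coupling on the stochastic component of each TF's profile so that
#' co-expression (and hence mutual information) carries the planted
#' regulatory structure without shifting the targets' tissue means.
#'
#' Planted ligand-receptor pairs are assigned dedicated pattern classes so
#' their tissue of over-expression is unambiguous: afferent pairs couple an
#' adjacent-specific up-regulated ligand (up in A) to a trend up-regulated
#' receptor (up in T); efferent pairs the converse.
#'
#' The generator is deterministic: identical `spec` (including `spec$seed`)
#' yields bit-identical output. Expression uses the seed directly;
#' [generate_annotation()] and [generate_interactome()] use `seed + 1` and
#' `seed + 2`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `expression` (an [expression_matrix()]) and
#'   `truth` (class `planted_truth`: per-gene `pattern`, `sign`,
#'   `tissue_up`, TF sets `tf_set` and `tf_targets`, ligand-receptor
#'   `pairs`, and `localization` for the planted pair genes).
#' @examples
#' sim <- generate_expression(cohort_spec(n_patients = 5, n_healthy = 4,
#'                                        n_genes = 50, n_tf = 2,
#'                                        targets_per_tf = 4, n_pairs = 2,
#'                                        seed = 1))
#' dim(sim$expression)
#' table(sim$truth$pattern)
#' @export
generate_expression <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  ng <- spec$n_genes
  np <- spec$n_patients
  nh <- spec$n_healthy
  genes <- sprintf("G%05d", seq_len(ng))

  # gene role bookkeeping: TFs first, then their targets, then pair genes
  tf_set <- genes[seq_len(spec$n_tf)]
  n_tg <- spec$n_tf * spec$targets_per_tf
  target_idx <- spec$n_tf + seq_len(n_tg)
  tf_targets <- if (spec$n_tf > 0L && spec$targets_per_tf > 0L)
    split(genes[target_idx],
          rep(tf_set, each = spec$targets_per_tf))[tf_set]
  else stats::setNames(vector("list", spec$n_tf), tf_set)
  n_pair_genes <- 2L * spec$n_pairs
  if (spec$n_tf + n_tg + n_pair_genes > ng)
    stop("not enough genes to plant TFs, targets and ligand-receptor pairs",
         call. = FALSE)
  pair_idx <- spec$n_tf + n_tg + seq_len(n_pair_genes)

  # pattern classes and signs; pair genes get forced classes below
  pattern <- sample(c("tumor_like", "trend", "adjacent_specific", "null"),
                    ng, replace = TRUE,
                    prob = c(spec$frac_tumor_like, spec$frac_trend,
                             spec$frac_adjacent_specific, spec$frac_null))
  sign_up <- ifelse(stats::runif(ng) < spec$frac_up, 1, -1)
  sign_up[pattern == "null"] <- 0

  pairs <- NULL
  localization <- character(0)
  if (spec$n_pairs > 0L) {
    lig <- genes[pair_idx[seq_len(spec$n_pairs)]]
    rec <- genes[pair_idx[spec$n_pairs + seq_len(spec$n_pairs)]]
    n_aff <- ceiling(spec$n_pairs / 2)
    direction <- rep(c("afferent", "efferent"),
                     c(n_aff, spec$n_pairs - n_aff))
    # afferent: ligand up in A only, receptor up in T; efferent: converse
    lig_pat <- ifelse(direction == "afferent", "adjacent_specific", "trend")
    rec_pat <- ifelse(direction == "afferent", "trend", "adjacent_specific")
    pattern[match(lig, genes)] <- lig_pat
    pattern[match(rec, genes)] <- rec_pat
    sign_up[pair_idx] <- 1
    pairs <- data.frame(
      ligand = lig,
      ligand_tissue = ifelse(direction == "afferent", "A", "T"),
      receptor = rec,
      receptor_tissue = ifelse(direction == "afferent", "T", "A"),
      direction = direction, stringsAsFactors = FALSE)
    localization <- stats::setNames(rep(c("secreted", "membrane"),
                                        each = spec$n_pairs),
                                    c(lig, rec))
  }

  # tissue offsets vs the healthy baseline
  eff <- spec$effect_size * sign_up
  off_A <- ifelse(pattern == "tumor_like", eff,
                  ifelse(pattern == "trend", eff / 2,
                         ifelse(pattern == "adjacent_specific", eff, 0)))
  off_T <- ifelse(pattern %in% c("tumor_like", "trend"), eff, 0)

  baseline <- stats::rnorm(ng, spec$baseline_mean, spec$baseline_sd)
  n_samp <- 2L * np + nh
  col_tissue <- rep(c("A", "T", "H"), c(np, np, nh))
  patient <- c(sprintf("P%03d", seq_len(np)), sprintf("P%03d", seq_len(np)),
               rep(NA_character_, nh))
  sample_ids <- c(sprintf("A%03d", seq_len(np)), sprintf("T%03d", seq_len(np)),
                  sprintf("H%03d", seq_len(nh)))

  # stochastic component: patient effect (shared by paired A/T) + noise
  pat_eff <- matrix(stats::rnorm(ng * np, 0, spec$patient_sd), ng, np)
  stoch <- matrix(stats::rnorm(ng * n_samp, 0, spec$noise_sd), ng, n_samp)
  stoch[, seq_len(np)] <- stoch[, seq_len(np)] + pat_eff
  stoch[, np + seq_len(np)] <- stoch[, np + seq_len(np)] + pat_eff

  # TF -> target coupling on the TF's stochastic deviation
  if (spec$n_tf > 0L && spec$targets_per_tf > 0L) {
    for (k in seq_len(spec$n_tf)) {
      tg <- match(tf_targets[[k]], genes)
      stoch[tg, ] <- stoch[tg, ] +
        spec$beta * matrix(stoch[k, ], length(tg), n_samp, byrow = TRUE)
    }
  }

  values <- stoch + baseline
  values[, seq_len(np)] <- values[, seq_len(np)] + off_A
  values[, np + seq_len(np)] <- values[, np + seq_len(np)] + off_T
  rownames(values) <- genes
  colnames(values) <- sample_ids

  tissue_up <- character(ng)
  tissue_up[pattern == "tumor_like" & sign_up > 0] <- "A,T"
  tissue_up[pattern == "trend" & sign_up > 0] <- "T"
  tissue_up[pattern == "adjacent_specific" & sign_up > 0] <- "A"

  truth <- structure(list(
    pattern = stats::setNames(pattern, genes),
    sign = stats::setNames(sign_up, genes),
    tissue_up = stats::setNames(tissue_up, genes),
    tf_set = tf_set,
    tf_targets = tf_targets,
    pairs = pairs,
    localization = localization
  ), class = "planted_truth")

  list(expression = expression_matrix(values, col_tissue, patient),
       truth = truth)
}

#' Generate a gene annotation table consistent with the planted truth
#'
#' Labels every gene with a transcription-factor flag and a protein
#' localization class. Planted ligands are always `secreted` and planted
#' receptors always `membrane`; the remaining genes draw their localization
#' from `spec$loc_probs`. Uses RNG substream `spec$seed + 1`.
#'
#' @param spec The [cohort_spec()] used to generate the cohort.
#' @param truth The `planted_truth` returned by [generate_expression()].
#' @return Data frame with columns `symbol`, `is_tf`, `localization`.
#' @export
generate_annotation <- function(spec, truth) {
  validate_cohort_spec(spec)
  set.seed(spec$seed + 1L)
  genes <- names(truth$pattern)
  loc <- sample(names(spec$loc_probs), length(genes), replace = TRUE,
                prob = spec$loc_probs)
  names(loc) <- genes
  loc[names(truth$localization)] <- truth$localization
  data.frame(symbol = genes,
             is_tf = genes %in% truth$tf_set,
             localization = unname(loc),
             stringsAsFactors = FALSE)
}

#' Generate an undirected interactome containing the planted pairs
#'
#' Combines the planted ligand-receptor edges with a scale-free background
#' generated by preferential attachment (`spec$background_m` edges per
#' node; 0 disables the background so the edge set equals the planted
#' pairs). Background vertices are mapped to gene symbols by a random
#' permutation. Self-loops and duplicate unordered pairs are removed. Uses
#' RNG substream `spec$seed + 2`.
#'
#' @inheritParams generate_annotation
#' @return Data frame with columns `gene_a`, `gene_b` (canonical order
#'   `gene_a < gene_b`, unique rows).
#' @export
generate_interactome <- function(spec, truth) {
  validate_cohort_spec(spec)
  set.seed(spec$seed + 2L)
  genes <- names(truth$pattern)
  edges <- if (!is.null(truth$pairs))
    data.frame(gene_a = truth$pairs$ligand, gene_b = truth$pairs$receptor,
               stringsAsFactors = FALSE)
  else data.frame(gene_a = character(0), gene_b = character(0))
  if (spec$background_m > 0L) {
    g <- igraph::sample_pa(length(genes), power = 1, m = spec$background_m,
                           directed = FALSE)
    perm <- sample(genes)
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- rbind(edges, data.frame(gene_a = perm[el[, 1]],
                                     gene_b = perm[el[, 2]],
                                     stringsAsFactors = FALSE))
  }
  canonicalize_edges(edges)
}

# undirected canonical form: gene_a < gene_b, no self-loops, no duplicates
canonicalize_edges <- function(edges) {
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  keep <- a != b & !duplicated(paste(a, b, sep = "\t"))
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
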