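#' Pipeline configuration
#'
#' Collects the inputs and thresholds for [run_pipeline()]. Exactly one of
#' `spec` (simulate a cohort) or the four input paths must be supplied.
#'
#' @param spec Optional [cohort_spec()]; when given, the cohort is
#'   simulated.
#' @param expression,metadata,annotation,interactome Input file paths (used
#'   when `spec` is `NULL`).
#' @param sd_min Low-variability filter threshold (default 0.3).
#' @param q_max DEG q-value threshold (default 0.01).
#' @param diff_min DEG minimum absolute log2 difference (default 1).
#' @param delta Pattern-classification equality tolerance (default 0.5).
#' @param n_perm Permutations for the MI threshold (default 250).
#' @param mi_alpha Per-pair false-positive rate for the MI threshold.
#' @param dpi_tolerance DPI pruning tolerance (default 0.1).
#' @param n_iter Resampling iterations for empirical p-values.
#' @param seed Integer seed for all pipeline randomness.
#' @param out_dir Optional output directory; when given, all stage outputs
#'   and a JSON summary are written there.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, expression = NULL, metadata = NULL,
                            annotation = NULL, interactome = NULL,
                            sd_min = 0.3, q_max = 0.01, diff_min = 1,
                            delta = 0.5, n_perm = 250, mi_alpha = 0.005,
                            dpi_tolerance = 0.1, n_iter = 1000, seed = 1L,
                            out_dir = NULL) {
  have_paths <- !is.null(expression) && !is.null(metadata) &&
    !is.null(annotation) && !is.null(interactome)
  if (is.null(spec) && !have_paths)
    stop("supply either 'spec' or all four input paths", call. = FALSE)
  if (!is.null(spec)) validate_cohort_spec(spec)
  stopifnot(sd_min >= 0, q_max > 0, q_max <= 1, diff_min >= 0, delta >= 0,
            dpi_tolerance >= 0, dpi_tolerance <= 1)
  structure(list(spec = spec, expression = expression, metadata = metadata,
                 annotation = annotation, interactome = interactome,
                 sd_min = sd_min, q_max = q_max, diff_min = diff_min,
                 delta = delta, n_perm = n_perm, mi_alpha = mi_alpha,
                 dpi_tolerance = dpi_tolerance, n_iter = n_iter,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

tissue_samples <- function(em, tissue) {
  em$samples$sample_id[em$samples$tissue == tissue]
}

#' Run the full tri-tissue analysis pipeline
#'
#' Executes, in order: optional cohort simulation, low-variability
#' filtering, differential expression for the A-vs-H and T-vs-H contrasts,
#' tri-tissue pattern classification of the A-vs-H DEG, transcriptional
#' network inference on the A and H sample subsets with node turnover and
#' TF ranking, and crosstalk classification of secreted/membrane DEG over
#' the interactome. Identical configuration and seed give identical output.
#'
#' @param config A [pipeline_config()].
#' @return A list bundle: `expression`, `truth` (simulated runs only),
#'   `deg_a`, `deg_t` (DEG tables), `patterns`, `pattern_summary`,
#'   `net_a`, `net_h`, `net_diff`, `tf_ranks`, `seeds`, `level0`, `pairs`,
#'   `crosstalk`, and `summary` (the JSON-ready run summary).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(spec = cohort_spec(n_patients = 10, n_healthy = 8,
#'                                           n_genes = 120, n_tf = 3,
#'                                           targets_per_tf = 5,
#'                                           n_pairs = 4, seed = 2),
#'                        n_perm = 100, seed = 2)
#' bundle <- run_pipeline(cfg)
#' bundle$summary$deg
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$spec)) {
    sim <- generate_expression(config$spec)
    em <- sim$expression
    truth <- sim$truth
    annotation <- generate_annotation(config$spec, truth)
    interactome <- generate_interactome(config$spec, truth)
  } else {
    em <- read_expression(config$expression, config$metadata)
    annotation <- read_annotation(config$annotation)
    interactome <- read_interactome(config$interactome)
    extra <- setdiff(rownames(em$values), annotation$symbol)
    if (length(extra))
      warning("genes absent from annotation: ",
              paste(utils::head(extra, 5), collapse = ", "),
              if (length(extra) > 5) " ...", call. = FALSE)
  }

  filtered <- filter_low_variability(em, config$sd_min)
  a <- tissue_samples(filtered, "A")
  t_ <- tissue_samples(filtered, "T")
  h <- tissue_samples(filtered, "H")

  deg_a <- call_deg(two_group_test(filtered, a, h),
                    q_max = config$q_max, diff_min = config$diff_min)
  deg_t <- call_deg(two_group_test(filtered, t_, h),
                    q_max = config$q_max, diff_min = config$diff_min)

  mean_h <- rowMeans(filtered$values[, h, drop = FALSE])
  mean_a <- rowMeans(filtered$values[, a, drop = FALSE])
  mean_t <- rowMeans(filtered$values[, t_, drop = FALSE])
  deg_idx <- which(deg_a$is_deg)
  patterns <- classify_pattern(mean_h[deg_idx], mean_a[deg_idx],
                               mean_t[deg_idx], delta = config$delta,
                               genes = deg_a$gene[deg_idx])

  tf_list <- intersect(annotation$symbol[annotation$is_tf],
                       rownames(filtered$values))
  em_a <- subset_expression(filtered, samples = a)
  em_h <- subset_expression(filtered, samples = h)
  net_a <- infer_network(em_a, tf_list, n_perm = config$n_perm,
                         alpha = config$mi_alpha,
                         tolerance = config$dpi_tolerance,
                         seed = config$seed)
  net_h <- infer_network(em_h, tf_list, n_perm = config$n_perm,
                         alpha = config$mi_alpha,
                         tolerance = config$dpi_tolerance,
                         seed = config$seed + 1L)
  net_diff <- compare_networks(net_a, net_h)
  deg_set <- deg_a$gene[deg_a$is_deg]
  tf_ranks <- tf_rank_table(net_a, deg_set, rownames(filtered$values),
                            reference_network = net_h,
                            n_iter = config$n_iter,
                            seed = config$seed + 2L)

  a_up <- deg_a$gene[deg_a$is_deg & deg_a$direction == "up"]
  t_up <- deg_t$gene[deg_t$is_deg & deg_t$direction == "up"]
  seeds <- select_seed_genes(a_up, t_up, annotation)
  level0 <- build_level0(seeds, interactome)
  pairs <- classify_edges(level0)
  crosstalk <- crosstalk_summary(pairs, family_prefixes = "SLIT")

  summary <- list(
    parameters = config[c("sd_min", "q_max", "diff_min", "delta", "n_perm",
                          "mi_alpha", "dpi_tolerance", "n_iter", "seed")],
    samples = list(n = ncol(em$values),
                   by_tissue = as.list(table(em$samples$tissue))),
    genes = list(input = nrow(em$values), after_filter = nrow(filtered$values)),
    deg = list(a_vs_h = sum(deg_a$is_deg), t_vs_h = sum(deg_t$is_deg),
               a_vs_h_frac_up = attr(deg_a, "frac_up")),
    patterns = stats::setNames(as.list(pattern_counts(patterns)$n),
                               pattern_counts(patterns)$class),
    networks = list(
      adjacent = list(nodes = length(net_a$nodes), edges = nrow(net_a$edges)),
      healthy = list(nodes = length(net_h$nodes), edges = nrow(net_h$edges)),
      gained = length(net_diff$gained), lost = length(net_diff$lost),
      shared = length(net_diff$shared)),
    crosstalk = c(as.list(crosstalk$direction_counts),
                  list(total = crosstalk$total,
                       level0_nodes = nrow(level0$nodes),
                       level0_edges = nrow(level0$edges),
                       seeds = nrow(seeds))))

  bundle <- list(expression = em, truth = truth, filtered = filtered,
                 annotation = annotation, interactome = interactome,
                 deg_a = deg_a, deg_t = deg_t, patterns = patterns,
                 pattern_summary = pattern_counts(patterns),
                 net_a = net_a, net_h = net_h, net_diff = net_diff,
                 tf_ranks = tf_ranks, seeds = seeds, level0 = level0,
                 pairs = pairs, crosstalk = crosstalk, summary = summary)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$out_dir
    write_expression(filtered, file.path(od, "expression_filtered.tsv"),
                     file.path(od, "metadata.tsv"))
    utils::write.table(deg_a, file.path(od, "deg_a_vs_h.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(deg_t, file.path(od, "deg_t_vs_h.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(patterns, file.path(od, "patterns.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_network(net_a, file.path(od, "network_adjacent.tsv"))
    write_network(net_h, file.path(od, "network_healthy.tsv"))
    utils::write.table(tf_ranks, file.path(od, "tf_ranks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(pairs, file.path(od, "crosstalk_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(level0, file.path(od, "level0.sif"), format = "sif")
    jsonlite::write_json(summary, file.path(od, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  bundle
}
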