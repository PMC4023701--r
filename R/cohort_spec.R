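#' Specify a synthetic tri-tissue cohort
#'
#' Builds the parameter object consumed by [generate_expression()],
#' [generate_annotation()] and [generate_interactome()]. The default cohort
#' shape mirrors a paired tumor / adjacent-mucosa design with an independent
#' healthy-donor arm: `n_patients` patients each contribute one
#' adjacent-mucosa (A) and one tumor (T) sample, and `n_healthy` donors
#' contribute one healthy-mucosa (H) sample, for `2 * n_patients + n_healthy`
#' samples in total (246 with the defaults).
#'
#' Each gene is planted in exactly one expression-pattern class. Relative to
#' the healthy baseline, a gene of class `tumor_like` is offset by
#' `effect_size` in both A and T; `trend` by half the offset in A and the
#' full offset in T; `adjacent_specific` by the full offset in A only;
#' `null` genes carry no offset. The offset sign is up with probability
#' `frac_up`, down otherwise. The first `n_tf` genes are flagged as
#' transcription factors and each drives `targets_per_tf` disjoint target
#' genes through an additive coupling `beta * (TF deviation)`, giving the
#' mutual-information network inference a recoverable signal.
#'
#' @param n_patients Number of patients; each contributes a paired A and T
#'   sample.
#' @param n_healthy Number of healthy donors (one H sample each).
#' @param n_genes Total number of genes.
#' @param n_tf Number of transcription-factor genes (the first `n_tf` genes).
#' @param targets_per_tf Targets coupled to each TF; TFs and targets are
#'   disjoint gene sets, so `n_tf * (1 + targets_per_tf) <= n_genes`.
#' @param frac_tumor_like,frac_trend,frac_adjacent_specific,frac_null
#'   Proportions of genes planted in each pattern class; must sum to 1.
#' @param effect_size Tissue offset magnitude, log2 units.
#' @param noise_sd I.i.d. Gaussian noise standard deviation, log2 units.
#' @param patient_sd Standard deviation of the per-gene, per-patient random
#'   effect shared by a patient's paired A and T samples, log2 units.
#' @param baseline_mean,baseline_sd Per-gene healthy baseline distribution,
#'   log2 units.
#' @param frac_up Probability that a planted non-null gene is up-regulated
#'   (rather than down-regulated).
#' @param beta Coupling coefficient from TF deviation to target expression.
#' @param n_pairs Number of planted ligand-receptor crosstalk pairs
#'   (half afferent, half efferent).
#' @param background_m Preferential-attachment edges added per node when
#'   generating background interactome edges; 0 means the interactome
#'   contains exactly the planted ligand-receptor edges.
#' @param loc_probs Named probabilities for the localization classes
#'   `secreted`, `membrane`, `both`, `other` assigned to genes that are not
#'   planted ligands/receptors.
#' @param seed Integer RNG seed. Generators use documented substreams:
#'   expression uses `seed`, annotation `seed + 1`, interactome `seed + 2`.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @examples
#' spec <- cohort_spec(n_patients = 6, n_healthy = 4, n_genes = 60,
#'                     n_tf = 2, targets_per_tf = 5, seed = 1)
#' spec$n_genes
#' @export
cohort_spec <- function(n_patients = 98,
                        n_healthy = 50,
                        n_genes = 2000,
                        n_tf = 20,
                        targets_per_tf = 10,
                        frac_tumor_like = 0.10,
                        frac_trend = 0.04,
                        frac_adjacent_specific = 0.11,
                        frac_null = 0.75,
                        effect_size = 2,
                        noise_sd = 0.4,
                        patient_sd = 0.3,
                        baseline_mean = 7,
                        baseline_sd = 1.5,
                        frac_up = 0.88,
                        beta = 0.8,
                        n_pairs = 20,
                        background_m = 2,
                        loc_probs = c(secreted = 0.10, membrane = 0.20,
                                      both = 0.02, other = 0.68),
                        seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients), n_healthy = as.integer(n_healthy),
    n_genes = as.integer(n_genes), n_tf = as.integer(n_tf),
    targets_per_tf = as.integer(targets_per_tf),
    frac_tumor_like = frac_tumor_like, frac_trend = frac_trend,
    frac_adjacent_specific = frac_adjacent_specific, frac_null = frac_null,
    effect_size = effect_size, noise_sd = noise_sd, patient_sd = patient_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    frac_up = frac_up, beta = beta, n_pairs = as.integer(n_pairs),
    background_m = as.integer(background_m), loc_probs = loc_probs,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  counts <- c("n_patients", "n_healthy", "n_genes")
  for (f in counts) {
    if (is.na(spec[[f]]) || spec[[f]] <= 0L)
      stop("'", f, "' must be a positive count", call. = FALSE)
  }
  if (spec$n_tf < 0L || spec$targets_per_tf < 0L || spec$n_pairs < 0L ||
      spec$background_m < 0L)
    stop("counts must be non-negative", call. = FALSE)
  fr <- c(spec$frac_tumor_like, spec$frac_trend,
          spec$frac_adjacent_specific, spec$frac_null)
  if (any(fr < 0) || any(fr > 1))
    stop("pattern proportions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("pattern proportions must sum to 1 (got ", sum(fr), ")",
         call. = FALSE)
  if (spec$n_tf * (1L + spec$targets_per_tf) > spec$n_genes)
    stop("n_tf * (1 + targets_per_tf) exceeds n_genes; TFs and their ",
         "targets must be disjoint gene sets", call. = FALSE)
  if (spec$noise_sd < 0 || spec$patient_sd < 0 || spec$baseline_sd < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (spec$frac_up < 0 || spec$frac_up > 1)
    stop("'frac_up' must lie in [0, 1]", call. = FALSE)
  lp <- spec$loc_probs
  if (!setequal(names(lp), c("secreted", "membrane", "both", "other")) ||
      any(lp < 0) || abs(sum(lp) - 1) > 1e-9)
    stop("'loc_probs' must be named probabilities over ",
         "{secreted, membrane, both, other} summing to 1", call. = FALSE)
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic tri-tissue cohort specification\n")
  cat(sprintf("  samples: %d patients (paired A/T) + %d healthy = %d\n",
              x$n_patients, x$n_healthy, 2L * x$n_patients + x$n_healthy))
  cat(sprintf("  genes: %d (%d TFs x %d targets; %d ligand-receptor pairs)\n",
              x$n_genes, x$n_tf, x$targets_per_tf, x$n_pairs))
  cat(sprintf("  patterns: tumor_like %.2f, trend %.2f, adjacent_specific %.2f, null %.2f\n",
              x$frac_tumor_like, x$frac_trend, x$frac_adjacent_specific,
              x$frac_null))
  cat(sprintf("  effect %.2f, noise sd %.2f, patient sd %.2f, seed %d\n",
              x$effect_size, x$noise_sd, x$patient_sd, x$seed))
  invisible(x)
}
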