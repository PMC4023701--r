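#' Remove low-variability genes
#'
#' Drops every gene whose across-all-samples standard deviation
#' (denominator n-1) is not strictly greater than `sd_min`. On microarray
#' data this removes mostly non-hybridized and saturated probes before
#' differential expression testing.
#'
#' @param em An [expression_matrix()].
#' @param sd_min Minimum standard deviation, log2 units; genes with
#'   `sd <= sd_min` are removed (strict inequality retained). Default 0.3.
#' @return The filtered `expression_matrix`, gene order preserved.
#' @export
filter_low_variability <- function(em, sd_min = 0.3) {
  stopifnot(inherits(em, "expression_matrix"))
  if (sd_min < 0) stop("'sd_min' must be >= 0", call. = FALSE)
  if (ncol(em$values) < 2L)
    stop("standard deviation undefined with fewer than 2 samples",
         call. = FALSE)
  sds <- row_sds(em$values)
  subset_expression(em, genes = which(sds > sd_min))
}

row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

#' Per-gene two-group differential expression test
#'
#' Tests every gene for a mean difference between two sample groups. The
#' unpaired mode is a two-sided Welch (unequal-variance) t-test; the paired
#' mode matches samples by patient id and applies a two-sided paired t-test
#' to the within-patient differences. Degenerate genes with zero variance
#' are reported with `t = 0, p = 1` when the group means agree, and
#' `p = 0` otherwise.
#'
#' @param em An [expression_matrix()].
#' @param group1,group2 Sample ids (character) defining the two groups; the
#'   reported `log2_diff` is `mean(group1) - mean(group2)`.
#' @param paired If `TRUE`, groups must be patient-matched (equal length,
#'   same patient set); the test is then on paired differences.
#' @return Data frame with one row per gene: `gene`, `mean1`, `mean2`,
#'   `log2_diff`, `t_stat`, `df`, `p_value`.
#' @examples
#' sim <- generate_expression(cohort_spec(n_patients = 6, n_healthy = 6,
#'                                        n_genes = 30, n_tf = 0,
#'                                        targets_per_tf = 0, n_pairs = 0,
#'                                        seed = 3))
#' em <- sim$expression
#' a <- em$samples$sample_id[em$samples$tissue == "A"]
#' h <- em$samples$sample_id[em$samples$tissue == "H"]
#' head(two_group_test(em, a, h))
#' @export
two_group_test <- function(em, group1, group2, paired = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  i1 <- match(group1, colnames(em$values))
  i2 <- match(group2, colnames(em$values))
  if (anyNA(i1) || anyNA(i2))
    stop("unknown sample ids in group definition", call. = FALSE)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  x1 <- em$values[, i1, drop = FALSE]
  x2 <- em$values[, i2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  diff <- m1 - m2

  if (paired) {
    p1 <- em$samples$patient_id[i1]
    p2 <- em$samples$patient_id[i2]
    if (length(i1) != length(i2) || anyNA(p1) || anyNA(p2) ||
        !setequal(p1, p2))
      stop("paired test requires patient-matched groups", call. = FALSE)
    x2 <- x2[, match(p1, p2), drop = FALSE]
    d <- x1 - x2
    n <- ncol(d)
    sd_d <- row_sds(d)
    se <- sd_d / sqrt(n)
    t_stat <- rowMeans(d) / se
    df <- rep(n - 1, nrow(d))
  } else {
    n1 <- ncol(x1); n2 <- ncol(x2)
    v1 <- row_sds(x1)^2
    v2 <- row_sds(x2)^2
    se2 <- v1 / n1 + v2 / n2
    t_stat <- diff / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs(t_stat), df)
  zero_se <- !is.finite(t_stat)
  if (any(zero_se)) {
    same <- zero_se & abs(diff) < .Machine$double.eps^0.5
    t_stat[same] <- 0; p[same] <- 1; df[same] <- NA_real_
    t_stat[zero_se & !same] <- sign(diff[zero_se & !same]) * Inf
    p[zero_se & !same] <- 0; df[zero_se & !same] <- NA_real_
  }
  data.frame(gene = rownames(em$values), mean1 = m1, mean2 = m2,
             log2_diff = diff, t_stat = t_stat, df = df, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Storey q-values
#'
#' False discovery rate q-values with the proportion of true nulls pi0
#' estimated on a lambda grid: `pi0(lambda) = mean(p > lambda)/(1 -
#' lambda)`, smoothed with a cubic smoothing spline and evaluated at the
#' largest lambda, then floored at 0 and capped at 1. With `pi0 = 1` the
#' result equals Benjamini-Hochberg adjusted p-values exactly.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda Grid for pi0 estimation (default `seq(0.05, 0.95, 0.05)`).
#' @param pi0 Optional fixed pi0 overriding the estimate (e.g. `1` for BH).
#' @return Numeric vector of q-values, in the order of `p`.
#' @examples
#' p <- c(0.001, 0.02, 0.5, 0.9)
#' qvalues(p, pi0 = 1) # identical to p.adjust(p, "BH")
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05), pi0 = NULL) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- if (length(lambda) >= 4L) {
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      stats::predict(fit, x = max(lambda))$y
    } else pi0_l[length(lambda)]
    pi0 <- min(max(pi0, 0), 1)
  }
  pmin(pi0 * stats::p.adjust(p, method = "BH"), 1)
}

#' Call differentially expressed genes
#'
#' Applies the joint significance and effect-size rule: a gene is a DEG
#' exactly when its q-value is below `q_max` and its absolute log2 mean
#' difference exceeds `diff_min`. Defaults correspond to 1% FDR and a
#' two-fold change.
#'
#' @param records Data frame from [two_group_test()].
#' @param q_max Maximum q-value (default 0.01).
#' @param diff_min Minimum absolute log2 difference (default 1).
#' @param pi0 Passed to [qvalues()] (optional).
#' @return The input with columns `q_value`, `is_deg`, `direction`
#'   (`"up"`/`"down"` by the sign of `log2_diff`) appended, plus attribute
#'   `frac_up`, the fraction of DEG that are up-regulated.
#' @export
call_deg <- function(records, q_max = 0.01, diff_min = 1, pi0 = NULL) {
  stopifnot(is.data.frame(records),
            all(c("log2_diff", "p_value") %in% names(records)))
  records$q_value <- qvalues(records$p_value, pi0 = pi0)
  records$is_deg <- records$q_value < q_max & abs(records$log2_diff) > diff_min
  records$direction <- ifelse(records$log2_diff > 0, "up", "down")
  attr(records, "frac_up") <-
    if (any(records$is_deg))
      mean(records$direction[records$is_deg] == "up")
    else NA_real_
  records
}
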