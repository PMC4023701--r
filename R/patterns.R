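#' Classify tri-tissue expression patterns
#'
#' Assigns each A-vs-H differentially expressed gene to one of three
#' patterns given its mean log2 expression in healthy mucosa (H),
#' tumor-adjacent mucosa (A) and tumor (T):
#'
#' * **tumor_like** — A behaves like T (`A = T > H` or `H > A = T`): the A
#'   and T means agree within `delta` and both deviate from H in the same
#'   direction by more than `delta`.
#' * **adjacent_specific** — A deviates from *both* H and T in the same
#'   direction by more than `delta` (A is the highest or lowest of the
#'   three), irrespective of how T relates to H.
#' * **trend** — A is intermediate (`H < A < T` or `T < A < H`) with both
#'   gaps exceeding `delta`.
#' * **unclassified** — none of the above.
#'
#' Rules are evaluated in the order tumor_like, adjacent_specific, trend, so
#' each gene receives exactly one label. Labels are invariant under adding a
#' constant to all three means, and sign-symmetric (flipping all deviations
#' around H maps `A > (T,H)` cases onto `A < (T,H)` cases).
#'
#' With `require_significance = TRUE` the `> delta` gaps must additionally
#' be supported by pairwise-contrast q-values below `q_max` (supplied via
#' `q_ah`, `q_at`, `q_th`).
#'
#' @param mean_h,mean_a,mean_t Numeric vectors of group means, log2 units.
#' @param delta Equality tolerance between group means, log2 units
#'   (default 0.5, half the DEG fold-change threshold).
#' @param require_significance Also require pairwise significance for each
#'   gap (default `FALSE`, keeping the classifier a deterministic function
#'   of the means).
#' @param q_ah,q_at,q_th Pairwise q-values for the A-H, A-T and T-H
#'   contrasts (only used when `require_significance = TRUE`).
#' @param q_max Significance threshold for the pairwise gaps.
#' @param genes Optional gene symbols for the output.
#' @return Data frame with columns `gene` (if supplied) and `class`.
#' @examples
#' classify_pattern(mean_h = c(5, 5, 5), mean_a = c(7, 6, 8),
#'                  mean_t = c(7.1, 7, 5.2))$class
#' @export
classify_pattern <- function(mean_h, mean_a, mean_t, delta = 0.5,
                             require_significance = FALSE,
                             q_ah = NULL, q_at = NULL, q_th = NULL,
                             q_max = 0.01, genes = NULL) {
  if (delta < 0) stop("'delta' must be >= 0", call. = FALSE)
  n <- length(mean_h)
  if (length(mean_a) != n || length(mean_t) != n)
    stop("mean vectors must have equal length", call. = FALSE)
  if (anyNA(mean_h) || anyNA(mean_a) || anyNA(mean_t))
    stop("missing group means", call. = FALSE)

  sig <- function(q) {
    if (!require_significance) return(rep(TRUE, n))
    if (is.null(q)) stop("require_significance = TRUE needs pairwise ",
                         "q-values", call. = FALSE)
    q < q_max
  }
  s_ah <- sig(q_ah); s_at <- sig(q_at); s_th <- sig(q_th)

  ah <- mean_a - mean_h
  at <- mean_a - mean_t
  th <- mean_t - mean_h

  gap_ah <- abs(ah) > delta & s_ah
  gap_at <- abs(at) > delta & s_at
  gap_th <- abs(th) > delta & s_th

  tumor_like <- abs(at) <= delta & gap_ah & gap_th & sign(ah) == sign(th)
  adjacent_specific <- gap_ah & gap_at & sign(ah) == sign(at)
  trend <- gap_ah & gap_at & sign(ah) == -sign(at) # H<A<T or T<A<H

  class <- rep("unclassified", n)
  class[trend] <- "trend"
  class[adjacent_specific] <- "adjacent_specific"
  class[tumor_like] <- "tumor_like"

  out <- data.frame(class = class, stringsAsFactors = FALSE)
  if (!is.null(genes)) out <- cbind(data.frame(gene = genes,
                                               stringsAsFactors = FALSE), out)
  out
}

#' Tabulate pattern-class labels
#'
#' @param labels Data frame from [classify_pattern()] (needs a `class`
#'   column).
#' @return Data frame with columns `class`, `n`, `proportion`, covering all
#'   four classes; counts sum to the number of labelled genes.
#' @export
pattern_counts <- function(labels) {
  lv <- c("tumor_like", "trend", "adjacent_specific", "unclassified")
  cl <- factor(labels$class, levels = lv)
  n <- as.vector(table(cl))
  data.frame(class = lv, n = n,
             proportion = if (sum(n) > 0) n / sum(n) else rep(0, 4),
             stringsAsFactors = FALSE)
}
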