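#' Construct a tri-tissue expression matrix
#'
#' Container for a log2 expression matrix (genes in rows, samples in
#' columns) together with per-sample tissue labels (`H`, `A` or `T`) and
#' patient identifiers that pair each patient's adjacent-mucosa (A) and
#' tumor (T) samples. Healthy (H) samples carry `NA` patient ids.
#'
#' @param values Numeric matrix, genes x samples, finite log2 values;
#'   rownames are gene symbols, colnames sample ids.
#' @param tissue Character vector, one of `"H"`, `"A"`, `"T"` per sample.
#' @param patient_id Character vector of patient ids per sample (`NA` for H
#'   samples). When both an A and a T sample are present, every A sample's
#'   patient must have a matching T sample.
#' @return An object of class `expression_matrix`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' em <- expression_matrix(m, tissue = c("A", "T", "H", "H"),
#'                         patient_id = c("P1", "P1", NA, NA))
#' dim(em$values)
#' @export
expression_matrix <- function(values, tissue, patient_id = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  tissue <- as.character(tissue)
  if (length(tissue) != ncol(values))
    stop("'tissue' must have one entry per sample", call. = FALSE)
  if (!all(tissue %in% c("H", "A", "T")))
    stop("tissue labels must be 'H', 'A' or 'T'", call. = FALSE)
  if (is.null(patient_id)) patient_id <- rep(NA_character_, ncol(values))
  patient_id <- as.character(patient_id)
  if (length(patient_id) != ncol(values))
    stop("'patient_id' must have one entry per sample", call. = FALSE)
  pa <- patient_id[tissue == "A"]
  pt <- patient_id[tissue == "T"]
  if (length(pa) && length(pt) && !all(stats::na.omit(pa) %in% pt))
    stop("paired design declared but some A samples have no matching T ",
         "sample", call. = FALSE)
  samples <- data.frame(sample_id = colnames(values), tissue = tissue,
                        patient_id = patient_id, stringsAsFactors = FALSE)
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(factor(x$samples$tissue, levels = c("H", "A", "T")))
  cat(sprintf("expression_matrix: %d genes x %d samples (H=%d, A=%d, T=%d)\n",
              nrow(x$values), ncol(x$values), tab["H"], tab["A"], tab["T"]))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param em An [expression_matrix()].
#' @param genes Gene symbols or row indices to keep (default all).
#' @param samples Sample ids or column indices to keep (default all).
#' @return The subsetted `expression_matrix`.
#' @export
subset_expression <- function(em, genes = NULL, samples = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  keep <- seq_len(ncol(v))
  if (!is.null(samples)) {
    keep <- if (is.character(samples)) match(samples, colnames(v)) else samples
    v <- v[, keep, drop = FALSE]
  }
  expression_matrix(v, em$samples$tissue[keep], em$samples$patient_id[keep])
}

#' Collapse probe-level rows to gene level
#'
#' Microarray matrices are often probe-level with several probes per gene.
#' For each gene the probe with the largest across-sample standard
#' deviation (denominator n-1) is retained, a common convention when a
#' single expression profile per gene is needed downstream.
#'
#' @param em An [expression_matrix()] whose rownames are probe ids.
#' @param probe_map Data frame with columns `probe` and `gene` mapping each
#'   probe id to a gene symbol.
#' @return An `expression_matrix` with one row per gene.
#' @export
collapse_probes <- function(em, probe_map) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!all(c("probe", "gene") %in% names(probe_map)))
    stop("'probe_map' needs columns 'probe' and 'gene'", call. = FALSE)
  idx <- match(rownames(em$values), probe_map$probe)
  if (anyNA(idx))
    stop("probes missing from 'probe_map': ",
         paste(utils::head(rownames(em$values)[is.na(idx)], 5),
               collapse = ", "), call. = FALSE)
  gene <- toupper(probe_map$gene[idx])
  sds <- apply(em$values, 1, stats::sd)
  ord <- order(gene, -sds)
  keep <- ord[!duplicated(gene[ord])]
  keep <- sort(keep)
  v <- em$values[keep, , drop = FALSE]
  rownames(v) <- gene[keep]
  expression_matrix(v, em$samples$tissue, em$samples$patient_id)
}
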