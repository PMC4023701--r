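#' Read and write expression matrices as TSV
#'
#' The expression TSV has gene symbols in the first column (`gene`) and one
#' column per sample; the metadata TSV has columns `sample_id`, `tissue`
#' (`H`/`A`/`T`) and `patient_id` (empty for healthy samples). Gene symbols
#' are uppercased on load; duplicate sample ids, duplicate or empty gene
#' symbols, and non-numeric expression cells are rejected with the
#' offending location.
#'
#' @param path Expression TSV path.
#' @param metadata_path Sample metadata TSV path.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1] != "gene")
    stop("first column of ", path, " must be 'gene'", call. = FALSE)
  genes <- toupper(tab$gene)
  if (any(genes == "")) stop("empty gene symbols in ", path, call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene symbols in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at data row ", bad[1], ", sample '",
         colnames(vals)[bad[2]], "' in ", path, call. = FALSE)
  }
  rownames(vals) <- genes
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  need <- c("sample_id", "tissue", "patient_id")
  if (!all(need %in% names(meta)))
    stop("metadata needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  idx <- match(colnames(vals), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(colnames(vals)[is.na(idx)], collapse = ", "), call. = FALSE)
  expression_matrix(vals, meta$tissue[idx],
                    as.character(meta$patient_id[idx]))
}

#' @rdname read_expression
#' @param em An [expression_matrix()] to write.
#' @export
write_expression <- function(em, path, metadata_path) {
  stopifnot(inherits(em, "expression_matrix"))
  tab <- data.frame(gene = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(em$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(path, metadata_path))
}

#' Read a gene annotation table
#'
#' TSV with columns `symbol`, `is_tf` (logical or TRUE/FALSE strings) and
#' `localization` (one of `secreted`, `membrane`, `both`, `other`).
#' Symbols are uppercased.
#'
#' @param path Annotation TSV path.
#' @return Data frame with the three columns.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("symbol", "localization") %in% names(ann)))
    stop("annotation needs columns 'symbol' and 'localization'",
         call. = FALSE)
  ann$symbol <- toupper(ann$symbol)
  bad <- setdiff(unique(ann$localization),
                 c("secreted", "membrane", "both", "other"))
  if (length(bad))
    stop("unknown localization values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(ann$is_tf)) ann$is_tf <- as.logical(ann$is_tf)
  ann
}

#' Read an undirected interactome edge list (TSV or SIF)
#'
#' TSV files need columns `gene_a` and `gene_b`; SIF files use the dialect
#' `geneA <relation> geneB` (whitespace-separated, relation ignored).
#' Symbols are uppercased; self-loops and duplicate unordered pairs are
#' removed, so re-reading a written file yields the same edge set.
#'
#' @param path Edge list path.
#' @param format `"tsv"` or `"sif"`; default guesses from the extension.
#' @return Data frame with columns `gene_a`, `gene_b` in canonical order.
#' @export
read_interactome <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
      stop("malformed SIF line(s): ", paste(utils::head(bad, 5),
                                            collapse = ", "), call. = FALSE)
    edges <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                        gene_b = vapply(parts, `[`, "", 3L),
                        stringsAsFactors = FALSE)
  } else {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b") %in% names(edges)))
      stop("interactome TSV needs columns 'gene_a' and 'gene_b'",
           call. = FALSE)
  }
  edges$gene_a <- toupper(edges$gene_a)
  edges$gene_b <- toupper(edges$gene_b)
  canonicalize_edges(edges)
}

#' Write a network to TSV, SIF or GraphML
#'
#' Accepts a `transcriptional_network`, a `ppi_network`, or a plain edge
#' data frame. TSV keeps all edge columns; SIF writes
#' `a interacts b` lines; GraphML goes through [igraph::write_graph()].
#'
#' @param network Network object or edge data frame (first two columns are
#'   node pairs).
#' @param path Output path.
#' @param format `"tsv"`, `"sif"` or `"graphml"` (default from extension).
#' @export
write_network <- function(network, path,
                          format = c("auto", "tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sif", "graphml")) ext else "tsv"
  }
  edges <- if (is.data.frame(network)) network else network$edges
  if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    writeLines(paste(edges[[1]], "interacts", edges[[2]]), path)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Write a full synthetic cohort to disk
#'
#' Writes the expression and metadata TSVs, annotation TSV, interactome TSV
#' and SIF, and the planted truth as JSON into `dir`.
#'
#' @param sim Result of [generate_expression()].
#' @param annotation Result of [generate_annotation()].
#' @param interactome Result of [generate_interactome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_cohort <- function(sim, annotation, interactome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             interactome = file.path(dir, "interactome.tsv"),
             interactome_sif = file.path(dir, "interactome.sif"),
             truth = file.path(dir, "truth.json"))
  write_expression(sim$expression, paths["expression"], paths["metadata"])
  utils::write.table(annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(interactome, paths["interactome"], format = "tsv")
  write_network(interactome, paths["interactome_sif"], format = "sif")
  truth <- sim$truth
  jsonlite::write_json(list(pattern = as.list(truth$pattern),
                            sign = as.list(truth$sign),
                            tissue_up = as.list(truth$tissue_up),
                            tf_set = truth$tf_set,
                            tf_targets = truth$tf_targets,
                            pairs = truth$pairs,
                            localization = as.list(truth$localization)),
                       paths["truth"], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}
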