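#' Packaged reference table of ranked transcription factors
#'
#' Curated table of 60 transcription factors differentially expressed
#' between tumor-adjacent and healthy colon mucosa in a colorectal field
#' cancerization cohort, with their transcriptional-network connection
#' counts, DEG connections, rank score, resampling p-value, eccentricity,
#' closeness centrality, and whether the TF also appears in the
#' healthy-mucosa network. Useful as a worked reference for
#' [tf_rank_score()].
#'
#' @return Data frame with columns `gene`, `connections`,
#'   `deg_connections`, `rank`, `p_value` (character, printed form),
#'   `eccentricity`, `closeness`, `in_healthy_network`.
#' @export
tf_reference_table <- function() {
  utils::read.delim(system.file("extdata", "table1_tfs.tsv",
                                package = "crctalk"),
                    stringsAsFactors = FALSE, check.names = TRUE)
}

#' Packaged reference table of crosstalk ligand-receptor pairs
#'
#' Curated table of 84 secreted-protein to membrane-receptor interactions
#' between tumor and adjacent mucosa in a colorectal field cancerization
#' cohort: 23 afferent (ligand secreted by adjacent mucosa, receptor on the
#' tumor membrane) and 61 efferent (the converse). Each row records the
#' tissue of over-expression of both genes as printed in its source
#' section.
#'
#' @return Data frame with columns `secreted_gene`, `secreted_tissue`,
#'   `receptor_gene`, `receptor_tissue`.
#' @export
crosstalk_reference_pairs <- function() {
  utils::read.delim(system.file("extdata", "table2_pairs.tsv",
                                package = "crctalk"),
                    stringsAsFactors = FALSE)
}

#' Run the crosstalk classifier on a reference pair table
#'
#' Encodes each row of a reference pair table (such as
#' [crosstalk_reference_pairs()]) as one protein-interaction edge whose
#' endpoints carry that row's printed localization (ligand `secreted`,
#' receptor `membrane`) and tissue labels, runs [classify_edges()] on it,
#' and concatenates the results. Row-local annotation matters because a
#' receptor may be over-expressed in different tissues in different pairs.
#'
#' @param pairs Data frame with columns `secreted_gene`, `secreted_tissue`,
#'   `receptor_gene`, `receptor_tissue`.
#' @return Data frame in the format of [classify_edges()].
#' @examples
#' \dontrun{
#' cls <- classify_reference_pairs(crosstalk_reference_pairs())
#' crosstalk_summary(cls, family_prefixes = "SLIT")
#' }
#' @export
classify_reference_pairs <- function(pairs) {
  stopifnot(all(c("secreted_gene", "secreted_tissue", "receptor_gene",
                  "receptor_tissue") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    nodes <- data.frame(
      symbol = c(pairs$secreted_gene[i], pairs$receptor_gene[i]),
      localization = c("secreted", "membrane"),
      tissue_up = c(pairs$secreted_tissue[i], pairs$receptor_tissue[i]),
      stringsAsFactors = FALSE)
    net <- structure(list(nodes = nodes,
                          edges = data.frame(
                            gene_a = pairs$secreted_gene[i],
                            gene_b = pairs$receptor_gene[i],
                            stringsAsFactors = FALSE),
                          level = 0L),
                     class = "ppi_network")
    classify_edges(net)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
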