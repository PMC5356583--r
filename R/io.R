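## Plain-text readers and writers for the pipeline's artefacts.

#' Write and read gene x sample matrices as TSV
#'
#' Genes in rows (first column `gene`), one column per sample.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `write_matrix_tsv()` returns `path` invisibly; `read_matrix_tsv()`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write a survival table as TSV
#'
#' Columns `sample`, `time`, `event` plus any covariates.
#'
#' @param survival data.frame with at least `sample`, `time`, `event`.
#' @param path output path.
#' @export
write_survival_tsv <- function(survival, path) {
  validate_survival(survival)
  write.table(survival, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  validate_survival(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a network as a TSV edge list
#'
#' For a `causal_network` the columns are `regulator`, `target`, `weight`
#' and a companion `<path>.cis.tsv` file lists the cis genes and effects;
#' for a `consensus_network` the third column is `frequency`.
#'
#' @param network a `causal_network` or `consensus_network`.
#' @param path output path for the edge list.
#' @export
write_network_tsv <- function(network, path) {
  if (inherits(network, "causal_network")) {
    write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    cis <- data.frame(gene = network$cis_genes,
                      cis_effect = unname(network$cis_effect),
                      stringsAsFactors = FALSE)
    write.table(cis, paste0(path, ".cis.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else if (inherits(network, "consensus_network")) {
    write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stop("unsupported network class", call. = FALSE)
  }
  invisible(path)
}

#' Export a consensus network to GraphML
#'
#' Node attributes carry the cis flag and optional seed / key-driver flags
#' for viewing in Cytoscape-style tools.
#'
#' @param network a `consensus_network`.
#' @param path output `.graphml` path.
#' @param seeds optional character vector flagged as seed nodes.
#' @param key_drivers optional character vector flagged as key drivers.
#' @export
write_graphml <- function(network, path, seeds = character(0),
                          key_drivers = character(0)) {
  g <- as_igraph(network)
  igraph::V(g)$seed <- as.integer(network$nodes %in% seeds)
  igraph::V(g)$key_driver <- as.integer(network$nodes %in% key_drivers)
  igraph::V(g)$cis <- as.integer(unname(network$cis[network$nodes]))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a 2-column TSV as an edge-set reference
#'
#' @param path TSV with two gene columns (header optional but expected).
#' @param name label for the collection.
#' @return a `reference_collection` of kind `"edge_set"`.
#' @export
read_edge_reference_tsv <- function(path, name = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  reference_edge_set(df[, 1:2], name = name)
}
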