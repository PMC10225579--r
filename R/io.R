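# Readers and writers for the pipeline's plain-text exchange formats:
# counts TSV (first column `gene_id`), metadata TSV (`sample_id`,
# `condition`), annotation TSV (`gene_id`, `biotype`), network JSON and SIF.

#' Read a gene-by-sample count matrix from TSV
#'
#' @param path TSV with header; first column `gene_id`, remaining columns
#'   one per sample.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column of a counts TSV must be `gene_id`", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "numeric"
  check_counts(m)
  m
}

#' Write a count or expression matrix to TSV
#'
#' @param m Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_counts_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, condition) from TSV
#'
#' @param path TSV with header columns `sample_id` and `condition`.
#' @return Data frame with those two columns.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(df))) {
    stop("metadata TSV needs columns `sample_id` and `condition`", call. = FALSE)
  }
  df
}

#' Read a gene annotation table (gene_id, biotype) from TSV
#'
#' @param path TSV with header columns `gene_id` and `biotype`.
#' @return Data frame with those two columns.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "biotype") %in% names(df))) {
    stop("annotation TSV needs columns `gene_id` and `biotype`", call. = FALSE)
  }
  df
}

#' Write a differential co-expression network to JSON
#'
#' Serialises the retained pairs, DCLs, DCG table, gene universe and
#' thresholds, so networks from different datasets can be compared later
#' with [pairwise_ami()].
#'
#' @param network A [diffcoexp_network()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "diffcoexp_network"))
  payload <- list(genes = network$genes,
                  n1 = network$n1, n2 = network$n2,
                  thresholds = network$thresholds,
                  pairs = network$pairs[, c("gene_i", "gene_j", "r1", "r2",
                                            "coexp_1", "coexp_2")],
                  n_pairs_tested = attr(network$pairs, "n_pairs_tested"),
                  dcls = as.data.frame(network$dcls)[, intersect(
                    c("gene_i", "gene_j", "r1", "p1", "r2", "p2", "z_stat",
                      "p_diff", "q_diff", "dcl_class"), names(network$dcls))],
                  dcgs = network$dcgs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a differential co-expression network from JSON
#'
#' @param path A file written by [write_network_json()].
#' @return A [diffcoexp_network()]-classed object (sufficient for
#'   comparison and reporting; correlation matrices are not stored).
#' @export
read_network_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(x) if (is.data.frame(x)) x else as.data.frame(x)
  pairs <- as_df(p$pairs)
  attr(pairs, "n_pairs_tested") <- p$n_pairs_tested
  dcls <- as_df(p$dcls)
  dcgs <- as_df(p$dcgs)
  structure(list(pairs = pairs, dcls = dcls, dcgs = dcgs,
                 genes = p$genes,
                 nodes = sort(unique(c(dcls$gene_i, dcls$gene_j))),
                 n1 = p$n1, n2 = p$n2, thresholds = p$thresholds),
            class = "diffcoexp_network")
}

#' Write a network edge list in SIF format
#'
#' Simple interaction format (`gene_i <TAB> relation <TAB> gene_j`), readable
#' by common graph tools; the relation is the DCL class.
#'
#' @param network A [diffcoexp_network()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_network_sif <- function(network, path) {
  stopifnot(inherits(network, "diffcoexp_network"))
  d <- network$dcls
  lines <- if (nrow(d) > 0) paste(d$gene_i, d$dcl_class, d$gene_j, sep = "\t") else character(0)
  writeLines(lines, path)
  invisible(path)
}
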