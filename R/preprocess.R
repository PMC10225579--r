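#' Counts-per-million normalisation
#'
#' Scales every sample (column) to a library size of one million:
#' `cpm_gs = counts_gs / sum_g(counts_gs) * 1e6`. Column sums of the result
#' equal `1e6` exactly (up to floating-point error). Library sizes are always
#' recomputed from the matrix as given, so CPM after a gene filter reflects
#' the retained genes.
#'
#' @param counts Non-negative numeric matrix, genes x samples, with dimnames.
#' @return Numeric matrix of the same shape, tagged `transform = "cpm"` and
#'   with a provenance record (see [provenance()]).
#' @export
cpm_normalize <- function(counts) {
  check_counts(counts)
  depth <- colSums(counts)
  if (any(depth == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[depth == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(counts, 2, depth, "/") * 1e6
  attr(out, "transform") <- "cpm"
  attr(out, "provenance") <- attr(counts, "provenance")
  add_provenance(out, "cpm_normalize")
}

#' Remove transcripts below the global average of reads
#'
#' Computes each gene's total count across samples, `T_g`, and the global
#' average `A = mean(T_g)`; genes with `T_g < A` are removed (strict "less
#' than": genes at exactly the average are retained).
#'
#' @param counts Counts matrix, genes x samples.
#' @return The filtered matrix; the provenance record stores the cutoff `A`
#'   and the number of genes removed.
#' @export
filter_transcripts_global_average <- function(counts) {
  check_counts(counts)
  if (nrow(counts) == 0) stop("empty count matrix", call. = FALSE)
  totals <- rowSums(counts)
  a <- mean(totals)
  keep <- totals >= a
  out <- counts[keep, , drop = FALSE]
  attr(out, "transform") <- attr(counts, "transform")
  attr(out, "provenance") <- attr(counts, "provenance")
  add_provenance(out, "filter_transcripts_global_average",
                 list(global_average = a, removed = sum(!keep)))
}

#' Remove samples with insufficient sequencing depth
#'
#' Drops samples whose total read count is strictly below `min_reads`
#' (default ten million reads, the usual floor for co-expression work).
#' The filter acts on raw counts; CPM columns all sum to `1e6` by
#' construction and carry no depth information.
#'
#' @param counts Counts matrix, genes x samples.
#' @param min_reads Minimum column total to keep a sample.
#' @return The filtered matrix; dropped sample ids are messaged and recorded
#'   in provenance.
#' @export
filter_samples_by_depth <- function(counts, min_reads = 1e7) {
  check_counts(counts)
  depth <- colSums(counts)
  keep <- depth >= min_reads
  if (!any(keep)) {
    stop("all samples fall below min_reads = ", format(min_reads), call. = FALSE)
  }
  dropped <- colnames(counts)[!keep]
  if (length(dropped) > 0) {
    message("filter_samples_by_depth: dropping ", length(dropped), " sample(s): ",
            paste(dropped, collapse = ", "))
  }
  out <- counts[, keep, drop = FALSE]
  attr(out, "transform") <- attr(counts, "transform")
  attr(out, "provenance") <- attr(counts, "provenance")
  add_provenance(out, "filter_samples_by_depth",
                 list(min_reads = min_reads, dropped = dropped))
}

#' Restrict a count matrix to selected gene biotypes
#'
#' @param counts Counts matrix, genes x samples.
#' @param annotation Data frame with columns `gene_id` and `biotype`. Genes
#'   absent from the table resolve to the sentinel biotype `"unannotated"`.
#' @param keep Character vector of biotypes to retain
#'   (default `"protein_coding"`).
#' @return The filtered matrix (provenance records the kept biotypes).
#' @export
filter_by_biotype <- function(counts, annotation, keep = "protein_coding") {
  check_counts(counts)
  stopifnot(is.data.frame(annotation), all(c("gene_id", "biotype") %in% names(annotation)))
  biotype <- annotation$biotype[match(rownames(counts), annotation$gene_id)]
  biotype[is.na(biotype)] <- "unannotated"
  keep_gene <- biotype %in% keep
  if (!any(keep_gene)) {
    stop("no genes left after biotype filter (keep = ",
         paste(keep, collapse = ", "), ")", call. = FALSE)
  }
  out <- counts[keep_gene, , drop = FALSE]
  attr(out, "transform") <- attr(counts, "transform")
  attr(out, "provenance") <- attr(counts, "provenance")
  add_provenance(out, "filter_by_biotype",
                 list(keep = keep, removed = sum(!keep_gene)))
}

#' Variance-stabilising transform: log2(CPM + 1)
#'
#' Correlation-based network analysis assumes roughly homoskedastic inputs;
#' raw counts have variance growing with the mean. `log2(CPM + 1)` is the
#' standard variance stabiliser used here; the transform tag in provenance
#' makes it swappable.
#'
#' @param counts Counts matrix, genes x samples.
#' @return Numeric matrix of `log2(cpm + 1)` values, tagged
#'   `transform = "log2cpm1"`.
#' @export
vst <- function(counts) {
  out <- log2(cpm_normalize(counts) + 1)
  attr(out, "transform") <- "log2cpm1"
  add_provenance(out, "vst", list(formula = "log2(cpm + 1)"))
}
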