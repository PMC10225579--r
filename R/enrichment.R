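#' Read a gene-set collection from a GMT file
#'
#' GMT is the standard tab-separated gene-set exchange format: one set per
#' line as `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate member
#' genes within a set are removed; case is preserved.
#'
#' @param path Path to a GMT file.
#' @return Object of class `"gene_set_collection"`: list with `sets` (named
#'   list of character vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    name <- fields[1]
    if (name %in% names(sets)) stop("duplicate gene-set name: ", name, call. = FALSE)
    sets[[name]] <- unique(fields[-(1:2)])
    descriptions[name] <- fields[2]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A `"gene_set_collection"` (see [read_gmt()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d set(s), median size %g\n",
              length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else 0))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set `S` (intersected with the universe), the overlap
#' `k = |query and S|` is tested against
#' `X ~ Hypergeometric(N = |universe|, K = |S and universe|, n = |query|)`
#' with the upper-tail p-value `P(X >= k)`; p-values are BH-adjusted across
#' sets. The universe should be the genes that entered the analysis stage
#' the query came from, not the whole genome.
#'
#' @param query Character vector of query genes (deduplicated; genes outside
#'   the universe are dropped with a warning).
#' @param universe Character vector of background genes.
#' @param collection A `"gene_set_collection"` ([read_gmt()]) or a named
#'   list of character vectors.
#' @param q_threshold BH q-value threshold for the `significant` flag
#'   (default 0.05).
#' @return Object of class `"ora_result"`: data frame with one row per set:
#'   `set`, `description`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, `significant`, `genes` (overlap genes,
#'   comma-separated), ordered by `p`.
#' @export
ora_hypergeom <- function(query, universe, collection, q_threshold = 0.05) {
  if (is.list(collection) && !inherits(collection, "gene_set_collection")) {
    collection <- structure(list(sets = collection,
                                 descriptions = stats::setNames(rep("", length(collection)),
                                                                names(collection))),
                            class = "gene_set_collection")
  }
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(query) == 0) stop("empty query", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning("dropping ", length(outside), " query gene(s) outside the universe")
    query <- intersect(query, universe)
    if (length(query) == 0) stop("no query genes left within the universe", call. = FALSE)
  }
  n_univ <- length(universe)
  n_query <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, m = length(s), n = n_univ - length(s),
                       k = n_query, lower.tail = FALSE)
    data.frame(set = nm,
               description = unname(collection$descriptions[nm]),
               overlap = k, set_size = length(s),
               query_size = n_query, universe_size = n_univ,
               p = p,
               genes = paste(sort(intersect(query, s)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(0), description = character(0),
                      overlap = integer(0), set_size = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p = numeric(0), genes = character(0))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= q_threshold
  out <- out[order(out$p, out$set), c("set", "description", "overlap", "set_size",
                                      "query_size", "universe_size", "p", "q",
                                      "significant", "genes")]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("Over-representation analysis: %d set(s), %d significant\n",
              nrow(x), sum(x$significant)))
  show <- x[, c("set", "overlap", "set_size", "p", "q", "significant")]
  print(utils::head(as.data.frame(show), 10), row.names = FALSE)
  invisible(x)
}
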