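#' Edge labelings of differential networks over a shared pair universe
#'
#' To compare differential co-expression networks from different datasets,
#' each network is reduced to a binary labeling of a common universe of gene
#' pairs: the union over networks of all retained (tested) pairs, restricted
#' to genes present in every dataset. A pair is labeled 1 in a network iff
#' it is a DCL there; a pair tested only elsewhere is labeled 0.
#'
#' @param networks List (>= 2, ideally named) of [diffcoexp_network()]
#'   objects.
#' @return Named list of objects of class `"edge_labeling"`: each a list
#'   with `universe` (character pair keys `"i|j"`, shared and ordered) and
#'   `labels` (integer 0/1 per pair).
#' @export
build_edge_labelings <- function(networks) {
  stopifnot(length(networks) >= 2)
  lapply(networks, function(n) stopifnot(inherits(n, "diffcoexp_network")))
  shared_genes <- Reduce(intersect, lapply(networks, function(n) n$genes))
  if (length(shared_genes) == 0) stop("no genes shared by all networks", call. = FALSE)
  restrict <- function(df) {
    df[df$gene_i %in% shared_genes & df$gene_j %in% shared_genes, , drop = FALSE]
  }
  universe <- sort(unique(unlist(lapply(networks, function(n) {
    p <- restrict(n$pairs)
    pair_key(p$gene_i, p$gene_j)
  }))))
  if (length(universe) == 0) stop("empty pair universe over the shared genes", call. = FALSE)
  out <- lapply(networks, function(n) {
    d <- restrict(n$dcls)
    dcl_keys <- if (nrow(d) > 0) pair_key(d$gene_i, d$gene_j) else character(0)
    structure(list(universe = universe,
                   labels = as.integer(universe %in% dcl_keys)),
              class = "edge_labeling")
  })
  names(out) <- names(networks)
  out
}

# Exact expected mutual information under the permutation (hypergeometric)
# model, from the marginals of a contingency table. Natural-log units.
expected_mutual_information <- function(a_counts, b_counts, n) {
  emi <- 0
  for (ai in a_counts) {
    for (bj in b_counts) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      log_p <- lgamma(ai + 1) - lgamma(nij + 1) - lgamma(ai - nij + 1) +
        lgamma(n - ai + 1) - lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1) -
        (lgamma(n + 1) - lgamma(bj + 1) - lgamma(n - bj + 1))
      term <- nij / n * log(n * nij / (ai * bj))
      emi <- emi + sum(exp(log_p) * term)
    }
  }
  emi
}

# Shannon entropy (nats) of a label vector's counts.
label_entropy <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Adjusted mutual information between two labelings
#'
#' `AMI = (MI - E[MI]) / (mean(H_a, H_b) - E[MI])`, with the expected mutual
#' information computed exactly under the permutation model of the
#' contingency table. AMI is 1 for identical (non-constant) labelings,
#' approximately 0 for independent ones, and invariant to label renaming.
#'
#' @param a,b Two labelings: either equal-length atomic vectors, or two
#'   `"edge_labeling"` objects over the same universe.
#' @return A single number (practically in `[0, 1]`; small negative values
#'   can occur for anti-correlated labelings). If both labelings are
#'   constant the AMI is defined as 0 with a warning.
#' @export
adjusted_mutual_information <- function(a, b) {
  if (inherits(a, "edge_labeling") || inherits(b, "edge_labeling")) {
    stopifnot(inherits(a, "edge_labeling"), inherits(b, "edge_labeling"))
    if (!identical(a$universe, b$universe)) {
      stop("edge labelings must share the same pair universe", call. = FALSE)
    }
    a <- a$labels
    b <- b$labels
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  n <- length(a)
  tab <- table(a, b)
  a_counts <- rowSums(tab)
  b_counts <- colSums(tab)
  if (length(a_counts) == 1 && length(b_counts) == 1) {
    warning("both labelings are constant; AMI defined as 0")
    return(0)
  }
  h_a <- label_entropy(a_counts, n)
  h_b <- label_entropy(b_counts, n)
  nz <- tab > 0
  mi <- sum((tab[nz] / n) * log(n * tab[nz] / outer(a_counts, b_counts)[nz]))
  emi <- expected_mutual_information(a_counts, b_counts, n)
  denom <- mean(c(h_a, h_b)) - emi
  if (abs(denom) < 1e-15) {
    # degenerate normaliser (e.g. one labeling constant): no chance-corrected
    # agreement can be claimed
    return(0)
  }
  (mi - emi) / denom
}

#' Gene community labels from the connected components of a DCL network
#'
#' Alternative clustering view for network comparison: each gene is labeled
#' by the connected component of the differential-link graph it belongs to
#' (component ids ordered by their smallest member gene), or 0 when it
#' touches no DCL.
#'
#' @param network A [diffcoexp_network()] object.
#' @param genes Gene universe over which to emit labels.
#' @return Integer vector of component labels, one per `genes` entry.
#' @export
gene_community_labels <- function(network, genes) {
  stopifnot(inherits(network, "diffcoexp_network"))
  parent <- stats::setNames(genes, genes)
  find <- function(g) {
    while (parent[[g]] != g) {
      parent[[g]] <<- parent[[parent[[g]]]]
      g <- parent[[g]]
    }
    g
  }
  d <- network$dcls
  for (k in seq_len(nrow(d))) {
    gi <- d$gene_i[k]; gj <- d$gene_j[k]
    if (gi %in% genes && gj %in% genes) parent[[find(gi)]] <- find(gj)
  }
  root <- vapply(genes, find, character(1))
  in_dcl <- genes %in% c(d$gene_i, d$gene_j)
  labels <- integer(length(genes))
  comp_roots <- unique(root[in_dcl])
  comp_roots <- comp_roots[order(comp_roots)]
  labels[in_dcl] <- match(root[in_dcl], comp_roots)
  labels
}

#' Pairwise AMI comparison of differential networks
#'
#' Computes the adjusted mutual information between every pair of networks,
#' plus the genes incident to at least one DCL in both networks of each
#' pair. Two comparison modes exist: `"edges"` (default) compares binary
#' DCL labelings of the shared tested-pair universe; `"communities"`
#' compares gene labelings by connected components of each network's DCL
#' graph over the shared genes.
#'
#' @param networks Named list (>= 2) of [diffcoexp_network()] objects.
#' @param mode `"edges"` or `"communities"`.
#' @return Object of class `"network_comparison"`: list with `ami`
#'   (symmetric matrix, unit diagonal), `mode` and `shared_dcl_genes`
#'   (named list, one character vector per unordered pair `"x|y"`).
#' @export
pairwise_ami <- function(networks, mode = c("edges", "communities")) {
  stopifnot(length(networks) >= 2)
  mode <- match.arg(mode)
  if (is.null(names(networks)) || anyDuplicated(names(networks))) {
    names(networks) <- paste0("net", seq_along(networks))
  }
  if (mode == "edges") {
    labelings <- build_edge_labelings(networks)
  } else {
    shared_genes <- Reduce(intersect, lapply(networks, function(n) n$genes))
    if (length(shared_genes) == 0) stop("no genes shared by all networks", call. = FALSE)
    labelings <- lapply(networks, gene_community_labels, genes = shared_genes)
  }
  k <- length(networks)
  ami <- diag(1, k)
  dimnames(ami) <- list(names(networks), names(networks))
  shared <- list()
  dcl_genes <- lapply(networks, function(n) sort(unique(c(n$dcls$gene_i, n$dcls$gene_j))))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      val <- adjusted_mutual_information(labelings[[i]], labelings[[j]])
      ami[i, j] <- ami[j, i] <- val
      shared[[paste(names(networks)[i], names(networks)[j], sep = "|")]] <-
        intersect(dcl_genes[[i]], dcl_genes[[j]])
    }
  }
  structure(list(ami = ami, mode = mode, shared_dcl_genes = shared),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("Pairwise adjusted mutual information between differential networks:\n")
  print(round(x$ami, 3))
  invisible(x)
}
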