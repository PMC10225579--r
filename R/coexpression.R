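#' Unsupervised gene filter based on the inverse-gamma distribution
#'
#' Fits an inverse-gamma distribution to the per-gene sample variances by
#' maximum likelihood and keeps genes whose variance is improbably large
#' under that fit. If `V ~ InvGamma(shape, scale)` then `1/V ~ Gamma(shape,
#' rate = scale)`, so the fit is performed as a gamma MLE on the reciprocal
#' variances; a gene's p-value is the upper-tail probability
#' `P(V >= v) = P(1/V <= 1/v)` of its observed variance.
#'
#' @param expr Expression matrix, genes x samples (>= 2 samples).
#' @param p_threshold Keep genes with upper-tail `p <= p_threshold`
#'   (default 0.1). `p_threshold = 1` keeps every gene.
#' @return Character vector of retained gene ids, with the per-gene p-values
#'   attached as attribute `"p"` (named, all genes).
#' @export
filter_genes_invgamma <- function(expr, p_threshold = 0.1) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2) stop("need >= 2 samples to estimate variances", call. = FALSE)
  check_param(p_threshold >= 0 && p_threshold <= 1, "p_threshold", "must lie in [0, 1]")
  v <- row_variances(expr)
  if (stats::var(v) == 0) {
    stop("all gene variances are equal; the inverse-gamma filter is not ",
         "informative here - skip filtering instead", call. = FALSE)
  }
  if (any(v <= 0)) {
    # zero-variance genes cannot carry correlation signal; give them p = 1
    pos <- v > 0
  } else {
    pos <- rep(TRUE, length(v))
  }
  fit <- fitdistrplus::fitdist(1 / v[pos], "gamma", method = "mle")
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  p <- rep(1, length(v))
  p[pos] <- stats::pgamma(1 / v[pos], shape = shape, rate = rate)
  names(p) <- rownames(expr)
  keep <- rownames(expr)[p <= p_threshold]
  attr(keep, "p") <- p
  attr(keep, "fit") <- c(shape = shape, rate = rate)
  keep
}

#' Weighted (unsigned) co-expression adjacency
#'
#' `a_gh = |cor(g, h)|^beta` with unit diagonal. Soft thresholding with the
#' power `beta` suppresses weak correlations smoothly instead of cutting at a
#' hard threshold.
#'
#' @param expr Expression matrix, genes x samples.
#' @param beta Integer soft-threshold power (>= 1).
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @return Symmetric numeric matrix with entries in `[0, 1]` and unit
#'   diagonal. Genes with zero variance get zero adjacency to all others
#'   (with a warning).
#' @export
adjacency_matrix <- function(expr, beta, method = c("pearson", "spearman")) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2)
  check_param(length(beta) == 1 && beta >= 1, "beta", "must be a power >= 1")
  method <- match.arg(method)
  v <- row_variances(expr)
  r <- suppressWarnings(stats::cor(t(expr), method = method))
  if (any(v == 0)) {
    warning("gene(s) with zero variance: ",
            paste(rownames(expr)[v == 0], collapse = ", "),
            "; their correlations are set to 0")
    r[v == 0, ] <- 0
    r[, v == 0] <- 0
  }
  a <- abs(r)^beta
  diag(a) <- 1
  a <- (a + t(a)) / 2
  a
}

#' Topological overlap similarity
#'
#' `TOM_gh = (L_gh + a_gh) / (min(k_g, k_h) + 1 - a_gh)` where
#' `L_gh = sum_{u != g,h} a_gu * a_uh` counts shared neighbours and
#' `k_g = sum_{u != g} a_gu` is connectivity; `TOM_gg = 1`. Two genes are
#' topologically similar when they are connected to each other *and* share
#' neighbours, which makes `1 - TOM` a robust clustering dissimilarity.
#'
#' @param adj Symmetric adjacency matrix with entries in `[0, 1]` and unit
#'   diagonal (as produced by [adjacency_matrix()]).
#' @return Symmetric matrix of topological overlap values in `[0, 1]`.
#' @export
tom_similarity <- function(adj) {
  stopifnot(is.matrix(adj))
  if (max(abs(adj - t(adj))) > 1e-8) stop("adjacency must be symmetric", call. = FALSE)
  if (min(adj) < -1e-12 || max(adj) > 1 + 1e-12) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(diag(adj) - 1)) > 1e-12) stop("adjacency must have unit diagonal", call. = FALSE)
  k <- rowSums(adj) - 1
  # (A^2)_gh includes u = g and u = h terms (a_gg = a_hh = 1), each equal a_gh
  l <- adj %*% adj - 2 * adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  tom
}

# Scale-free topology fit of a connectivity vector: bin k, regress
# log10(frequency) on log10(mean k) and return the signed R^2 (negated when
# the slope is positive, so positive slopes can never satisfy the criterion).
# A fit is only considered valid when at least `min_occupied` bins are
# occupied: a connectivity histogram collapsed onto a few clusters (e.g.
# module genes vs background) can produce a spuriously high R^2 from 3-4
# points while the network is nothing like scale-free.
scale_free_fit <- function(k, n_bins = 10, min_occupied = 6) {
  k <- k[k > 0]
  if (length(k) < 3 || stats::var(k) == 0) {
    return(list(r_squared = NA_real_, slope = NA_real_, n_bins_occupied = 0L))
  }
  cut_pts <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = cut_pts, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  ok <- !is.na(dk) & freq > 0 & dk > 0
  if (sum(ok) < min_occupied) {
    return(list(r_squared = NA_real_, slope = NA_real_,
                n_bins_occupied = as.integer(sum(ok))))
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(r_squared = if (slope > 0) -r2 else r2, slope = slope,
       n_bins_occupied = as.integer(sum(ok)))
}

#' Automatic soft-threshold power selection
#'
#' For each candidate power the unsigned adjacency and its connectivity
#' distribution are computed; the scale-free topology fit `R^2` is the
#' goodness of a linear fit of `log10 p(k)` against `log10 k` over
#' connectivity bins, with the sign convention that a positive log-log slope
#' negates `R^2`. The selected `beta` is the smallest power whose signed
#' `R^2` reaches `r2_target`; if none does, the power with the largest
#' signed `R^2` is returned with `criterion_met = FALSE`. A fit counts only
#' when at least 6 of the 10 connectivity bins are occupied: histograms
#' collapsed onto a few clusters give meaninglessly high `R^2` from a
#' handful of points (recorded as `NA` in the fit table, with the occupancy
#' in `n_bins_occupied`).
#'
#' @param expr Expression matrix, genes x samples (>= 3 genes).
#' @param betas Candidate integer powers (default `1:20`).
#' @param r2_target Scale-free fit target (default 0.8).
#' @param method Correlation method passed to [adjacency_matrix()].
#' @return An object of class `"soft_threshold"`: list with `beta`,
#'   `criterion_met` and `fit_table` (one row per candidate: signed `R^2`,
#'   slope, mean and median connectivity).
#' @export
select_soft_threshold <- function(expr, betas = 1:20, r2_target = 0.8,
                                  method = c("pearson", "spearman")) {
  stopifnot(is.matrix(expr), nrow(expr) >= 3)
  method <- match.arg(method)
  a1 <- adjacency_matrix(expr, beta = 1, method = method)
  fit_table <- do.call(rbind, lapply(betas, function(b) {
    a <- a1^b
    diag(a) <- 1
    k <- rowSums(a) - 1
    f <- scale_free_fit(k)
    data.frame(beta = b, r_squared = f$r_squared, slope = f$slope,
               n_bins_occupied = f$n_bins_occupied,
               mean_k = mean(k), median_k = stats::median(k))
  }))
  ok <- !is.na(fit_table$r_squared) & fit_table$r_squared >= r2_target
  if (any(ok)) {
    beta <- fit_table$beta[which(ok)[1]]
    criterion_met <- TRUE
  } else if (all(is.na(fit_table$r_squared))) {
    beta <- betas[1]
    criterion_met <- FALSE
  } else {
    beta <- fit_table$beta[which.max(fit_table$r_squared)]
    criterion_met <- FALSE
  }
  structure(list(beta = beta, criterion_met = criterion_met, fit_table = fit_table,
                 r2_target = r2_target),
            class = "soft_threshold")
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat(sprintf("Soft-threshold selection: beta = %d (criterion %s, target R^2 = %g)\n",
              x$beta, if (x$criterion_met) "met" else "NOT met", x$r2_target))
  invisible(x)
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Genes are clustered by average-linkage hierarchical clustering of the
#' dissimilarity `1 - TOM`, and branches with at least `min_module_size`
#' members become modules. The dendrogram is cut adaptively: among all cut
#' positions at or below `cut_height` (merges above that ceiling join
#' effectively uncorrelated branches), the cut that yields the largest
#' number of min-size branches is chosen, ties resolving to the highest
#' cut. Genes outside every module branch get label 0 ("not correlated").
#' Labels 1..K are assigned in decreasing module size. The cut is
#' deterministic: the assignment is a pure function of the TOM and the two
#' parameters.
#'
#' @param tom Topological overlap matrix ([tom_similarity()]).
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height Ceiling on the `1 - TOM` dissimilarity scale (default
#'   0.99): genes whose branches join above it are treated as uncorrelated.
#' @return An object of class `"module_assignment"`: list with
#'   `module_of_gene` (named integer vector, 0 = unassigned), `module_sizes`
#'   (named integer vector over labels 1..K) and `n_modules`.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  stopifnot(is.matrix(tom), !is.null(rownames(tom)))
  genes <- rownames(tom)
  n <- length(genes)
  module_of_gene <- stats::setNames(integer(n), genes)
  if (n >= 2 && n >= min_module_size) {
    hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
    # candidate cuts: just below each merge at or under the ceiling, plus
    # the ceiling itself; keep the cut yielding the most min-size branches
    # (ties -> highest cut, so weakly attached genes stay assigned)
    hts <- sort(unique(hc$height))
    candidates <- c(cut_height, hts[hts <= cut_height] - 1e-10)
    best_raw <- NULL
    best <- c(count = -1, h = -Inf)
    for (h in candidates) {
      raw <- stats::cutree(hc, h = h)
      count <- sum(table(raw) >= min_module_size)
      if (count > best["count"] ||
          (count == best["count"] && h > best["h"])) {
        best <- c(count = count, h = h)
        best_raw <- raw
      }
    }
    raw <- best_raw
    sizes <- table(raw)
    big <- names(sizes)[sizes >= min_module_size]
    # order kept clusters by decreasing size, ties by first member's position
    if (length(big) > 0) {
      first_member <- vapply(big, function(b) which(raw == as.integer(b))[1], integer(1))
      ord <- big[order(-sizes[big], first_member)]
      for (i in seq_along(ord)) {
        module_of_gene[raw == as.integer(ord[i])] <- i
      }
    }
  }
  labs <- sort(unique(module_of_gene[module_of_gene > 0]))
  module_sizes <- stats::setNames(
    vapply(labs, function(l) sum(module_of_gene == l), integer(1)),
    labs)
  structure(list(module_of_gene = module_of_gene,
                 module_sizes = module_sizes,
                 n_modules = length(labs),
                 min_module_size = min_module_size,
                 cut_height = cut_height),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("Module assignment: %d module(s) over %d genes (%d unassigned)\n",
              x$n_modules, length(x$module_of_gene), sum(x$module_of_gene == 0)))
  if (x$n_modules > 0) {
    cat("  sizes:", paste(sprintf("M%s=%d", names(x$module_sizes), x$module_sizes),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hub genes by intramodular connectivity
#'
#' Within each module, genes are ranked by their intramodular connectivity
#' `k_within(g) = sum of adjacency to other module members`; the top
#' `n_hubs` per module are the module's hubs. Ties break lexicographically
#' by gene id.
#'
#' @param adj Adjacency matrix over the module genes ([adjacency_matrix()]).
#' @param modules A [detect_modules()] result covering the adjacency's genes.
#' @param n_hubs Hubs per module (default 5); a module smaller than `n_hubs`
#'   returns all members, ranked.
#' @return Named list (one element per module label) of data frames with
#'   columns `gene_id` and `k_within`, in rank order.
#' @export
find_hubs <- function(adj, modules, n_hubs = 5) {
  stopifnot(inherits(modules, "module_assignment"))
  mog <- modules$module_of_gene
  if (!all(rownames(adj) %in% names(mog))) {
    stop("module assignment does not cover all genes in the adjacency", call. = FALSE)
  }
  labs <- sort(unique(mog[mog > 0]))
  hubs <- lapply(labs, function(l) {
    members <- names(mog)[mog == l]
    members <- members[members %in% rownames(adj)]
    sub <- adj[members, members, drop = FALSE]
    k_within <- rowSums(sub) - 1
    ord <- order(-k_within, members)
    top <- ord[seq_len(min(n_hubs, length(members)))]
    data.frame(gene_id = members[top], k_within = unname(k_within[top]))
  })
  names(hubs) <- labs
  hubs
}

#' Full per-group co-expression analysis
#'
#' Chains the co-expression stages on a count matrix: variance-stabilising
#' transform, optional inverse-gamma gene filter, automatic soft-threshold
#' selection, adjacency, topological overlap, module detection and hub
#' identification.
#'
#' @param counts Counts matrix, genes x samples.
#' @param filter_p Upper-tail threshold for [filter_genes_invgamma()], or
#'   `NULL` to skip the variance filter (e.g. when the gene set was already
#'   curated).
#' @param beta Soft-threshold power; `NULL` (default) selects it
#'   automatically via [select_soft_threshold()].
#' @param betas,r2_target Candidate grid and target for the automatic
#'   selection.
#' @param min_module_size,cut_height Passed to [detect_modules()].
#' @param n_hubs Hubs per module ([find_hubs()]).
#' @param method Correlation method.
#' @return An object of class `"coexpression_result"`: list with `genes`
#'   (analysed gene ids), `soft_threshold`, `beta`, `modules`, `hubs`,
#'   `adjacency` and `tom`.
#' @export
coexpression_analysis <- function(counts, filter_p = 0.1, beta = NULL,
                                  betas = 1:20, r2_target = 0.8,
                                  min_module_size = 30, cut_height = 0.99,
                                  n_hubs = 5,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  expr <- vst(counts)
  if (!is.null(filter_p) && filter_p < 1) {
    keep <- filter_genes_invgamma(expr, p_threshold = filter_p)
    if (length(keep) < max(10, min_module_size)) {
      warning("inverse-gamma filter at p <= ", filter_p, " keeps only ",
              length(keep), " gene(s); skipping the filter")
    } else {
      expr <- expr[keep, , drop = FALSE]
    }
  }
  st <- NULL
  if (is.null(beta)) {
    st <- select_soft_threshold(expr, betas = betas, r2_target = r2_target, method = method)
    beta <- st$beta
  }
  adj <- adjacency_matrix(expr, beta = beta, method = method)
  tom <- tom_similarity(adj)
  modules <- detect_modules(tom, min_module_size = min_module_size, cut_height = cut_height)
  hubs <- find_hubs(adj, modules, n_hubs = n_hubs)
  structure(list(genes = rownames(expr), soft_threshold = st, beta = beta,
                 modules = modules, hubs = hubs, adjacency = adj, tom = tom),
            class = "coexpression_result")
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat(sprintf("Co-expression analysis of %d genes (beta = %d)\n",
              length(x$genes), x$beta))
  print(x$modules)
  n_hub <- sum(vapply(x$hubs, nrow, integer(1)))
  cat(sprintf("  hubs: %d across %d module(s)\n", n_hub, length(x$hubs)))
  invisible(x)
}

#' Bootstrap stability of module detection
#'
#' Reruns the full co-expression chain `n_reps` times on random subsamples
#' (without replacement) of `sample_fraction` of the samples, and summarises
#' how stable the module structure is: the distribution of the detected
#' module count, the frequency of the modal count ("accuracy"), per-rank
#' module sizes, and how often each gene appears as a hub.
#'
#' @param counts Counts matrix, genes x samples.
#' @param sample_fraction Fraction of samples per replicate (default 0.7).
#' @param n_reps Replicates (default 100).
#' @param seed Integer seed; replicates use named sub-streams.
#' @param ... Passed to [coexpression_analysis()] (e.g. `filter_p`,
#'   `min_module_size`).
#' @return Object of class `"stability_report"`: list with `n_reps`,
#'   `sample_fraction`, `module_counts` (per-replicate counts),
#'   `module_count_distribution` (named frequencies summing to 1),
#'   `modal_count`, `modal_count_accuracy`, `module_size_mean_sd` (per rank)
#'   and `hub_recovery` (named fraction of replicates each gene was a hub).
#' @export
module_stability <- function(counts, sample_fraction = 0.7, n_reps = 100,
                             seed = 1L, ...) {
  check_counts(counts)
  n <- ncol(counts)
  m <- floor(sample_fraction * n)
  if (m < 4) stop("sample_fraction too small: floor(fraction * n) must be >= 4", call. = FALSE)
  module_counts <- integer(n_reps)
  size_by_rank <- list()
  hub_hits <- stats::setNames(numeric(nrow(counts)), rownames(counts))
  for (i in seq_len(n_reps)) {
    idx <- with_substream(seed, sprintf("module-stability-rep%d", i), sample.int(n, m))
    res <- coexpression_analysis(counts[, idx, drop = FALSE], ...)
    module_counts[i] <- res$modules$n_modules
    sizes <- sort(res$modules$module_sizes, decreasing = TRUE)
    for (r in seq_along(sizes)) {
      size_by_rank[[r]] <- c(if (r <= length(size_by_rank)) size_by_rank[[r]], sizes[r])
    }
    rep_hubs <- unique(unlist(lapply(res$hubs, function(h) h$gene_id)))
    hub_hits[rep_hubs] <- hub_hits[rep_hubs] + 1
  }
  dist <- table(module_counts) / n_reps
  modal <- as.integer(names(dist)[which.max(dist)])
  size_stats <- if (length(size_by_rank) > 0) {
    data.frame(rank = seq_along(size_by_rank),
               mean = vapply(size_by_rank, mean, numeric(1)),
               sd = vapply(size_by_rank, function(s) if (length(s) > 1) stats::sd(s) else NA_real_,
                           numeric(1)),
               n_obs = vapply(size_by_rank, length, integer(1)))
  } else {
    data.frame(rank = integer(0), mean = numeric(0), sd = numeric(0), n_obs = integer(0))
  }
  structure(list(n_reps = n_reps, sample_fraction = sample_fraction,
                 module_counts = module_counts,
                 module_count_distribution = dist,
                 modal_count = modal,
                 modal_count_accuracy = max(dist),
                 module_size_mean_sd = size_stats,
                 hub_recovery = hub_hits / n_reps),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Module stability over %d subsamples at %.0f%% of samples\n",
              x$n_reps, 100 * x$sample_fraction))
  cat(sprintf("  modal module count: %d (accuracy %.2f)\n",
              x$modal_count, x$modal_count_accuracy))
  if (nrow(x$module_size_mean_sd) > 0) {
    with(x$module_size_mean_sd,
         cat("  sizes by rank:",
             paste(sprintf("M%d %.1f (+/-%.1f)", rank, mean, sd), collapse = ", "), "\n"))
  }
  invisible(x)
}
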