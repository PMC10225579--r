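#' Split an expression matrix by condition
#'
#' Builds the two-condition container consumed by the differential
#' co-expression functions: the same genes, restricted per condition.
#'
#' @param expr Expression matrix, genes x samples (typically [vst()] output).
#' @param condition Factor-like vector with exactly two levels, one label per
#'   sample; the first level is "condition 1".
#' @return Object of class `"conditioned_expression"`: list with `expr1`,
#'   `expr2`, `n1`, `n2`, `levels`.
#' @export
conditioned_expression <- function(expr, condition) {
  stopifnot(is.matrix(expr))
  condition <- check_condition(condition, expr)
  if (nlevels(condition) != 2) {
    stop("`condition` must have exactly two levels, got ", nlevels(condition), call. = FALSE)
  }
  n <- table(condition)
  if (any(n < 4)) stop("each condition needs >= 4 samples (Fisher-Z requires n - 3 > 0)", call. = FALSE)
  structure(list(expr1 = expr[, condition == levels(condition)[1], drop = FALSE],
                 expr2 = expr[, condition == levels(condition)[2], drop = FALSE],
                 n1 = unname(n[1]), n2 = unname(n[2]),
                 levels = levels(condition)),
            class = "conditioned_expression")
}

#' @export
print.conditioned_expression <- function(x, ...) {
  cat(sprintf("Two-condition expression: %d genes; %s n=%d, %s n=%d\n",
              nrow(x$expr1), x$levels[1], x$n1, x$levels[2], x$n2))
  invisible(x)
}

#' All pairwise gene-gene correlations with p-values
#'
#' Pearson (or Spearman) correlation for every gene pair, with the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom; `|r| = 1` gives `p = 0`. Zero-variance genes get `r = 0`,
#' `p = 1` with a warning.
#'
#' @param expr Expression matrix, genes x samples (>= 4 samples).
#' @param method `"pearson"` (default) or `"spearman"` (same t
#'   approximation).
#' @return List with symmetric matrices `r` and `p`.
#' @export
pairwise_correlations <- function(expr, method = c("pearson", "spearman")) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2)
  method <- match.arg(method)
  n <- ncol(expr)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  v <- row_variances(expr)
  r <- suppressWarnings(stats::cor(t(expr), method = method))
  if (any(v == 0)) {
    warning("zero-variance gene(s): ", paste(rownames(expr)[v == 0], collapse = ", "),
            "; r set to 0, p to 1")
    r[v == 0, ] <- 0
    r[, v == 0] <- 0
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0
  zero <- v == 0
  p[zero, ] <- 1
  p[, zero] <- 1
  diag(p) <- 0
  list(r = r, p = p)
}

#' Gene pairs co-expressed in at least one condition
#'
#' Per condition, all pairwise correlation p-values are Benjamini-Hochberg
#' adjusted; a pair is co-expressed in a condition iff `|r| >= rth` and
#' `q <= q_coexp`. Pairs co-expressed in at least one condition are
#' retained, with a per-condition flag. Only these retained pairs enter the
#' differential test.
#'
#' @param cond A [conditioned_expression()] object.
#' @param rth Correlation magnitude threshold (default 0.5).
#' @param q_coexp BH q-value threshold per condition (default 0.1).
#' @param method Correlation method.
#' @return Data frame with one row per retained pair: `gene_i`, `gene_j`
#'   (with `gene_i < gene_j` in the matrix gene order), `r1`, `p1`, `q1`,
#'   `r2`, `p2`, `q2`, `coexp_1`, `coexp_2`. The total number of tested
#'   pairs is attached as attribute `"n_pairs_tested"`.
#' @export
coexpressed_pairs <- function(cond, rth = 0.5, q_coexp = 0.1,
                              method = c("pearson", "spearman")) {
  stopifnot(inherits(cond, "conditioned_expression"))
  method <- match.arg(method)
  genes <- rownames(cond$expr1)
  pc1 <- pairwise_correlations(cond$expr1, method = method)
  pc2 <- pairwise_correlations(cond$expr2, method = method)
  ut <- upper.tri(pc1$r)
  idx <- which(ut, arr.ind = TRUE)
  r1 <- pc1$r[ut]; p1 <- pc1$p[ut]
  r2 <- pc2$r[ut]; p2 <- pc2$p[ut]
  q1 <- stats::p.adjust(p1, method = "BH")
  q2 <- stats::p.adjust(p2, method = "BH")
  coexp_1 <- abs(r1) >= rth & q1 <= q_coexp
  coexp_2 <- abs(r2) >= rth & q2 <= q_coexp
  keep <- coexp_1 | coexp_2
  out <- data.frame(gene_i = genes[idx[keep, 1]],
                    gene_j = genes[idx[keep, 2]],
                    r1 = r1[keep], p1 = p1[keep], q1 = q1[keep],
                    r2 = r2[keep], p2 = p2[keep], q2 = q2[keep],
                    coexp_1 = coexp_1[keep], coexp_2 = coexp_2[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_pairs_tested") <- sum(ut)
  attr(out, "thresholds") <- list(rth = rth, q_coexp = q_coexp)
  out
}

#' Fisher's Z test for a difference between two correlations
#'
#' `z_k = atanh(r_k)` is approximately normal with variance `1/(n_k - 3)`;
#' the difference statistic is
#' `z = (z_1 - z_2) / sqrt(1/(n_1 - 3) + 1/(n_2 - 3))` with a two-sided
#' standard-normal p-value. Correlations at exactly `+/-1` are clamped to
#' `+/-(1 - 1e-15)` to keep the statistic finite while preserving ordering.
#'
#' @param r1,r2 Sample correlations (vectorised), `|r| <= 1`.
#' @param n1,n2 Sample sizes (> 3).
#' @return Data frame with columns `z_stat` and `p_diff`.
#' @export
fisher_z_diff_test <- function(r1, n1, r2, n2) {
  if (any(c(n1, n2) <= 3)) stop("Fisher-Z requires n > 3 in both conditions", call. = FALSE)
  if (any(abs(c(r1, r2)) > 1 + 1e-12)) stop("|r| must be <= 1", call. = FALSE)
  clamp <- function(r) sign(r) * pmin(abs(r), 1 - 1e-15)
  z1 <- atanh(clamp(r1))
  z2 <- atanh(clamp(r2))
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (z1 - z2) / se
  data.frame(z_stat = z, p_diff = 2 * stats::pnorm(-abs(z)))
}

#' Call differentially co-expressed links (DCLs)
#'
#' Applies [fisher_z_diff_test()] to every retained co-expressed pair,
#' BH-adjusts over the retained pairs only (they are the tested family), and
#' calls a pair a DCL iff `q_diff <= q_dcl`. Each DCL is classified by
#' [classify_dcl()].
#'
#' @param pairs Output of [coexpressed_pairs()].
#' @param cond The [conditioned_expression()] the pairs came from (provides
#'   `n1`, `n2`).
#' @param q_dcl BH q-value threshold (default 0.1).
#' @return Data frame of called DCLs (subset of `pairs` plus `z_stat`,
#'   `p_diff`, `q_diff`, `dcl_class`). The full tested table is attached as
#'   attribute `"tested"`.
#' @export
call_dcls <- function(pairs, cond, q_dcl = 0.1) {
  stopifnot(inherits(cond, "conditioned_expression"))
  if (nrow(pairs) == 0) {
    out <- cbind(pairs, z_stat = numeric(0), p_diff = numeric(0),
                 q_diff = numeric(0), dcl_class = character(0))
    attr(out, "tested") <- out
    return(out)
  }
  ft <- fisher_z_diff_test(pairs$r1, cond$n1, pairs$r2, cond$n2)
  tested <- cbind(pairs, ft)
  tested$q_diff <- stats::p.adjust(tested$p_diff, method = "BH")
  dcl <- tested[tested$q_diff <= q_dcl, , drop = FALSE]
  dcl$dcl_class <- classify_dcl(dcl$r1, dcl$r2, dcl$coexp_1, dcl$coexp_2)
  rownames(dcl) <- NULL
  attr(dcl, "tested") <- tested
  attr(dcl, "n_pairs_tested") <- attr(pairs, "n_pairs_tested")
  dcl
}

#' Classify a differentially co-expressed link
#'
#' Convention: a DCL co-expressed in both conditions is `same-signed` when
#' the two correlations share a sign and `switched-opposite` when they do
#' not; a DCL co-expressed in exactly one condition is `diff-signed`.
#'
#' @param r1,r2 Per-condition correlations (vectorised).
#' @param coexp_1,coexp_2 Per-condition co-expression flags.
#' @return Character vector of class labels.
#' @export
classify_dcl <- function(r1, r2, coexp_1, coexp_2) {
  if (any(!coexp_1 & !coexp_2)) {
    stop("a DCL must be co-expressed in at least one condition", call. = FALSE)
  }
  ifelse(coexp_1 & coexp_2,
         ifelse(sign(r1) == sign(r2), "same-signed", "switched-opposite"),
         "diff-signed")
}

#' Call differentially co-expressed genes (DCGs) with a binomial model
#'
#' Under the null, a gene's incident retained pairs each become a DCL
#' independently with the global rate `p_hat = (total DCLs)/(total retained
#' pairs)`. A gene with `n_links` incident retained pairs and `n_dcls`
#' incident DCLs gets the binomial upper-tail p-value
#' `P(X >= n_dcls), X ~ Binomial(n_links, p_hat)`, BH-adjusted over all
#' genes with at least one link; DCG iff `q_binom <= q_dcg`.
#'
#' @param dcls Called DCLs ([call_dcls()]).
#' @param pairs Retained pairs ([coexpressed_pairs()]).
#' @param q_dcg BH q-value threshold (default 0.1).
#' @return Data frame with one row per gene with `n_links >= 1`: `gene`,
#'   `n_links`, `n_dcls`, `p_binom`, `q_binom`, `dcg` (logical).
#' @export
call_dcgs <- function(dcls, pairs, q_dcg = 0.1) {
  if (nrow(pairs) == 0) stop("zero retained pairs: nothing to test", call. = FALSE)
  p_hat <- nrow(dcls) / nrow(pairs)
  genes <- sort(unique(c(pairs$gene_i, pairs$gene_j)))
  n_links <- vapply(genes, function(g) sum(pairs$gene_i == g | pairs$gene_j == g), numeric(1))
  n_dcls <- vapply(genes, function(g) {
    if (nrow(dcls) == 0) 0 else sum(dcls$gene_i == g | dcls$gene_j == g)
  }, numeric(1))
  p_binom <- stats::pbinom(n_dcls - 1, size = n_links, prob = p_hat, lower.tail = FALSE)
  out <- data.frame(gene = genes, n_links = as.integer(n_links),
                    n_dcls = as.integer(n_dcls), p_binom = p_binom,
                    q_binom = stats::p.adjust(p_binom, method = "BH"),
                    stringsAsFactors = FALSE)
  out$dcg <- out$q_binom <= q_dcg
  attr(out, "p_hat") <- p_hat
  rownames(out) <- NULL
  out
}

#' Build a differential co-expression network
#'
#' Convenience wrapper chaining [coexpressed_pairs()], [call_dcls()] and
#' [call_dcgs()] into the network object consumed by the comparison and
#' reporting stages.
#'
#' @param cond A [conditioned_expression()] object (or pass `expr` +
#'   `condition` to [conditioned_expression()] first).
#' @param rth,q_coexp,q_dcl,q_dcg Stage thresholds (see the stage functions).
#' @param method Correlation method.
#' @return Object of class `"diffcoexp_network"`: list with `pairs`
#'   (retained co-expressed pairs), `dcls`, `dcgs` (full gene table with
#'   `dcg` flag), `genes` (all genes tested), `nodes` (genes touched by
#'   DCLs) and `thresholds`.
#' @export
diffcoexp_network <- function(cond, rth = 0.5, q_coexp = 0.1, q_dcl = 0.1,
                              q_dcg = 0.1, method = c("pearson", "spearman")) {
  stopifnot(inherits(cond, "conditioned_expression"))
  method <- match.arg(method)
  pairs <- coexpressed_pairs(cond, rth = rth, q_coexp = q_coexp, method = method)
  dcls <- call_dcls(pairs, cond, q_dcl = q_dcl)
  dcgs <- if (nrow(pairs) > 0) call_dcgs(dcls, pairs, q_dcg = q_dcg) else
    data.frame(gene = character(0), n_links = integer(0), n_dcls = integer(0),
               p_binom = numeric(0), q_binom = numeric(0), dcg = logical(0))
  structure(list(pairs = pairs, dcls = dcls, dcgs = dcgs,
                 genes = rownames(cond$expr1),
                 nodes = sort(unique(c(dcls$gene_i, dcls$gene_j))),
                 n1 = cond$n1, n2 = cond$n2,
                 thresholds = list(rth = rth, q_coexp = q_coexp,
                                   q_dcl = q_dcl, q_dcg = q_dcg)),
            class = "diffcoexp_network")
}

#' @export
print.diffcoexp_network <- function(x, ...) {
  cat(sprintf("Differential co-expression network: %d node(s), %d DCL(s), %d DCG(s)\n",
              length(x$nodes), nrow(x$dcls), sum(x$dcgs$dcg)))
  cat(sprintf("  retained co-expressed pairs: %d (of %d tested); n1=%d, n2=%d\n",
              nrow(x$pairs), attr(x$pairs, "n_pairs_tested"), x$n1, x$n2))
  invisible(x)
}

#' @export
summary.diffcoexp_network <- function(object, ...) {
  print(object)
  if (nrow(object$dcls) > 0) {
    cat("  DCL classes:", paste(sprintf("%s=%d", names(table(object$dcls$dcl_class)),
                                        table(object$dcls$dcl_class)), collapse = ", "), "\n")
  }
  top <- object$dcgs[object$dcgs$dcg, , drop = FALSE]
  if (nrow(top) > 0) {
    top <- top[order(top$p_binom), , drop = FALSE]
    cat("  top DCGs:\n")
    print(utils::head(top, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Resampling stability of DCG calls
#'
#' Subsamples each condition's samples independently (without replacement)
#' at `sample_fraction`, reruns the whole DCL/DCG chain, and reports per
#' gene the fraction of replicates in which it was called a DCG.
#'
#' @param cond A [conditioned_expression()] object.
#' @param sample_fraction Fraction per condition (default 0.7).
#' @param n_reps Replicates (default 100).
#' @param seed Integer seed.
#' @param joint If `TRUE`, subsample the pooled sample set instead of each
#'   condition independently (does not preserve the group ratio).
#' @param ... Passed to [diffcoexp_network()] (thresholds, method).
#' @return Named numeric vector over all genes: DCG recovery fraction.
#' @export
dcg_stability <- function(cond, sample_fraction = 0.7, n_reps = 100, seed = 1L,
                          joint = FALSE, ...) {
  stopifnot(inherits(cond, "conditioned_expression"))
  m1 <- floor(sample_fraction * cond$n1)
  m2 <- floor(sample_fraction * cond$n2)
  if (min(m1, m2) < 4) stop("resampled group sizes must be >= 4", call. = FALSE)
  hits <- stats::setNames(numeric(nrow(cond$expr1)), rownames(cond$expr1))
  for (i in seq_len(n_reps)) {
    sub <- with_substream(seed, sprintf("dcg-stability-rep%d", i), {
      if (joint) {
        n <- cond$n1 + cond$n2
        m <- floor(sample_fraction * n)
        idx <- sort(sample.int(n, m))
        i1 <- idx[idx <= cond$n1]
        i2 <- idx[idx > cond$n1] - cond$n1
        if (length(i1) < 4 || length(i2) < 4) NULL else list(i1 = i1, i2 = i2)
      } else {
        list(i1 = sample.int(cond$n1, m1), i2 = sample.int(cond$n2, m2))
      }
    })
    if (is.null(sub)) next
    sub_cond <- structure(list(expr1 = cond$expr1[, sub$i1, drop = FALSE],
                               expr2 = cond$expr2[, sub$i2, drop = FALSE],
                               n1 = length(sub$i1), n2 = length(sub$i2),
                               levels = cond$levels),
                          class = "conditioned_expression")
    net <- diffcoexp_network(sub_cond, ...)
    called <- net$dcgs$gene[net$dcgs$dcg]
    hits[called] <- hits[called] + 1
  }
  hits / n_reps
}
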