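# Internal helpers shared across the pipeline stages.

#' Derive a deterministic sub-stream seed
#'
#' All randomness in the package flows from one top-level seed; each stage or
#' replicate derives its own seed from that seed plus a string tag, so that
#' e.g. adding genes to the generator or reordering pipeline stages does not
#' perturb unrelated draws.
#'
#' @param seed Integer master seed.
#' @param tag Character tag naming the sub-stream.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @keywords internal
substream_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps results in integer range
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded from (seed, tag); restores the
# caller's RNG state afterwards.
with_substream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, tag))
  expr
}

# Parameter validation that names the offending field.
check_param <- function(ok, field, message) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid parameter `%s`: %s", field, message), call. = FALSE)
  }
  invisible(TRUE)
}

# Validate a counts matrix: non-negative finite numeric matrix with unique
# row (gene) and column (sample) names.
check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("`counts` must have unique rownames (gene ids)", call. = FALSE)
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("`counts` must have unique colnames (sample ids)", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must be finite and non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

# Validate a condition vector against a matrix's samples; returns a factor
# with exactly two levels in order of first appearance unless already a factor.
check_condition <- function(condition, counts) {
  if (length(condition) != ncol(counts)) {
    stop("`condition` must have one label per sample", call. = FALSE)
  }
  if (anyNA(condition)) stop("`condition` contains missing labels", call. = FALSE)
  if (!is.factor(condition)) condition <- factor(condition, levels = unique(condition))
  condition
}

# Append a provenance record (step name + parameters) to a matrix attribute.
add_provenance <- function(x, step, params = list()) {
  prov <- attr(x, "provenance")
  if (is.null(prov)) prov <- list()
  prov[[length(prov) + 1L]] <- list(step = step, params = params)
  attr(x, "provenance") <- prov
  x
}

#' Retrieve the provenance trail of a matrix
#'
#' Filters and transforms in this package record themselves (with their
#' parameters) on the object they return; this accessor reads the trail back.
#'
#' @param x A matrix returned by a `dcnet` preprocessing function.
#' @return A list of `list(step =, params =)` records, oldest first.
#' @export
provenance <- function(x) {
  prov <- attr(x, "provenance")
  if (is.null(prov)) list() else prov
}

# Canonical "i|j" key for an unordered gene pair, with lexicographically
# smaller id first, so the same pair always maps to the same key.
pair_key <- function(gene_i, gene_j) {
  a <- pmin(gene_i, gene_j)
  b <- pmax(gene_i, gene_j)
  paste(a, b, sep = "|")
}

# Per-gene sample variances of an expression matrix (genes x samples).
row_variances <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("at least 2 samples are required to compute variances", call. = FALSE)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}
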