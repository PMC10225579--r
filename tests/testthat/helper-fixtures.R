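# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately use different code paths than the implementation.

toy_counts <- function(values, n_genes, n_samples) {
  m <- matrix(values, n_genes, n_samples)
  rownames(m) <- sprintf("g%d", seq_len(n_genes))
  colnames(m) <- sprintf("s%d", seq_len(n_samples))
  m
}

random_counts <- function(n_genes, n_samples, seed = 1, lambda = 50) {
  set.seed(seed)
  toy_counts(rpois(n_genes * n_samples, lambda), n_genes, n_samples)
}

# Independent Benjamini-Hochberg implementation (step-up, written from the
# definition rather than via p.adjust).
bh_ref <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running_min <- 1
  for (i in n:1) {
    val <- p[ord[i]] * n / i
    running_min <- min(running_min, val)
    q[ord[i]] <- running_min
  }
  pmin(q, 1)
}

# Reference AMI via scikit-learn (pre-installed python on PATH).
ref_ami_python <- function(a, b) {
  code <- sprintf(
    "from sklearn.metrics import adjusted_mutual_info_score as f; print(repr(f([%s],[%s])))",
    paste(a, collapse = ","), paste(b, collapse = ","))
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  as.numeric(gsub("np.float64\\(|\\)", "", out))
}

# Brute-force triple-loop topological overlap (independent of the matrix
# algebra used by the implementation).
tom_ref <- function(adj) {
  n <- nrow(adj)
  out <- diag(1, n)
  for (g in seq_len(n)) {
    for (h in seq_len(n)) {
      if (g == h) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != g && u != h) l <- l + adj[g, u] * adj[u, h]
      }
      k_g <- sum(adj[g, -g])
      k_h <- sum(adj[h, -h])
      out[g, h] <- (l + adj[g, h]) / (min(k_g, k_h) + 1 - adj[g, h])
    }
  }
  dimnames(out) <- dimnames(adj)
  out
}

# Exhaustive pairwise AUC oracle (ties counted 1/2).
auc_ref <- function(scores, labels) {
  pos <- which(as.logical(labels))
  neg <- which(!as.logical(labels))
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# Exhaustive hypergeometric upper tail via binomial coefficients.
hyper_tail_ref <- function(k, set_size, universe_size, query_size) {
  support <- max(0, query_size + set_size - universe_size):min(set_size, query_size)
  support <- support[support >= k]
  sum(choose(set_size, support) * choose(universe_size - set_size, query_size - support)) /
    choose(universe_size, query_size)
}

# Minimal stand-in differential network for the comparison module.
fake_network <- function(genes, pairs_i, pairs_j, dcl_idx) {
  pairs <- data.frame(gene_i = pairs_i, gene_j = pairs_j,
                      r1 = 0.8, r2 = 0, coexp_1 = TRUE, coexp_2 = FALSE,
                      stringsAsFactors = FALSE)
  dcls <- pairs[dcl_idx, , drop = FALSE]
  structure(list(pairs = pairs, dcls = dcls,
                 dcgs = data.frame(gene = character(0), n_links = integer(0),
                                   n_dcls = integer(0), p_binom = numeric(0),
                                   q_binom = numeric(0), dcg = logical(0)),
                 genes = genes,
                 nodes = sort(unique(c(dcls$gene_i, dcls$gene_j))),
                 n1 = 10, n2 = 10,
                 thresholds = list(rth = 0.5, q_coexp = 0.1, q_dcl = 0.1, q_dcg = 0.1)),
            class = "diffcoexp_network")
}

# Two centred vectors with exact sample correlation r.
exact_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n); x <- (x - mean(x)) / sd(x)
  z <- rnorm(n); z <- residuals(lm(z ~ x)); z <- z / sd(z)
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}
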