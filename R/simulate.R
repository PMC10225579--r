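#' Simulation parameters for two-condition count data with planted structure
#'
#' Bundles and validates the parameters of [generate_dataset()]. The generator
#' emulates the design of a two-group bulk RNA-seq study: negative-binomial
#' counts with log-normal library-size variation, latent-factor co-expression
#' modules shared by both conditions, and planted gene pairs whose true
#' correlation differs between conditions.
#'
#' @param n_genes Total number of genes.
#' @param n_samples_per_condition Integer vector `c(n1, n2)`, samples per
#'   condition. Both must be at least 4 (the Fisher-Z test needs `n - 3 > 0`).
#' @param module_sizes Integer vector of planted module sizes; modules occupy
#'   the first `sum(module_sizes)` genes, remaining genes are background.
#' @param within_module_cor Target Pearson correlation `rho` in `[0, 1)`
#'   between genes of the same module on the latent log scale.
#' @param planted_pairs `NULL` or a data frame with columns `gene_i`, `gene_j`
#'   (integer gene indices), `r1`, `r2` (true correlations per condition,
#'   `|r| < 1`). By default planted genes must be background genes so that
#'   module recovery and differential-pair recovery stay independent.
#' @param nb_dispersion Negative-binomial dispersion `alpha`
#'   (`Var = mu + alpha * mu^2`); `0` gives Poisson counts.
#' @param mean_log_expression Mean of the natural-log expression scale.
#' @param library_size_log_sd Standard deviation of log library-size factors.
#' @param n_unexpressed Number of "unexpressed" decoy genes (baseline shifted
#'   down by 6 natural-log units, i.e. ~400-fold), appended as the last genes.
#'   They emulate the near-zero transcripts that abundance filters remove in
#'   real data; modules and planted pairs never use them.
#' @param seed Integer master seed; all draws derive from it via named
#'   sub-streams, so regeneration is bit-identical.
#' @param allow_module_overlap If `TRUE`, planted pairs may reuse module genes
#'   (their module signal is overwritten).
#' @return A validated list of class `"sim_params"`.
#' @seealso [generate_dataset()], [planted_star()]
#' @export
sim_params <- function(n_genes = 200L,
                       n_samples_per_condition = c(100L, 100L),
                       module_sizes = c(50L, 50L),
                       within_module_cor = 0.85,
                       planted_pairs = NULL,
                       nb_dispersion = 0.1,
                       mean_log_expression = 6,
                       library_size_log_sd = 0.2,
                       n_unexpressed = 0L,
                       seed = 1L,
                       allow_module_overlap = FALSE) {
  check_param(length(n_genes) == 1 && n_genes >= 1, "n_genes", "must be a positive count")
  check_param(length(n_samples_per_condition) == 2 && all(n_samples_per_condition >= 4),
              "n_samples_per_condition", "needs two counts, each >= 4 (Fisher-Z requires n - 3 > 0)")
  check_param(length(module_sizes) == 0 || all(module_sizes >= 1),
              "module_sizes", "sizes must be positive")
  check_param(length(n_unexpressed) == 1 && n_unexpressed >= 0 && n_unexpressed < n_genes,
              "n_unexpressed", "must be a count below n_genes")
  check_param(sum(module_sizes) <= n_genes - n_unexpressed, "module_sizes",
              sprintf("sum(module_sizes) = %d exceeds the %d expressed genes",
                      sum(module_sizes), n_genes - n_unexpressed))
  check_param(length(within_module_cor) == 1 && within_module_cor >= 0 && within_module_cor < 1,
              "within_module_cor", "must lie in [0, 1)")
  check_param(nb_dispersion >= 0, "nb_dispersion", "must be non-negative")
  check_param(library_size_log_sd >= 0, "library_size_log_sd", "must be non-negative")
  check_param(length(seed) == 1 && is.finite(seed), "seed", "must be a single integer")

  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    need <- c("gene_i", "gene_j", "r1", "r2")
    check_param(all(need %in% names(planted_pairs)), "planted_pairs",
                "needs columns gene_i, gene_j, r1, r2")
    check_param(all(planted_pairs$gene_i >= 1 & planted_pairs$gene_i <= n_genes - n_unexpressed &
                    planted_pairs$gene_j >= 1 & planted_pairs$gene_j <= n_genes - n_unexpressed),
                "planted_pairs", "gene indices out of range (decoy genes cannot be planted)")
    check_param(all(planted_pairs$gene_i != planted_pairs$gene_j), "planted_pairs",
                "a gene cannot be paired with itself")
    check_param(all(abs(planted_pairs$r1) < 1 & abs(planted_pairs$r2) < 1),
                "planted_pairs", "|r| must be < 1")
    if (!allow_module_overlap && sum(module_sizes) > 0) {
      in_module <- c(planted_pairs$gene_i, planted_pairs$gene_j) <= sum(module_sizes)
      check_param(!any(in_module), "planted_pairs",
                  "planted genes must be background genes (set allow_module_overlap = TRUE to override)")
    }
  }

  structure(list(
    n_genes = as.integer(n_genes),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    module_sizes = as.integer(module_sizes),
    within_module_cor = within_module_cor,
    planted_pairs = planted_pairs,
    nb_dispersion = nb_dispersion,
    mean_log_expression = mean_log_expression,
    library_size_log_sd = library_size_log_sd,
    n_unexpressed = as.integer(n_unexpressed),
    seed = as.integer(seed),
    allow_module_overlap = allow_module_overlap
  ), class = "sim_params")
}

#' Build a star of planted differential pairs around one hub gene
#'
#' Convenience constructor for `planted_pairs`: pairs `(hub, partner)` for each
#' partner, all with the same per-condition correlations. A hub with many
#' differential links is the planted analogue of a differentially co-expressed
#' gene (DCG).
#'
#' @param hub Integer index of the hub gene.
#' @param partners Integer indices of the partner genes.
#' @param r1,r2 True correlation of every pair in condition 1 and 2.
#' @return A data frame suitable for the `planted_pairs` field of [sim_params()].
#' @export
planted_star <- function(hub, partners, r1, r2) {
  data.frame(gene_i = rep(as.integer(hub), length(partners)),
             gene_j = as.integer(partners), r1 = r1, r2 = r2)
}

#' Generate a two-condition count matrix with planted structure
#'
#' Latent-factor construction: for module `m` and sample `s` a factor
#' `f_ms ~ N(0,1)` is drawn; gene `g` in module `m` has log-scale signal
#' `x_gs = sqrt(rho) * f_ms + sqrt(1 - rho) * eps_gs` with `eps ~ N(0,1)`,
#' which gives every within-module gene pair true correlation `rho`.
#' Background genes have `x ~ N(0,1)`. Planted differential pairs override
#' this: the second gene of a pair is rebuilt as
#' `r_c * x_i + sqrt(1 - r_c^2) * eps_j` per condition `c`, so the pair has
#' true correlation `r1` in condition 1 and `r2` in condition 2 (pairs may
#' share genes, e.g. a star, as long as they form no cycle). Counts are
#' `NB(mu = L_s * exp(mean_log_expression + x_gs), dispersion)` with
#' `log L_s ~ N(0, library_size_log_sd)`.
#'
#' Every gene, module factor, library-size vector and count draw uses its own
#' named sub-stream of the master seed, so the same seed reproduces the data
#' bit for bit and adding genes does not perturb earlier genes' draws.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `"sim_dataset"` with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, gene ids `G000001...`,}
#'     \item{condition}{factor `cond1`/`cond2` per sample,}
#'     \item{truth}{list with `module_of_gene` (named integer, 0 = background)
#'       and `differential_pairs` (data frame of planted pairs with gene ids
#'       and true correlations).}
#'   }
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  nG <- params$n_genes
  n1 <- params$n_samples_per_condition[1]
  n2 <- params$n_samples_per_condition[2]
  rho <- params$within_module_cor
  gene_ids <- sprintf("G%06d", seq_len(nG))

  module_of_gene <- integer(nG)
  if (length(params$module_sizes) > 0) {
    module_of_gene[seq_len(sum(params$module_sizes))] <-
      rep(seq_along(params$module_sizes), params$module_sizes)
  }
  names(module_of_gene) <- gene_ids

  # `within_module_cor` and the planted r's refer to the observed log-CPM
  # scale; the latent correlations are calibrated upward to compensate the
  # two attenuation mechanisms of count data (see the methods vignette):
  # count noise (log-scale measurement variance tau^2) and the CPM
  # compositional effect (module factors fluctuate the library depth, and
  # dividing by depth perturbs all correlations).
  # decoy genes carry ~400-fold less signal and hence negligible depth weight;
  # the calibration sees only the expressed genes
  n_expressed <- nG - params$n_unexpressed
  baseline <- rep(params$mean_log_expression, nG)
  if (params$n_unexpressed > 0) {
    baseline[(n_expressed + 1):nG] <- params$mean_log_expression - 6
  }
  cal <- calibrate_latent_correlations(
    rho = rho, module_sizes = params$module_sizes, n_genes = n_expressed,
    nb_dispersion = params$nb_dispersion,
    mean_log_expression = params$mean_log_expression,
    planted_r = if (is.null(params$planted_pairs)) numeric(0) else
      c(params$planted_pairs$r1, params$planted_pairs$r2))
  rho_lat <- cal$rho_lat

  sim_condition <- function(cond, n) {
    # module factors
    factors <- lapply(seq_along(params$module_sizes), function(m) {
      with_substream(params$seed, sprintf("factor-m%d-%s", m, cond), stats::rnorm(n))
    })
    # per-gene idiosyncratic draws (the same stream serves as eps for both the
    # module mixture and the planted-pair construction)
    eps <- matrix(0, nG, n)
    for (g in seq_len(nG)) {
      eps[g, ] <- with_substream(params$seed, sprintf("eps-g%d-%s", g, cond), stats::rnorm(n))
    }
    x <- eps
    for (g in seq_len(nG)) {
      m <- module_of_gene[g]
      if (m > 0) x[g, ] <- sqrt(rho_lat[m]) * factors[[m]] + sqrt(1 - rho_lat[m]) * eps[g, ]
    }
    # planted differential pairs: rebuild gene_j from gene_i per condition
    if (!is.null(params$planted_pairs)) {
      r_col <- if (cond == "cond1") "r1" else "r2"
      rebuilt <- logical(nG)
      for (k in seq_len(nrow(params$planted_pairs))) {
        i <- params$planted_pairs$gene_i[k]
        j <- params$planted_pairs$gene_j[k]
        r <- cal$planted_latent(params$planted_pairs[[r_col]][k])
        if (rebuilt[j]) {
          stop("planted pairs form a cycle: gene ", gene_ids[j],
               " is the dependent member of more than one pair", call. = FALSE)
        }
        x[j, ] <- r * x[i, ] + sqrt(1 - r^2) * eps[j, ]
        rebuilt[j] <- TRUE
      }
    }
    # library sizes and counts
    logL <- with_substream(params$seed, paste0("lib-", cond),
                           stats::rnorm(n, 0, params$library_size_log_sd))
    L <- exp(logL)
    counts <- matrix(0L, nG, n)
    for (g in seq_len(nG)) {
      mu <- L * exp(baseline[g] + x[g, ])
      counts[g, ] <- with_substream(params$seed, sprintf("nb-g%d-%s", g, cond), {
        if (params$nb_dispersion > 0) {
          stats::rnbinom(n, mu = mu, size = 1 / params$nb_dispersion)
        } else {
          stats::rpois(n, lambda = mu)
        }
      })
    }
    counts
  }

  c1 <- sim_condition("cond1", n1)
  c2 <- sim_condition("cond2", n2)
  counts <- cbind(c1, c2)
  rownames(counts) <- gene_ids
  colnames(counts) <- c(sprintf("S1_%04d", seq_len(n1)), sprintf("S2_%04d", seq_len(n2)))
  condition <- factor(rep(c("cond1", "cond2"), c(n1, n2)), levels = c("cond1", "cond2"))

  differential_pairs <- if (is.null(params$planted_pairs)) {
    data.frame(gene_i = character(0), gene_j = character(0),
               r1_true = numeric(0), r2_true = numeric(0))
  } else {
    data.frame(gene_i = gene_ids[params$planted_pairs$gene_i],
               gene_j = gene_ids[params$planted_pairs$gene_j],
               r1_true = params$planted_pairs$r1,
               r2_true = params$planted_pairs$r2)
  }

  structure(list(
    counts = counts,
    condition = condition,
    truth = list(module_of_gene = module_of_gene,
                 differential_pairs = differential_pairs,
                 unexpressed = if (params$n_unexpressed > 0)
                   gene_ids[(n_expressed + 1):nG] else character(0)),
    params = params
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic two-condition dataset: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", levels(x$condition), table(x$condition)), collapse = ", ")))
  k <- sum(x$truth$module_of_gene > 0)
  cat(sprintf("  planted modules: %d (%d genes), planted differential pairs: %d\n",
              length(x$params$module_sizes), k, nrow(x$truth$differential_pairs)))
  invisible(x)
}

# Solve for the latent module correlation (per module) and a mapping for
# planted correlations such that the *observed* log-CPM correlations match
# the requested targets, under a first-order log-linear model of the data:
#   y_g = x_g - D + noise,  D ~ (1/G) sum_h x_h  (log library depth),
#   tau^2 = Var(noise) = trigamma(1/dispersion) + exp(-mean_log_expression).
# For two genes of module m (signal sd s, a_m = size_m * s / G):
#   cov(y_i, y_j) = s^2 + Var(D) - 2 (s a_m + (1 - s^2)/G)
#   var(y_i)      = 1 + tau^2 + Var(D) - 2 (s a_m + (1 - s^2)/G)
# and s is found by root solving, iterating because Var(D) depends on all
# modules' s. Planted (background) pairs invert the analogous linear
# relation. Latent correlations are capped at 0.995; extreme configurations
# (modules dominating the library) can therefore fall slightly short.
calibrate_latent_correlations <- function(rho, module_sizes, n_genes,
                                          nb_dispersion, mean_log_expression,
                                          planted_r = numeric(0)) {
  g <- n_genes
  tau2 <- exp(-mean_log_expression) +
    if (nb_dispersion > 0) trigamma(1 / nb_dispersion) else 0
  s_cap <- sqrt(0.995)
  k <- length(module_sizes)
  s <- rep(sqrt(rho), k)
  var_d <- function(s_vec) {
    eps_part <- (sum(module_sizes * (1 - s_vec^2)) + (g - sum(module_sizes))) / g^2
    sum((module_sizes * s_vec / g)^2) + eps_part
  }
  if (k > 0 && rho > 0) {
    for (iter in 1:4) {
      vd <- var_d(s)
      for (m in seq_len(k)) {
        f <- function(sm) {
          depth_cov <- 2 * (sm * module_sizes[m] * sm / g + (1 - sm^2) / g)
          (sm^2 + vd - depth_cov) / (1 + tau2 + vd - depth_cov) - rho
        }
        s[m] <- if (f(s_cap) < 0) s_cap else
          stats::uniroot(f, c(sqrt(rho) * 0.5, s_cap), tol = 1e-12)$root
      }
    }
  }
  vd <- var_d(s)
  planted_latent <- function(r_target) {
    r_lat <- (r_target * (1 + tau2 + vd - 2 / g) - vd + 2 / g) / (1 - 2 / g)
    sign(r_lat) * min(abs(r_lat), 0.995)
  }
  list(rho_lat = if (k > 0) s^2 else numeric(0), planted_latent = planted_latent,
       tau2 = tau2, var_depth = vd)
}

#' Sample correlation pairs under a shared true correlation
#'
#' Calibration harness for the Fisher-Z difference test: draws `reps`
#' independent two-sample experiments in which both conditions share the same
#' true correlation `r_common`, and returns the two sample correlations of
#' each experiment. Under this null, `atanh(r_hat)` is approximately normal
#' with variance `1/(n - 3)`.
#'
#' @param n1,n2 Sample sizes per condition (each >= 4).
#' @param r_common Shared true correlation, `|r| < 1`.
#' @param reps Number of replicate experiments.
#' @param seed Integer seed.
#' @return A `reps` x 2 matrix with columns `r1_hat`, `r2_hat`.
#' @export
generate_null_correlation_pairs <- function(n1, n2, r_common, reps, seed = 1L) {
  check_param(n1 >= 4 && n2 >= 4, "n1/n2", "must be >= 4")
  check_param(abs(r_common) < 1, "r_common", "must satisfy |r| < 1")
  check_param(reps >= 0, "reps", "must be non-negative")
  out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("r1_hat", "r2_hat")))
  if (reps == 0) return(out)
  with_substream(seed, "null-correlation-pairs", {
    draw_r <- function(n) {
      u <- stats::rnorm(n)
      v <- r_common * u + sqrt(1 - r_common^2) * stats::rnorm(n)
      stats::cor(u, v)
    }
    out <- cbind(r1_hat = vapply(seq_len(reps), function(i) draw_r(n1), numeric(1)),
                 r2_hat = vapply(seq_len(reps), function(i) draw_r(n2), numeric(1)))
  })
  out
}
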