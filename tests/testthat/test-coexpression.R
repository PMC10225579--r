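test_that("inverse-gamma filter: p decreases in variance and calibrates", {
  # rows with exact sample variances drawn from an inverse gamma
  set.seed(8)
  n <- 60
  v <- 1 / rgamma(5000, shape = 3, rate = 2)
  expr <- t(vapply(v, function(vi) {
    x <- rnorm(n); (x - mean(x)) / sd(x) * sqrt(vi)
  }, numeric(n)))
  rownames(expr) <- sprintf("g%d", seq_along(v))
  colnames(expr) <- sprintf("s%d", seq_len(n))
  keep <- filter_genes_invgamma(expr, p_threshold = 0.1)
  p <- attr(keep, "p")
  # probability-integral transform: ~10% of genes in the upper tail
  expect_lt(abs(length(keep) / length(v) - 0.1), 0.03)
  # monotonicity: larger variance, smaller upper-tail p
  ord <- order(v)
  expect_true(all(diff(p[ord]) <= 1e-12))
  expect_length(filter_genes_invgamma(expr, p_threshold = 1), length(v))
})

test_that("inverse-gamma filter refuses degenerate equal variances", {
  expr <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:4)))
  expect_error(filter_genes_invgamma(expr), "equal")
})

test_that("adjacency is |cor|^beta with unit diagonal", {
  pair <- exact_cor_pair(30, -0.5, seed = 9)
  expr <- rbind(g1 = pair$x, g2 = pair$y)
  colnames(expr) <- sprintf("s%d", 1:30)
  a2 <- adjacency_matrix(expr, beta = 2)
  expect_equal(a2["g1", "g2"], 0.25, tolerance = 1e-12)

  m <- random_counts(4, 20, seed = 10) + 0.0
  a1 <- adjacency_matrix(m, beta = 1)
  a6 <- adjacency_matrix(m, beta = 6)
  off <- upper.tri(a1)
  expect_true(all(a6[off] < a1[off]))          # strict decrease for |r| < 1
  oracle <- abs(cor(t(m)))^6; diag(oracle) <- 1
  expect_equal(a6, oracle, tolerance = 1e-12)
})

test_that("zero-variance genes get zero adjacency with a warning", {
  m <- random_counts(4, 15, seed = 11) + 0.0
  m[2, ] <- 7
  expect_warning(a <- adjacency_matrix(m, beta = 2), "g2")
  expect_true(all(a["g2", -2] == 0))
})

test_that("topological overlap matches its closed form and the triple-loop oracle", {
  for (c_val in c(0.1, 0.3, 0.7, 0.95)) {
    adj <- matrix(c_val, 3, 3); diag(adj) <- 1
    dimnames(adj) <- list(sprintf("g%d", 1:3), sprintf("g%d", 1:3))
    tom <- tom_similarity(adj)
    expect_equal(tom[1, 2], c_val, tolerance = 1e-14)  # (c^2+c)/(c+1) = c
  }
  id <- diag(1, 4); dimnames(id) <- list(sprintf("g%d", 1:4), sprintf("g%d", 1:4))
  expect_equal(tom_similarity(id), id, ignore_attr = TRUE)

  set.seed(12)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    adj <- matrix(runif(n * n), n, n)
    adj <- (adj + t(adj)) / 2; diag(adj) <- 1
    dimnames(adj) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
    expect_equal(tom_similarity(adj), tom_ref(adj), tolerance = 1e-12)
  }
  bad <- matrix(runif(9), 3, 3)
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("soft-threshold criterion triggers on hub-structured data", {
  set.seed(13)
  G <- 300; n <- 150
  loading <- 3 * (seq_len(G) / G)^3
  f <- rnorm(n)
  expr <- t(vapply(loading, function(li) li * f + rnorm(n), numeric(n)))
  rownames(expr) <- sprintf("g%03d", seq_len(G))
  colnames(expr) <- sprintf("s%03d", seq_len(n))
  st <- select_soft_threshold(expr)
  expect_true(st$criterion_met)
  expect_lte(st$beta, 20)
  expect_gte(st$fit_table$r_squared[st$fit_table$beta == st$beta], 0.8)
  # smallest qualifying power is chosen
  qualifying <- st$fit_table$beta[!is.na(st$fit_table$r_squared) &
                                    st$fit_table$r_squared >= 0.8]
  expect_identical(st$beta, min(qualifying))
})

test_that("soft-threshold fit table is permutation invariant and fallback is honest", {
  d <- generate_dataset(sim_params(n_genes = 80, n_samples_per_condition = c(40, 4),
                                   module_sizes = c(25, 25), seed = 14))
  expr <- vst(d$counts[, d$condition == "cond1"])
  st <- select_soft_threshold(expr, betas = 1:8)
  perm <- sample(nrow(expr))
  st_perm <- select_soft_threshold(expr[perm, ], betas = 1:8)
  expect_equal(st$fit_table$r_squared, st_perm$fit_table$r_squared, tolerance = 1e-10)
  if (!st$criterion_met) {
    expect_identical(st$beta,
                     st$fit_table$beta[which.max(st$fit_table$r_squared)])
  }
})

test_that("identical expression for all genes defeats the scale-free fit", {
  base <- rnorm(20)
  expr <- matrix(rep(base, each = 5), 5, 20,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:20)))
  st <- select_soft_threshold(expr, betas = 1:5)
  expect_false(st$criterion_met)
  expect_true(all(is.na(st$fit_table$r_squared)))
})

test_that("planted modules are recovered and labels are permutation invariant", {
  d <- generate_dataset(sim_params(n_genes = 160, n_samples_per_condition = c(80, 4),
                                   module_sizes = c(40, 40), within_module_cor = 0.85,
                                   seed = 15))
  expr <- vst(d$counts[, d$condition == "cond1"])
  adj <- adjacency_matrix(expr, beta = 6)
  tom <- tom_similarity(adj)
  mod <- detect_modules(tom)
  expect_identical(mod$n_modules, 2L)
  truth <- d$truth$module_of_gene
  in_mod <- truth > 0
  expect_gte(adjusted_mutual_information(truth[in_mod],
                                         mod$module_of_gene[names(truth)[in_mod]]), 0.9)
  # labels ordered by decreasing size
  expect_true(all(diff(mod$module_sizes) <= 0))

  perm <- sample(nrow(tom))
  mod_perm <- detect_modules(tom[perm, perm])
  expect_identical(mod_perm$module_of_gene[rownames(tom)], mod$module_of_gene)
})

test_that("pure noise yields no modules in most seeds", {
  zero_mods <- vapply(1:10, function(s) {
    d <- generate_dataset(sim_params(n_genes = 120, n_samples_per_condition = c(60, 4),
                                     module_sizes = integer(0), seed = 100 + s))
    expr <- vst(d$counts[, d$condition == "cond1"])
    res <- coexpression_analysis(d$counts[, d$condition == "cond1"], filter_p = NULL)
    res$modules$n_modules == 0
  }, logical(1))
  expect_gte(mean(zero_mods), 0.9)
})

test_that("hubs are the most intramodularly connected genes", {
  # star adjacency: center g1 tied to all leaves, leaves mutually unlinked
  n <- 6
  adj <- diag(1, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 0.9
  dimnames(adj) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
  mod <- structure(list(module_of_gene = setNames(rep(1L, n), rownames(adj)),
                        module_sizes = c(`1` = n), n_modules = 1L),
                   class = "module_assignment")
  hubs <- find_hubs(adj, mod, n_hubs = 2)
  expect_identical(hubs[["1"]]$gene_id[1], "g1")
  all_ranked <- find_hubs(adj, mod, n_hubs = 99)[["1"]]
  expect_identical(nrow(all_ranked), as.integer(n))
  k_within <- rowSums(adj) - 1
  expect_identical(all_ranked$gene_id,
                   rownames(adj)[order(-k_within, rownames(adj))])
})

test_that("module stability is seed-reproducible and trivially exact at one rep", {
  d <- generate_dataset(sim_params(n_genes = 90, n_samples_per_condition = c(40, 40),
                                   module_sizes = c(30, 30), seed = 16))
  one <- module_stability(d$counts, n_reps = 1, seed = 5, filter_p = NULL)
  expect_identical(one$modal_count_accuracy, 1)
  r1 <- module_stability(d$counts, n_reps = 5, seed = 6, filter_p = NULL)
  r2 <- module_stability(d$counts, n_reps = 5, seed = 6, filter_p = NULL)
  expect_identical(r1$module_counts, r2$module_counts)
  expect_identical(r1$hub_recovery, r2$hub_recovery)
  expect_equal(sum(r1$module_count_distribution), 1)
  expect_equal(r1$modal_count_accuracy, max(r1$module_count_distribution))
})

test_that("hub recovery under subsampling favours true module genes", {
  d <- generate_dataset(sim_params(n_genes = 100, n_samples_per_condition = c(50, 50),
                                   module_sizes = c(30, 30), within_module_cor = 0.9,
                                   seed = 17))
  rep_out <- module_stability(d$counts, n_reps = 10, seed = 7, filter_p = NULL)
  truth <- d$truth$module_of_gene
  expect_gt(mean(rep_out$hub_recovery[truth > 0]),
            mean(rep_out$hub_recovery[truth == 0]))
})
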