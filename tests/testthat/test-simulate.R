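test_that("a fixed seed reproduces the dataset bit for bit", {
  p <- sim_params(n_genes = 60, n_samples_per_condition = c(20, 20),
                  module_sizes = c(15, 15), seed = 7)
  d1 <- generate_dataset(p)
  d2 <- generate_dataset(p)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth, d2$truth)
})

test_that("gene sub-streams are hierarchical: adding genes keeps earlier draws", {
  # module-free config: the observed-scale calibration depends on the gene
  # roster (library shares), so only background genes are roster-invariant
  base <- sim_params(n_genes = 40, n_samples_per_condition = c(10, 10),
                     module_sizes = integer(0), seed = 3)
  bigger <- sim_params(n_genes = 55, n_samples_per_condition = c(10, 10),
                       module_sizes = integer(0), seed = 3)
  d1 <- generate_dataset(base)
  d2 <- generate_dataset(bigger)
  expect_identical(d1$counts, d2$counts[1:40, ])
})

test_that("counts are non-negative integers with the requested shape", {
  d <- generate_dataset(sim_params(n_genes = 30, n_samples_per_condition = c(6, 9),
                                   module_sizes = c(10), seed = 1))
  expect_identical(dim(d$counts), c(30L, 15L))
  expect_true(all(d$counts >= 0))
  expect_true(all(d$counts == round(d$counts)))
  expect_identical(as.vector(table(d$condition)), c(6L, 9L))
  expect_identical(sum(d$truth$module_of_gene > 0), 10L)
})

test_that("realized within-module correlation on log-CPM matches the target", {
  cases <- list(list(rho = 0.81, sizes = 30, n = 200, tol = 0.10, seed = 11),
                list(rho = 0.81, sizes = 30, n = 500, tol = 0.05, seed = 12),
                list(rho = 0.85, sizes = c(50, 50), n = 100, tol = 0.10, seed = 13),
                list(rho = 0,    sizes = 30, n = 500, tol = 0.05, seed = 14))
  for (cs in cases) {
    d <- generate_dataset(sim_params(
      n_genes = 200, n_samples_per_condition = c(cs$n, 4),
      module_sizes = cs$sizes, within_module_cor = cs$rho, seed = cs$seed))
    expr <- vst(d$counts[, d$condition == "cond1"])
    cc <- cor(t(expr[seq_len(cs$sizes[1]), ]))
    realized <- mean(cc[upper.tri(cc)])
    expect_lt(abs(realized - cs$rho), cs$tol,
              label = sprintf("|%.3f - %g| (rho = %g)", realized, cs$rho, cs$rho))
  }
})

test_that("planted pair correlations are realized per condition", {
  pp <- data.frame(gene_i = 81, gene_j = 82, r1 = 0.8, r2 = 0.0)
  d <- generate_dataset(sim_params(
    n_genes = 100, n_samples_per_condition = c(500, 500), module_sizes = c(40),
    within_module_cor = 0.85, planted_pairs = pp, seed = 21))
  expr <- vst(d$counts)
  r1 <- cor(expr[81, d$condition == "cond1"], expr[82, d$condition == "cond1"])
  r2 <- cor(expr[81, d$condition == "cond2"], expr[82, d$condition == "cond2"])
  expect_lt(abs(r1 - 0.8), 0.1)
  expect_lt(abs(r2 - 0.0), 0.1)
})

test_that("a planted star induces the hub's correlations without cycles", {
  pp <- planted_star(50, 51:58, 0.7, 0.1)
  d <- generate_dataset(sim_params(n_genes = 60, n_samples_per_condition = c(400, 4),
                                   module_sizes = integer(0), planted_pairs = pp,
                                   seed = 2))
  expr <- vst(d$counts[, d$condition == "cond1"])
  hub_r <- sapply(51:58, function(j) cor(expr[50, ], expr[j, ]))
  expect_true(all(abs(hub_r - 0.7) < 0.15))
  cyc <- rbind(pp, data.frame(gene_i = 59, gene_j = 51, r1 = 0.5, r2 = 0.5))
  expect_error(generate_dataset(sim_params(n_genes = 60,
                                           n_samples_per_condition = c(10, 10),
                                           module_sizes = integer(0),
                                           planted_pairs = cyc, seed = 2)),
               "cycle")
})

test_that("parameter invariants are enforced with the offending field named", {
  expect_error(sim_params(n_genes = 20, module_sizes = c(15, 15)), "module_sizes")
  expect_error(sim_params(n_samples_per_condition = c(3, 10)), "n_samples_per_condition")
  expect_error(sim_params(n_genes = 50, module_sizes = c(10),
                          planted_pairs = data.frame(gene_i = 20, gene_j = 21,
                                                     r1 = 1, r2 = 0)),
               "planted_pairs")
  expect_error(sim_params(n_genes = 50, module_sizes = c(10),
                          planted_pairs = data.frame(gene_i = 5, gene_j = 21,
                                                     r1 = 0.5, r2 = 0)),
               "planted_pairs")  # module gene without overlap flag
  expect_error(sim_params(n_genes = 50, n_unexpressed = 50), "n_unexpressed")
})

test_that("unexpressed decoys have near-zero counts and are recorded in truth", {
  d <- generate_dataset(sim_params(n_genes = 50, n_samples_per_condition = c(20, 20),
                                   module_sizes = c(10), n_unexpressed = 15, seed = 4))
  expect_length(d$truth$unexpressed, 15)
  expect_lt(mean(rowSums(d$counts[d$truth$unexpressed, ])),
            mean(rowSums(d$counts[1:35, ])) / 50)
})

test_that("null correlation pairs have the Fisher-Z variance 1/(n-3)", {
  pairs <- generate_null_correlation_pairs(100, 100, r_common = 0, reps = 10000, seed = 5)
  expect_identical(dim(pairs), c(10000L, 2L))
  sd_z <- sd(atanh(pairs[, "r1_hat"]))
  expect_lt(abs(sd_z - 1 / sqrt(97)) / (1 / sqrt(97)), 0.1)
  expect_identical(nrow(generate_null_correlation_pairs(10, 10, 0, 0)), 0L)
  expect_identical(generate_null_correlation_pairs(20, 30, 0.4, 50, seed = 9),
                   generate_null_correlation_pairs(20, 30, 0.4, 50, seed = 9))
})
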