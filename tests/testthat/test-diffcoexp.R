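make_cond <- function(n_genes = 10, n1 = 30, n2 = 30, seed = 1) {
  d <- generate_dataset(sim_params(n_genes = n_genes,
                                   n_samples_per_condition = c(n1, n2),
                                   module_sizes = integer(0), seed = seed))
  conditioned_expression(vst(d$counts), d$condition)
}

test_that("pairwise correlations handle identity, antisymmetry and match cor.test", {
  set.seed(18)
  expr <- matrix(rnorm(5 * 30), 5, 30,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:30)))
  expr[2, ] <- expr[1, ]          # duplicate
  expr[3, ] <- -expr[1, ]         # negation
  pc <- pairwise_correlations(expr)
  expect_equal(pc$r["g1", "g2"], 1)
  expect_identical(pc$p["g1", "g2"], 0)
  expect_equal(pc$r["g1", "g3"], -1)
  for (pair in list(c(1, 4), c(4, 5), c(1, 5))) {
    ct <- cor.test(expr[pair[1], ], expr[pair[2], ])
    expect_equal(pc$p[pair[1], pair[2]], ct$p.value, tolerance = 1e-12)
  }
})

test_that("zero-variance genes get r = 0, p = 1 with a warning", {
  expr <- matrix(rnorm(3 * 20), 3, 20,
                 dimnames = list(sprintf("g%d", 1:3), sprintf("s%d", 1:20)))
  expr[2, ] <- 4
  expect_warning(pc <- pairwise_correlations(expr), "g2")
  expect_identical(pc$r["g2", "g1"], 0)
  expect_identical(pc$p["g2", "g3"], 1)
})

test_that("Fisher-Z difference test matches its closed form", {
  null_case <- fisher_z_diff_test(0.37, 50, 0.37, 80)
  expect_identical(null_case$z_stat, 0)
  expect_identical(null_case$p_diff, 1)

  swapped <- fisher_z_diff_test(0.2, 103, 0.8, 103)
  frozen <- fisher_z_diff_test(0.8, 103, 0.2, 103)
  expect_equal(frozen$z_stat, 6.334826354732, tolerance = 1e-10)
  expect_equal(frozen$p_diff, 2.376087221463e-10, tolerance = 1e-9)
  expect_equal(swapped$z_stat, -frozen$z_stat)
  expect_equal(swapped$p_diff, frozen$p_diff)

  expect_error(fisher_z_diff_test(0.5, 3, 0.2, 50), "n > 3")
  # |r| = 1 is clamped, not infinite
  extreme <- fisher_z_diff_test(1, 20, -1, 20)
  expect_true(is.finite(extreme$z_stat))
})

test_that("Fisher-Z statistic agrees with an independent formulation on a grid", {
  set.seed(19)
  r1 <- runif(1000, -0.99, 0.99); r2 <- runif(1000, -0.99, 0.99)
  n1 <- sample(5:300, 1000, replace = TRUE); n2 <- sample(5:300, 1000, replace = TRUE)
  got <- fisher_z_diff_test(r1, n1, r2, n2)
  # independent path: atanh via logs, normal tail via erfc relation
  z_ref <- (0.5 * log((1 + r1) / (1 - r1)) - 0.5 * log((1 + r2) / (1 - r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p_ref <- pchisq(z_ref^2, df = 1, lower.tail = FALSE)
  expect_equal(got$z_stat, z_ref, tolerance = 1e-10)
  expect_equal(got$p_diff, p_ref, tolerance = 1e-10)
})

test_that("co-expressed pair gating applies |r| and q thresholds per condition", {
  pair1 <- exact_cor_pair(40, 0.9, seed = 20)
  set.seed(21)
  expr1 <- rbind(g1 = pair1$x, g2 = pair1$y, g3 = rnorm(40))
  expr2 <- matrix(rnorm(3 * 40), 3, 40, dimnames = list(c("g1", "g2", "g3"), NULL))
  colnames(expr1) <- sprintf("a%d", 1:40); colnames(expr2) <- sprintf("b%d", 1:40)
  cond <- structure(list(expr1 = expr1, expr2 = expr2, n1 = 40, n2 = 40,
                         levels = c("c1", "c2")), class = "conditioned_expression")
  pairs <- coexpressed_pairs(cond)
  row <- pairs[pairs$gene_i == "g1" & pairs$gene_j == "g2", ]
  expect_identical(nrow(row), 1L)
  expect_true(row$coexp_1)
  expect_false(row$coexp_2)
  expect_identical(nrow(coexpressed_pairs(cond, rth = 1.01)), 0L)
})

test_that("retained pair set equals an oracle with an independent BH", {
  cond <- make_cond(n_genes = 10, n1 = 25, n2 = 25, seed = 22)
  rth <- 0.3; q_co <- 0.2
  got <- coexpressed_pairs(cond, rth = rth, q_coexp = q_co)
  oracle_keys <- character(0)
  n_g <- nrow(cond$expr1)
  for (cnd in 1:2) {
    expr <- if (cnd == 1) cond$expr1 else cond$expr2
    ps <- c(); rs <- c(); keys <- c()
    for (i in 1:(n_g - 1)) for (j in (i + 1):n_g) {
      ct <- cor.test(expr[i, ], expr[j, ])
      ps <- c(ps, ct$p.value); rs <- c(rs, unname(ct$estimate))
      keys <- c(keys, paste(rownames(expr)[i], rownames(expr)[j], sep = "|"))
    }
    qs <- bh_ref(ps)
    oracle_keys <- union(oracle_keys, keys[abs(rs) >= rth & qs <= q_co])
  }
  expect_setequal(paste(got$gene_i, got$gene_j, sep = "|"), oracle_keys)
})

test_that("planted differential pairs are called DCLs; empty input passes through", {
  pp <- data.frame(gene_i = 1, gene_j = 2, r1 = 0.8, r2 = 0.0)
  d <- generate_dataset(sim_params(n_genes = 15, n_samples_per_condition = c(70, 100),
                                   module_sizes = integer(0), planted_pairs = pp,
                                   seed = 23))
  cond <- conditioned_expression(vst(d$counts), d$condition)
  pairs <- coexpressed_pairs(cond)
  dcls <- call_dcls(pairs, cond)
  expect_true(any(dcls$gene_i == "G000001" & dcls$gene_j == "G000002"))
  # q-values are monotone in raw p rank and within [0, 1]
  tested <- attr(dcls, "tested")
  ord <- order(tested$p_diff)
  expect_true(all(diff(tested$q_diff[ord]) >= -1e-12))
  expect_true(all(tested$q_diff >= 0 & tested$q_diff <= 1))

  empty <- pairs[0, ]
  expect_identical(nrow(call_dcls(empty, cond)), 0L)
})

test_that("DCL classes follow the sign/flag convention", {
  expect_identical(classify_dcl(0.8, 0.3, TRUE, TRUE), "same-signed")
  expect_identical(classify_dcl(0.7, -0.6, TRUE, TRUE), "switched-opposite")
  expect_identical(classify_dcl(0.8, 0.1, TRUE, FALSE), "diff-signed")
  expect_error(classify_dcl(0.8, 0.1, FALSE, FALSE), "at least one")
})

test_that("DCG p-values equal exact binomial tail sums", {
  # constructed incidence: star pairs so that links/dcls are known exactly
  mk_pairs <- function(n) data.frame(gene_i = "hub", gene_j = sprintf("p%d", 1:n),
                                     r1 = 0.8, r2 = 0, coexp_1 = TRUE, coexp_2 = FALSE)
  # 100 pairs total, 10 DCLs -> p_hat = 0.1; hub has 10 links, 5 dcls
  filler <- data.frame(gene_i = sprintf("x%d", 1:90), gene_j = sprintf("y%d", 1:90),
                       r1 = 0.8, r2 = 0, coexp_1 = TRUE, coexp_2 = FALSE)
  pairs <- rbind(mk_pairs(10), filler)
  dcls <- rbind(mk_pairs(10)[1:5, ], filler[1:5, ])
  out <- call_dcgs(dcls, pairs)
  expect_equal(attr(out, "p_hat"), 0.1)
  hub <- out[out$gene == "hub", ]
  expect_equal(hub$p_binom, 1.6349374e-3, tolerance = 1e-12)
  expect_equal(hub$p_binom, sum(dbinom(5:10, 10, 0.1)), tolerance = 1e-12)
  # enumeration oracle across all genes with n_links <= 20
  for (i in seq_len(nrow(out))) {
    expect_equal(out$p_binom[i],
                 sum(dbinom(out$n_dcls[i]:out$n_links[i], out$n_links[i], 0.1)),
                 tolerance = 1e-12)
  }
  # zero incident DCLs -> p = 1
  expect_true(all(out$p_binom[out$n_dcls == 0] == 1))
})

test_that("saturated DCL rate gives no enrichment", {
  pairs <- data.frame(gene_i = c("a", "a", "b"), gene_j = c("b", "c", "c"),
                      r1 = 0.9, r2 = 0, coexp_1 = TRUE, coexp_2 = FALSE)
  out <- call_dcgs(pairs, pairs)  # every pair a DCL
  expect_true(all(out$p_binom == 1))
  expect_false(any(out$dcg))
  expect_error(call_dcgs(pairs[0, ], pairs[0, ]), "zero retained")
})

test_that("DCG stability is seed-reproducible and finds a strong planted hub", {
  # modules provide stable non-differential co-expressed pairs, so the global
  # DCL rate stays low and the planted star stands out
  pp <- planted_star(51, 52:59, 0.85, 0.0)
  d <- generate_dataset(sim_params(n_genes = 60, n_samples_per_condition = c(60, 60),
                                   module_sizes = c(20, 20), planted_pairs = pp,
                                   seed = 24))
  cond <- conditioned_expression(vst(d$counts), d$condition)
  s1 <- dcg_stability(cond, n_reps = 10, seed = 3)
  s2 <- dcg_stability(cond, n_reps = 10, seed = 3)
  expect_identical(s1, s2)
  expect_gte(s1[["G000051"]], 0.8)
})

test_that("diffcoexp network object keeps node and threshold invariants", {
  pp <- planted_star(6, 7:10, 0.8, 0.0)
  d <- generate_dataset(sim_params(n_genes = 12, n_samples_per_condition = c(50, 50),
                                   module_sizes = integer(0), planted_pairs = pp,
                                   seed = 25))
  net <- diffcoexp_network(conditioned_expression(vst(d$counts), d$condition))
  expect_setequal(net$nodes, unique(c(net$dcls$gene_i, net$dcls$gene_j)))
  dcg_genes <- net$dcgs$gene[net$dcgs$dcg]
  link_counts <- net$dcgs$n_links
  expect_true(all(net$dcgs$n_dcls <= link_counts))
  expect_output(print(net), "Differential co-expression network")
})
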