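test_that("snp_chi2 inverts the 1-df chi-square upper tail", {
  expect_equal(snp_chi2(1), 0)
  expect_equal(snp_chi2(0.3173), 1.00, tolerance = 0.01)
  expect_equal(snp_chi2(0.0455), 4.00, tolerance = 0.01)
  # round-trip property: upper-tail probability of the statistic is p
  for (p in c(0.9, 0.5, 0.01, 1e-8)) {
    expect_equal(pchisq(snp_chi2(p), 1, lower.tail = FALSE), p,
                 tolerance = 1e-12)
  }
  expect_error(snp_chi2(0), "clamp")
})

test_that("gene_statistic sums per-SNP chi-squares and ignores p = 1 SNPs", {
  expect_equal(gene_statistic(0.3173), 1.00, tolerance = 0.01)
  expect_equal(gene_statistic(c(1, 1, 1)), 0)
  expect_equal(gene_statistic(c(0.3173, 0.0455)), 5.00, tolerance = 0.02)
  ps <- c(0.2, 0.04, 0.7)
  expect_equal(gene_statistic(c(ps, 1)), gene_statistic(ps))
  expect_error(gene_statistic(numeric(0)), "at least one")
})

test_that("ld_correlation matches a long-hand Pearson computation", {
  G <- cbind(a = c(0, 1, 2, 2), b = c(0, 1, 1, 2))
  R <- ld_correlation(G)
  expect_equal(R[1, 2], oracle_pearson(G[, 1], G[, 2]), tolerance = 1e-12)
  expect_equal(diag(R), c(a = 1, b = 1))
})

test_that("ld_correlation: duplicates, independence, degenerate columns", {
  set.seed(5)
  x <- sample(0:2, 40, replace = TRUE)
  expect_equal(ld_correlation(cbind(x, x))[1, 2], 1, tolerance = 1e-7)

  g <- simulate_genotypes(5000, list(list(n_snps = 6, ld_rho = 0,
                                          maf_range = c(0.2, 0.5))), seed = 6)
  R <- ld_correlation(g$dosage)
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)

  expect_warning(Rz <- ld_correlation(cbind(x, rep(1, 40))), "zero-variance")
  expect_equal(Rz[1, 2], 0)
  expect_equal(diag(Rz), c(1, 1), ignore_attr = TRUE)
  expect_error(ld_correlation(cbind(c(0, 1), c(1, 0))), "3 individuals")
})

test_that("simulate_null_Q reproduces chi-square moments and closed forms", {
  n <- 20000
  q1 <- simulate_null_Q(diag(4), n, seed = 9)
  # Q ~ chi-square(4): mean 4, var 8
  expect_lt(abs(mean(q1) - 4), 3 * sqrt(8 / n))
  # perfect LD: Q = 5 * chi-square(1), variance 50
  q2 <- simulate_null_Q(matrix(1, 5, 5), n, seed = 10)
  expect_lt(abs(mean(q2) - 5), 3 * sqrt(50 / n))
  expect_lt(abs(var(q2) - 50), 7)
  # determinism
  expect_identical(simulate_null_Q(diag(3), 100, seed = 11),
                   simulate_null_Q(diag(3), 100, seed = 11))
})

test_that("empirical_p counts the upper tail with >= and floors at zero", {
  ns <- c(1, 2, 3, 4, 5)
  expect_equal(empirical_p(0.5, ns)$p, 1)
  expect_equal(empirical_p(3, ns)$p, 3 / 5)
  top <- empirical_p(10, ns)
  expect_equal(top$p, 0)
  expect_true(top$floored)
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("adaptive schedule escalates only when the running p is small", {
  # single SNP p = 0.5 -> stage-1 p ~ 0.5 > 0.1: stays at 10^3
  r1 <- adaptive_gene_test(0.5, stages = c(1e3, 1e4), escalate_p = 0.1,
                           seed = 1)
  expect_equal(r1$n_sims, 1e3)
  # single SNP p = 0.05 -> stage-1 p ~ 0.05 <= 0.1: escalates to 10^4
  r2 <- adaptive_gene_test(0.05, stages = c(1e3, 1e4), escalate_p = 0.1,
                           seed = 1)
  expect_equal(r2$n_sims, 1e4)
  # determinism of the full result
  expect_identical(adaptive_gene_test(c(0.05, 0.2), seed = 3,
                                      stages = c(1e3, 1e4), escalate_p = 0.1),
                   adaptive_gene_test(c(0.05, 0.2), seed = 3,
                                      stages = c(1e3, 1e4), escalate_p = 0.1))
})

test_that("an extreme gene is floored and read as p < 1/n_sims", {
  r <- adaptive_gene_test(1e-12, stages = c(1e3), escalate_p = numeric(0),
                          seed = 2)
  expect_true(r$floored)
  expect_equal(r$p, 0)
})

test_that("single-SNP gene p converges to the SNP p", {
  p_snp <- 0.07
  r <- adaptive_gene_test(p_snp, stages = 1e4, escalate_p = numeric(0),
                          seed = 13)
  mc_se <- sqrt(p_snp * (1 - p_snp) / 1e4)
  expect_lt(abs(r$p - p_snp), 3 * mc_se)
})

test_that("gene_test_all joins association, map and LD; empty genes go NA", {
  g <- simulate_genotypes(300, list(list(n_snps = 6, ld_rho = 0.5,
                                         maf_range = c(0.2, 0.5))), seed = 21)
  ph <- simulate_phenotype(g, noise_sd = 1, seed = 22)
  assoc <- snp_association(g, ph$y)
  map <- data.frame(snp = c(g$snps$snp, "rs_unknown"),
                    gene = c(rep(c("GA", "GB"), each = 3), "GC"))
  res <- suppressMessages(
    gene_test_all(assoc, map, geno = g, stages = 1e3,
                  escalate_p = numeric(0), seed = 23))
  expect_setequal(res$gene, c("GA", "GB", "GC"))
  expect_true(is.na(res$p[res$gene == "GC"]))
  expect_equal(res$n_snps[res$gene == "GA"], 3)
  expect_true(all(res$p[!is.na(res$p)] >= 0 & res$p[!is.na(res$p)] <= 1))
})

test_that("bonferroni_threshold divides alpha by the gene count", {
  expect_equal(signif(bonferroni_threshold(0.05, 22179), 3), 2.25e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})
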