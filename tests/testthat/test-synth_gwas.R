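test_that("genotype simulation is deterministic and honours Hardy-Weinberg means", {
  blocks <- list(list(n_snps = 3, ld_rho = 0.5, maf_range = c(0.1, 0.4)))
  g1 <- simulate_genotypes(200, blocks, seed = 7)
  g2 <- simulate_genotypes(200, blocks, seed = 7)
  expect_identical(g1$dosage, g2$dosage)
  expect_true(all(g1$dosage %in% 0:2))

  one <- simulate_genotypes(10000,
                            list(list(n_snps = 1, ld_rho = 0,
                                      maf_range = c(0.5, 0.5))), seed = 1)
  expect_lt(abs(mean(one$dosage) - 1.0), 0.05)

  expect_error(simulate_genotypes(100,
                                  list(list(n_snps = 1, ld_rho = 0,
                                            maf_range = c(0, 0.6)))),
               "maf_range")
})

test_that("ld_rho = 0 yields near-independent SNPs", {
  g <- simulate_genotypes(2000,
                          list(list(n_snps = 20, ld_rho = 0,
                                    maf_range = c(0.2, 0.5))), seed = 3)
  R <- cor(g$dosage)
  off <- abs(R[upper.tri(R)])
  expect_lt(mean(off), 0.05)
})

test_that("blocks with high ld_rho are internally correlated, independent across", {
  g <- simulate_genotypes(2000,
                          list(list(n_snps = 5, ld_rho = 0.9,
                                    maf_range = c(0.3, 0.5)),
                               list(n_snps = 5, ld_rho = 0.9,
                                    maf_range = c(0.3, 0.5))), seed = 4)
  R <- cor(g$dosage)
  within <- R[1, 2] # adjacent in block 1
  across <- abs(R[1:5, 6:10])
  expect_gt(within, 0.5)
  expect_lt(mean(across), 0.05)
})

test_that("phenotype with zero noise and one causal SNP is an exact linear map", {
  g <- simulate_genotypes(50, list(list(n_snps = 2, ld_rho = 0,
                                        maf_range = c(0.3, 0.5))), seed = 5)
  snp <- g$snps$snp[1]
  ph <- simulate_phenotype(g, causal = setNames(2.5, snp), noise_sd = 0,
                           seed = 6)
  expect_equal(ph$y, 2.5 * g$dosage[, snp], tolerance = 1e-12)

  expect_error(simulate_phenotype(g, causal = c(nope = 1)), "causal")
  expect_error(simulate_phenotype(g, noise_sd = -1))
})

test_that("qc_filter applies call-rate, MAF and HWE rules and conserves counts", {
  set.seed(11)
  g <- simulate_genotypes(100, list(list(n_snps = 5, ld_rho = 0,
                                         maf_range = c(0.2, 0.4))), seed = 11)
  # SNP 1: 10% missing; SNP 2: exact HW proportions (25/50/25); SNP 3: rare
  G <- g$dosage
  G[1:10, 1] <- NA
  G[, 2] <- rep(c(0, 1, 2), times = c(25, 50, 25))
  G[, 3] <- c(rep(1, 7), rep(0, 93)) # 7 minor alleles / 200
  g$dosage <- G
  res <- qc_filter(g, call_rate_min = 0.95, maf_min = 0.05, hwe_p_min = 1e-6)
  excluded <- res$report$snp
  expect_true(g$snps$snp[1] %in% excluded)
  expect_match(res$report$reason[res$report$snp == g$snps$snp[1]], "call_rate")
  expect_false(g$snps$snp[2] %in% excluded) # chi2 = 0, p = 1
  expect_true(g$snps$snp[3] %in% excluded)
  expect_match(res$report$reason[res$report$snp == g$snps$snp[3]], "maf")
  # conservation
  expect_equal(nrow(res$report) + ncol(res$geno$dosage), ncol(G))
})

test_that("hwe test is exact-zero on perfect HW proportions", {
  expect_equal(gwasnet:::hwe_chisq_p(25, 50, 25), 1)
  expect_lt(gwasnet:::hwe_chisq_p(50, 0, 50), 1e-6) # no hets: strong violation
})

test_that("snp_association: perfect fit underflows, constants flagged, reruns identical", {
  g <- simulate_genotypes(60, list(list(n_snps = 3, ld_rho = 0,
                                        maf_range = c(0.3, 0.5))), seed = 21)
  y <- as.numeric(g$dosage[, 1])
  a <- snp_association(g, y)
  expect_lt(a$p[1], 1e-12)

  g$dosage[, 2] <- 1L # constant column
  a2 <- snp_association(g, y)
  expect_equal(a2$p[2], 1)
  expect_true(a2$monomorphic[2])

  a3 <- snp_association(g, y)
  expect_identical(a2$p, a3$p)
})

test_that("type-I error of the per-SNP test is nominal under permuted traits", {
  g <- simulate_genotypes(1000, list(list(n_snps = 200, ld_rho = 0,
                                          maf_range = c(0.1, 0.5))), seed = 31)
  ph <- simulate_phenotype(g, causal = NULL, noise_sd = 1, seed = 32)
  a <- snp_association(g, ph$y, ph$covariates)
  expect_lt(abs(mean(a$p < 0.05) - 0.05), 0.03)
})

test_that("a strong causal SNP is detected with extreme significance", {
  g <- simulate_genotypes(1000, list(list(n_snps = 5, ld_rho = 0,
                                          maf_range = c(0.3, 0.5))), seed = 41)
  snp <- g$snps$snp[3]
  vg <- var(g$dosage[, snp])
  beta <- sqrt(1 / vg) # R^2 ~ 0.5 with noise_sd = 1
  ph <- simulate_phenotype(g, causal = setNames(beta, snp), noise_sd = 1,
                           seed = 42)
  a <- snp_association(g, ph$y)
  expect_lt(a$p[a$snp == snp], 1e-10)
})

test_that("drop-individuals mode agrees with imputation when nothing is missing", {
  g <- simulate_genotypes(80, list(list(n_snps = 4, ld_rho = 0,
                                        maf_range = c(0.2, 0.5))), seed = 51)
  ph <- simulate_phenotype(g, noise_sd = 1, seed = 52)
  ai <- snp_association(g, ph$y, ph$covariates, missing = "impute")
  ad <- snp_association(g, ph$y, ph$covariates, missing = "drop")
  expect_equal(ai$p, ad$p, tolerance = 1e-10)
})

test_that("assign_snps_to_genes is positional, many-to-many, flank-aware", {
  snps <- data.frame(snp = c("s1", "s2", "s3"), chrom = "1",
                     pos = c(100L, 250L, 900L))
  genes <- data.frame(gene = c("GA", "GB"), chrom = "1",
                      start = c(50L, 200L), end = c(300L, 260L))
  m <- assign_snps_to_genes(snps, genes)
  expect_setequal(m$gene[m$snp == "s2"], c("GA", "GB")) # overlapping genes
  expect_false("s3" %in% m$snp)
  m2 <- assign_snps_to_genes(snps, genes, flank = 700)
  expect_true("s3" %in% m2$snp)
})
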