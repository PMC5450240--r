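#' Chi-square statistic of a SNP p-value
#'
#' Inverts the 1-df chi-square upper tail: returns the statistic whose
#' upper-tail probability equals `p`.
#'
#' @param p SNP p-value(s) in `(0, 1]`.
#' @return The 1-df chi-square value(s).
#' @export
snp_chi2 <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("snp_chi2 requires p in (0, 1]; clamp upstream")
  }
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

#' Gene-level sum-of-chi-squares statistic
#'
#' The gene statistic is the sum of the per-SNP 1-df chi-square statistics of
#' the SNPs assigned to the gene. P-values are clamped to `[1e-15, 1]` before
#' inversion, so a SNP with `p = 1` contributes exactly 0.
#'
#' @param snp_ps Non-empty vector of SNP p-values.
#' @return The statistic `Q >= 0`.
#' @export
gene_statistic <- function(snp_ps) {
  if (!length(snp_ps)) stop("gene_statistic needs at least one SNP p-value")
  sum(snp_chi2(clamp_p(snp_ps)))
}

#' Pairwise LD correlation of a gene's SNPs
#'
#' Pearson correlation of dosage columns, with rows/columns of zero-variance
#' SNPs replaced by identity rows (warning), and a nearest-positive-
#' semidefinite repair (eigenvalue clipping at `1e-8`) when needed.
#'
#' @param G_sub Dosage matrix (individuals x SNPs) for one gene.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
ld_correlation <- function(G_sub) {
  G_sub <- as.matrix(G_sub)
  if (nrow(G_sub) < 3) stop("need at least 3 individuals for LD estimation")
  m <- ncol(G_sub)
  v <- apply(G_sub, 2, stats::var, na.rm = TRUE)
  zero <- !is.finite(v) | v < 1e-12
  R <- suppressWarnings(stats::cor(G_sub, use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance SNP(s); correlation rows set to identity",
                    sum(zero)))
    R[zero, ] <- 0; R[, zero] <- 0
  }
  diag(R) <- 1
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 && m > 1) {
    es <- eigen(R, symmetric = TRUE)
    d <- pmax(es$values, 1e-8)
    R <- es$vectors %*% (d * t(es$vectors))
    R <- (R + t(R)) / 2
  }
  R
}

#' Simulate the null distribution of the gene statistic
#'
#' Draws `n_sims` vectors from a multivariate normal with covariance `Sigma`
#' (the SNP LD correlation) and returns the sum of squares of each draw: the
#' null sample of the gene statistic under LD.
#'
#' @param Sigma SNP correlation matrix (positive semidefinite after repair).
#' @param n_sims Number of simulations.
#' @param seed Optional RNG seed.
#' @return Numeric vector of `n_sims` null statistics.
#' @export
simulate_null_Q <- function(Sigma, n_sims, seed = NULL) {
  Sigma <- as.matrix(Sigma)
  m <- ncol(Sigma)
  es <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  d <- es$values
  if (min(d) < -1e-6) stop("Sigma is not positive semidefinite after repair")
  A <- es$vectors %*% diag(sqrt(pmax(d, 0)), m) # cov(N %*% t(A)) = Sigma
  with_seed_opt(seed, {
    out <- numeric(n_sims)
    chunk <- max(1L, min(n_sims, floor(2e7 / m)))
    done <- 0L
    while (done < n_sims) {
      k <- min(chunk, n_sims - done)
      Z <- matrix(stats::rnorm(k * m), k, m) %*% t(A)
      out[done + seq_len(k)] <- rowSums(Z^2)
      done <- done + k
    }
    out
  })
}

#' Empirical p-value from a null sample
#'
#' `p = (# null >= Q_obs) / n`. A tail count of zero is reported as `p = 0`
#' with `floored = TRUE`, to be displayed as `< 1/n`.
#'
#' @param Q_obs Observed statistic.
#' @param null_sample Non-empty numeric vector of null statistics.
#' @return List with `p`, `floored`, `n_sims`.
#' @export
empirical_p <- function(Q_obs, null_sample) {
  n <- length(null_sample)
  if (!n) stop("empty null sample")
  cnt <- sum(null_sample >= Q_obs)
  list(p = cnt / n, floored = cnt == 0L, n_sims = n)
}

#' Adaptive gene-based association test
#'
#' Computes the gene statistic and its empirical p-value by multivariate-
#' normal simulation under the SNP LD correlation, with a three-stage
#' schedule: 10^3 simulations for every gene; 10^4 only if the stage-1 p is
#' <= 0.1; 10^6 only if the stage-2 p is <= 0.001. The returned p carries the
#' final stage's simulation count; an empty upper tail at the final stage is
#' flagged `floored` (read as `p < 1/n_sims`).
#'
#' @param snp_ps SNP p-values for the gene.
#' @param Sigma SNP LD correlation; `NULL` for independence (identity).
#' @param stages Simulation counts per stage.
#' @param escalate_p Escalation thresholds between consecutive stages.
#' @param seed Optional RNG seed.
#' @return List with `Q`, `p`, `n_sims`, `floored`, `n_snps`.
#' @export
adaptive_gene_test <- function(snp_ps, Sigma = NULL,
                               stages = c(1e3, 1e4, 1e6),
                               escalate_p = c(0.1, 0.001),
                               seed = NULL) {
  m <- length(snp_ps)
  if (!m) stop("no SNP p-values supplied")
  if (is.null(Sigma)) Sigma <- diag(m)
  stopifnot(ncol(as.matrix(Sigma)) == m, length(escalate_p) == length(stages) - 1)
  Q <- gene_statistic(snp_ps)
  with_seed_opt(seed, {
    res <- NULL
    for (s in seq_along(stages)) {
      null_s <- simulate_null_Q(Sigma, stages[s])
      res <- empirical_p(Q, null_s)
      if (s < length(stages) && res$p > escalate_p[s]) break
    }
    list(Q = Q, p = res$p, n_sims = res$n_sims, floored = res$floored,
         n_snps = m)
  })
}

#' Gene-based tests for all genes
#'
#' Runs [adaptive_gene_test()] for every gene in a SNP-to-gene map, taking
#' SNP p-values from an association table and, when genotypes are given, the
#' LD correlation from the gene's dosage columns (identity otherwise, an
#' LD-free approximation). Genes with no assigned SNP present in the
#' association table get `p = NA` and are excluded downstream.
#'
#' @param assoc SNP association `data.frame` (`snp`, `p`).
#' @param snp_gene_map `data.frame` (`snp`, `gene`); many-to-many.
#' @param geno Optional `genotype_matrix` for LD estimation.
#' @param stages,escalate_p Passed to [adaptive_gene_test()].
#' @param seed Optional RNG seed governing all simulations.
#' @return `data.frame` with `gene`, `n_snps`, `Q`, `p`, `n_sims`, `floored`.
#' @export
gene_test_all <- function(assoc, snp_gene_map, geno = NULL,
                          stages = c(1e3, 1e4, 1e6),
                          escalate_p = c(0.1, 0.001), seed = NULL) {
  pmap <- stats::setNames(assoc$p, assoc$snp)
  genes <- unique(snp_gene_map$gene)
  with_seed_opt(seed, {
    rows <- lapply(genes, function(g) {
      snps <- intersect(snp_gene_map$snp[snp_gene_map$gene == g], names(pmap))
      if (!length(snps)) {
        return(data.frame(gene = g, n_snps = 0L, Q = NA_real_, p = NA_real_,
                          n_sims = NA_integer_, floored = NA))
      }
      Sigma <- NULL
      if (!is.null(geno)) {
        cols <- intersect(snps, colnames(geno$dosage))
        if (length(cols) == length(snps) && length(cols) > 1) {
          Sigma <- suppressWarnings(
            ld_correlation(geno$dosage[, cols, drop = FALSE]))
        }
      }
      r <- adaptive_gene_test(pmap[snps], Sigma, stages, escalate_p)
      data.frame(gene = g, n_snps = r$n_snps, Q = r$Q, p = r$p,
                 n_sims = r$n_sims, floored = r$floored)
    })
    out <- do.call(rbind, rows)
    n_empty <- sum(is.na(out$p))
    if (n_empty) {
      message(sprintf("gene_test_all: %d gene(s) with no assigned SNPs (p = NA)",
                      n_empty))
    }
    out
  })
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in `(0, 1)`.
#' @param n_genes Number of genes tested (>= 1).
#' @return `alpha / n_genes`.
#' @examples
#' bonferroni_threshold(0.05, 22179) # ~2.25e-6
#' @export
bonferroni_threshold <- function(alpha, n_genes) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  stopifnot(n_genes >= 1)
  alpha / n_genes
}
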