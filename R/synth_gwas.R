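#' Simulate LD-blocked genotype dosages
#'
#' Generates an individuals-by-SNPs dosage matrix with block-wise linkage
#' disequilibrium. Within a block, two latent haplotype series follow an AR(1)
#' Gaussian process with lag-one correlation `ld_rho`; each series is
#' thresholded at the MAF-matched normal quantile so that allele frequencies
#' hit the requested range, and the two allele indicators sum to the dosage.
#' Blocks are mutually independent.
#'
#' @param n_ind Number of individuals (>= 2).
#' @param blocks A list of block specifications, each a list with elements
#'   `n_snps` (count), `ld_rho` (lag-one haplotype correlation in `[0,1)`) and
#'   `maf_range` (length-2 vector inside `(0, 0.5]`).
#' @param missing_rate Fraction of dosages set missing at random (default 0).
#' @param seed Optional RNG seed; the same seed reproduces the same matrix.
#' @return An object of class `genotype_matrix`: a list with `dosage`
#'   (`n_ind` x `n_snps` integer matrix with `NA` for missing) and `snps`
#'   (data.frame `snp`, `chrom`, `pos`, `block`, `maf`).
#' @export
simulate_genotypes <- function(n_ind, blocks, missing_rate = 0, seed = NULL) {
  stopifnot(n_ind >= 2, missing_rate >= 0, missing_rate < 1)
  with_seed_opt(seed, {
    dos <- list(); info <- list(); pos0 <- 0L
    for (b in seq_along(blocks)) {
      bl <- blocks[[b]]
      m <- bl$n_snps
      rho <- bl$ld_rho %||% 0
      stopifnot(m >= 1, rho >= 0, rho < 1)
      mr <- bl$maf_range %||% c(0.05, 0.5)
      if (any(mr <= 0) || any(mr > 0.5)) {
        stop("maf_range must lie in (0, 0.5]")
      }
      maf <- stats::runif(m, mr[1], mr[2])
      thr <- stats::qnorm(maf)
      hap <- function() {
        h <- matrix(stats::rnorm(n_ind * m), n_ind, m)
        if (rho > 0 && m > 1) {
          for (j in 2:m) h[, j] <- rho * h[, j - 1] + sqrt(1 - rho^2) * h[, j]
        }
        sweep(h, 2, thr, `<`) * 1L
      }
      g <- hap() + hap()
      dos[[b]] <- g
      info[[b]] <- data.frame(
        snp = sprintf("rs_b%d_%04d", b, seq_len(m)),
        chrom = "1",
        pos = pos0 + seq_len(m) * 1000L,
        block = b,
        maf = maf,
        stringsAsFactors = FALSE)
      pos0 <- pos0 + m * 1000L
    }
    G <- do.call(cbind, dos)
    snps <- do.call(rbind, info)
    colnames(G) <- snps$snp
    if (missing_rate > 0) {
      G[stats::runif(length(G)) < missing_rate] <- NA
    }
    structure(list(dosage = G, snps = snps), class = "genotype_matrix")
  })
}

#' Simulate a quantitative trait from genotypes
#'
#' Builds an additive phenotype `y = sum(beta * dosage) + covariate effects +
#' Normal(0, noise_sd)`, together with study-style covariates: a continuous
#' age-like variable, a binary sex indicator, and a five-level diagnosis
#' factor (dummy-coded downstream with one level dropped to keep the design
#' full rank).
#'
#' @param geno A `genotype_matrix`.
#' @param causal Named numeric vector of per-SNP effect sizes (names must be
#'   SNP ids present in `geno`); `NULL` for a pure-null trait.
#' @param covariate_betas Optional list with elements `age`, `sex`, and `dx`
#'   (length-4 vector for the non-reference diagnosis levels); defaults to 0.
#' @param noise_sd Residual standard deviation (>= 0).
#' @param seed Optional RNG seed.
#' @return A list with `y` (numeric vector) and `covariates` (data.frame with
#'   `age`, `sex`, `dx`).
#' @export
simulate_phenotype <- function(geno, causal = NULL, covariate_betas = NULL,
                               noise_sd = 1, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), noise_sd >= 0)
  G <- geno$dosage
  n <- nrow(G)
  if (!is.null(causal) && length(causal)) {
    missing_snps <- setdiff(names(causal), colnames(G))
    if (length(missing_snps)) {
      stop("causal SNP(s) not in genotype matrix: ",
           paste(missing_snps, collapse = ", "))
    }
  }
  with_seed_opt(seed, {
    age <- stats::rnorm(n, 72, 7)
    sex <- stats::rbinom(n, 1, 0.5)
    dx <- factor(sample(c("CN", "SMC", "EMCI", "LMCI", "AD"), n, replace = TRUE,
                        prob = c(199, 85, 239, 207, 113) / 843),
                 levels = c("CN", "SMC", "EMCI", "LMCI", "AD"))
    cb <- covariate_betas %||% list()
    y <- stats::rnorm(n, 0, noise_sd) +
      (cb$age %||% 0) * age + (cb$sex %||% 0) * sex
    dxb <- cb$dx %||% rep(0, 4)
    y <- y + c(0, dxb)[as.integer(dx)]
    if (!is.null(causal) && length(causal)) {
      Gc <- G[, names(causal), drop = FALSE]
      # mean-impute missing dosages for the generative step
      for (j in seq_len(ncol(Gc))) {
        nas <- is.na(Gc[, j])
        if (any(nas)) Gc[nas, j] <- mean(Gc[, j], na.rm = TRUE)
      }
      y <- y + as.numeric(Gc %*% causal)
    }
    list(y = y, covariates = data.frame(age = age, sex = sex, dx = dx))
  })
}

# 1-df chi-square Hardy-Weinberg test from genotype counts (n0, n1, n2).
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(1)
  p <- (2 * n2 + n1) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(n0, n1, n2)
  ok <- e > 0
  if (!any(ok)) return(1)
  x2 <- sum((o[ok] - e[ok])^2 / e[ok])
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Quality-control filter for SNPs
#'
#' Excludes SNPs failing per-SNP call rate, minor allele frequency, or the
#' 1-df chi-square Hardy-Weinberg test; defaults follow the common GWAS
#' thresholds (call rate >= 95%, MAF >= 5%, HWE p >= 1e-6).
#'
#' @param geno A `genotype_matrix`.
#' @param call_rate_min Minimum fraction of non-missing dosages per SNP.
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min Minimum Hardy-Weinberg p-value.
#' @return A list with `geno` (filtered `genotype_matrix`) and `report`
#'   (data.frame `snp`, `reason` for every excluded SNP; reasons are
#'   `;`-joined when several criteria fail).
#' @export
qc_filter <- function(geno, call_rate_min = 0.95, maf_min = 0.05,
                      hwe_p_min = 1e-6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  assert_prob(c(call_rate_min, maf_min, hwe_p_min), "QC threshold")
  G <- geno$dosage
  call_rate <- colMeans(!is.na(G))
  f <- colMeans(G, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  maf <- pmin(f, 1 - f)
  hwe <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]; g <- g[!is.na(g)]
    hwe_chisq_p(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  fail <- cbind(call_rate = call_rate < call_rate_min,
                maf = maf < maf_min,
                hwe = hwe < hwe_p_min)
  excl <- rowSums(fail) > 0
  reason <- apply(fail, 1, function(x) paste(colnames(fail)[x], collapse = ";"))
  report <- data.frame(snp = colnames(G)[excl], reason = reason[excl],
                       stringsAsFactors = FALSE)
  keep <- !excl
  if (!any(keep)) warning("qc_filter: no SNP passed quality control")
  out <- structure(list(dosage = G[, keep, drop = FALSE],
                        snps = geno$snps[keep, , drop = FALSE]),
                   class = "genotype_matrix")
  list(geno = out, report = report)
}

#' Per-SNP association by ordinary least squares
#'
#' For each SNP, regresses the trait on dosage plus covariates and reports the
#' two-sided p-value for the dosage coefficient (additive model). Covariates
#' are projected out of trait and dosages, so the test equals the full-model
#' t-test on the dosage term. Missing dosages are mean-imputed per SNP by
#' default; `missing = "drop"` instead drops individuals SNP-wise.
#'
#' @param geno A `genotype_matrix`.
#' @param y Numeric trait vector, no missing values.
#' @param covariates Optional covariate `data.frame` (factors dummy-coded with
#'   the first level as reference).
#' @param missing `"impute"` (default) or `"drop"`.
#' @return A `data.frame` with columns `snp`, `chrom`, `pos`, `p`, and
#'   `monomorphic` (flag; such SNPs get `p = 1`).
#' @export
snp_association <- function(geno, y, covariates = NULL,
                            missing = c("impute", "drop")) {
  missing <- match.arg(missing)
  stopifnot(inherits(geno, "genotype_matrix"))
  G <- geno$dosage
  n <- nrow(G)
  if (length(y) != n || anyNA(y)) {
    stop("y must be complete and of length nrow(dosage)")
  }
  X0 <- if (is.null(covariates)) {
    matrix(1, n, 1)
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  if (qr(X0)$rank < ncol(X0)) stop("covariate design matrix is rank deficient")

  fit_one <- function(g, yy, X) {
    qx <- qr(X)
    ry <- qr.resid(qx, yy)
    rg <- qr.resid(qx, g)
    sgg <- sum(rg^2)
    if (sgg < 1e-12) return(c(p = 1, mono = 1))
    beta <- sum(rg * ry) / sgg
    df <- length(yy) - ncol(X) - 1L
    if (df <= 0) return(c(p = 1, mono = 1))
    s2 <- max(0, (sum(ry^2) - beta^2 * sgg)) / df
    tt <- if (s2 == 0) Inf else beta / sqrt(s2 / sgg)
    c(p = 2 * stats::pt(-abs(tt), df), mono = 0)
  }

  if (missing == "impute") {
    qx <- qr(X0)
    ry <- qr.resid(qx, y)
    nas <- is.na(G)
    if (any(nas)) {
      mu <- colMeans(G, na.rm = TRUE)
      mu[is.nan(mu)] <- 0
      G[nas] <- mu[col(G)[nas]]
    }
    RG <- qr.resid(qx, G)
    sgg <- colSums(RG^2)
    mono <- sgg < 1e-12
    beta <- ifelse(mono, 0, colSums(RG * ry) / pmax(sgg, 1e-300))
    df <- n - ncol(X0) - 1L
    s2 <- pmax(0, sum(ry^2) - beta^2 * sgg) / df
    tt <- ifelse(s2 == 0, Inf, beta / sqrt(s2 / pmax(sgg, 1e-300)))
    p <- ifelse(mono, 1, 2 * stats::pt(-abs(tt), df))
  } else {
    res <- vapply(seq_len(ncol(G)), function(j) {
      ok <- !is.na(G[, j])
      if (sum(ok) < ncol(X0) + 2L) return(c(p = 1, mono = 1))
      fit_one(G[ok, j], y[ok], X0[ok, , drop = FALSE])
    }, c(p = 0, mono = 0))
    p <- res["p", ]; mono <- res["mono", ] > 0
  }
  data.frame(snp = geno$snps$snp, chrom = geno$snps$chrom,
             pos = geno$snps$pos, p = unname(p),
             monomorphic = unname(mono), stringsAsFactors = FALSE)
}

#' Assign SNPs to genes by position
#'
#' Builds a many-to-many SNP-to-gene map from positional annotation: a SNP is
#' assigned to every gene whose `[start - flank, end + flank]` interval on the
#' same chromosome contains it.
#'
#' @param snps `data.frame` with `snp`, `chrom`, `pos`.
#' @param genes `data.frame` with `gene`, `chrom`, `start`, `end`.
#' @param flank Flanking window in bp added to both gene ends (default 0).
#' @return `data.frame` with columns `snp`, `gene`.
#' @export
assign_snps_to_genes <- function(snps, genes, flank = 0) {
  stopifnot(flank >= 0)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- snps$chrom == genes$chrom[i] &
      snps$pos >= genes$start[i] - flank &
      snps$pos <= genes$end[i] + flank
    if (!any(hit)) return(NULL)
    data.frame(snp = snps$snp[hit], gene = genes$gene[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out %||% data.frame(snp = character(0), gene = character(0))
}
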