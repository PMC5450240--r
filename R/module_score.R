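#' Probit transform of a p-value
#'
#' `z = qnorm(1 - p)`: the standard Liptak-Stouffer convention for one-sided
#' significance aggregation, so smaller p gives larger z. P-values are clamped
#' to `[1e-15, 1 - 1e-15]` first.
#'
#' @param p P-value(s).
#' @return Finite z value(s).
#' @export
z_transform <- function(p) {
  stats::qnorm(clamp_p(p, 1e-15, 1 - 1e-15), lower.tail = FALSE)
}

# Fast vector form used throughout search: Z = sum(w z) / sqrt(sum(w^2)).
weighted_z <- function(w, z) {
  s2 <- sum(w^2)
  if (s2 == 0) stop("network_zscore: all node weights are zero")
  sum(w * z) / sqrt(s2)
}

#' Weighted Z network score of a gene set
#'
#' The Liptak-Stouffer combination of the genes' probit z values, weighted by
#' their smoothed node weights: `Z_A = sum(w_i z_i) / sqrt(sum(w_i^2))`. With
#' equal weights this reduces to the classical Stouffer statistic
#' `sum(z)/sqrt(k)`; it is invariant to uniform rescaling of the weights.
#'
#' @param genes Character vector of genes in the set.
#' @param scores Per-gene table with `gene`, `z`, `weight` columns (e.g. the
#'   `scores` element of a [smooth_scores()] result).
#' @return The raw network score `Z_A`.
#' @export
network_zscore <- function(genes, scores) {
  i <- match(genes, scores$gene)
  if (anyNA(i)) {
    stop("gene(s) without score: ",
         paste(utils::head(genes[is.na(i)], 5), collapse = ", "))
  }
  weighted_z(scores$weight[i], scores$z[i])
}

#' Calibrate the background distribution of the network score
#'
#' For every size `k` in `1..k_max`, draws `n_draws` uniform random gene sets
#' (no connectivity requirement) and records the mean and standard deviation
#' of their weighted Z score. The table standardizes raw scores into adjusted
#' scores via [adjusted_score()].
#'
#' @param scores Per-gene table with `gene`, `z`, `weight`.
#' @param k_max Largest set size calibrated (default 500).
#' @param n_draws Random sets per size (default 1000).
#' @param seed Optional RNG seed; by default draws from the current stream,
#'   which is what makes repeated search runs stochastic.
#' @return `data.frame` with columns `k`, `mu`, `sigma`, `n_draws`.
#' @export
calibrate_background <- function(scores, k_max = 500, n_draws = 1000,
                                 seed = NULL) {
  n <- nrow(scores)
  if (k_max > n) stop("k_max exceeds the number of scored genes")
  w <- scores$weight; z <- scores$z
  with_seed_opt(seed, {
    mu <- numeric(k_max); sg <- numeric(k_max)
    for (k in seq_len(k_max)) {
      idx <- vapply(seq_len(n_draws), function(d) sample.int(n, k),
                    integer(k))
      idx <- matrix(idx, nrow = k)
      W <- matrix(w[idx], nrow = k)
      Zm <- matrix(z[idx], nrow = k)
      num <- colSums(W * Zm)
      den <- sqrt(colSums(W^2))
      Zs <- ifelse(den > 0, num / den, 0)
      mu[k] <- mean(Zs)
      sg[k] <- stats::sd(Zs)
    }
    if (any(sg <= 0 | !is.finite(sg))) {
      stop("degenerate background: zero variance of Z at some size k")
    }
    data.frame(k = seq_len(k_max), mu = mu, sigma = sg, n_draws = n_draws)
  })
}

#' Background-adjusted network score
#'
#' Standardizes a raw score against the random-set background of the same
#' size: `S_A = (Z_A - mu_k) / sigma_k`.
#'
#' @param Z Raw network score.
#' @param k Gene-set size.
#' @param bg Background table from [calibrate_background()].
#' @return The adjusted score `S_A`.
#' @export
adjusted_score <- function(Z, k, bg) {
  if (k < 1 || k > max(bg$k)) {
    stop("set size ", k, " outside calibrated range; re-run ",
         "calibrate_background() with k_max >= ", k)
  }
  i <- match(k, bg$k)
  (Z - bg$mu[i]) / bg$sigma[i]
}
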