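#' Search parameter set
#'
#' Bundles the module-search thresholds: the adjusted-score cutoff
#' (`min_score`, modules must exceed it strictly), size limits, and the number
#' of background draws per size used in each run's calibration.
#'
#' @param min_score Minimum adjusted score `S` a reported module must exceed
#'   (default 3.0).
#' @param min_size Minimum module size (default 5).
#' @param max_size Maximum module size, also the background `k_max`
#'   (default 300).
#' @param bg_draws Background draws per size (default 1000).
#' @return A list of class `search_params`.
#' @export
search_params <- function(min_score = 3.0, min_size = 5, max_size = 300,
                          bg_draws = 1000) {
  stopifnot(min_size >= 1, max_size >= min_size, bg_draws >= 2)
  structure(list(min_score = min_score, min_size = min_size,
                 max_size = max_size, bg_draws = bg_draws),
            class = "search_params")
}

# Core greedy growth on integer indices with incremental score updates.
# Each step adds the neighbor maximizing the raw weighted Z (strict
# improvement required); the returned module is the growth prefix that
# maximizes the adjusted score S. Hill-climbing directly on S stalls at tiny
# sizes because sigma_k rises steeply with k before the signal accumulates;
# the raw score is monotone along a significant module, so it drives the
# expansion and S picks the stopping size.
# adj: list of integer neighbor vectors; w, z, p: node vectors; mu, sigma:
# background moments indexed by size.
grow_module_idx <- function(start_i, adj, w, z, p, genes, mu, sigma,
                            max_size, n_draws = Inf) {
  members <- integer(max_size)
  members[1L] <- start_i
  in_set <- logical(length(w)); in_set[start_i] <- TRUE
  swz <- w[start_i] * z[start_i]
  sw2 <- w[start_i]^2
  Z <- if (sw2 > 0) swz / sqrt(sw2) else -Inf
  S_path <- rep(-Inf, max_size)
  Z_path <- rep(-Inf, max_size)
  S_path[1L] <- (Z - mu[1]) / sigma[1]
  Z_path[1L] <- Z
  cand <- adj[[start_i]][!in_set[adj[[start_i]]]]
  k <- 1L
  while (k < max_size && length(cand)) {
    Znew <- (swz + w[cand] * z[cand]) / sqrt(sw2 + w[cand]^2)
    # ties: smaller gene p first, then lexicographic symbol
    best <- order(-Znew, p[cand], genes[cand])[1L]
    if (!(Znew[best] > Z)) break
    g <- cand[best]
    k <- k + 1L
    members[k] <- g
    in_set[g] <- TRUE
    swz <- swz + w[g] * z[g]
    sw2 <- sw2 + w[g]^2
    Z <- Znew[best]
    Z_path[k] <- Z
    S_path[k] <- (Z - mu[k]) / sigma[k]
    cand <- unique(c(cand[-best], adj[[g]]))
    cand <- cand[!in_set[cand]]
  }
  # The background moments are Monte-Carlo estimates, so S values closer to
  # the path maximum than their sampling error are indistinguishable; take
  # the smallest prefix within one delta-method standard error of the best
  # (se^2(S) ~ (1 + S^2/2)/n_draws from the mu and sigma estimates).
  S_seen <- S_path[seq_len(k)]
  S_max <- max(S_seen)
  se <- sqrt((1 + S_max^2 / 2) / n_draws)
  kbest <- which(S_seen >= S_max - se)[1L]
  list(genes = genes[members[seq_len(kbest)]], start = genes[start_i],
       size = kbest, Z = Z_path[kbest], S = S_path[kbest])
}

#' Grow one module greedily from a start gene
#'
#' Starting from the singleton, repeatedly evaluates the raw weighted-Z score
#' of the current set plus each neighboring gene and adds the neighbor giving
#' the largest score, provided it strictly exceeds the current one and the
#' size stays within `max_size`; the returned module is the prefix of this
#' growth path with the largest background-adjusted score `S`. Ties among
#' candidate neighbors are broken by smaller gene p, then lexicographic
#' symbol, so growth is deterministic.
#'
#' @param start Start gene symbol.
#' @param network A `gwas_network` from [smooth_scores()].
#' @param bg Background table from [calibrate_background()].
#' @param max_size Maximum module size (default 300; capped at the
#'   background's `k_max`).
#' @return A list of class `subnetwork`: `genes`, `start`, `size`, `Z`, `S`.
#' @export
grow_module <- function(start, network, bg, max_size = 300) {
  sc <- network$scores
  start_i <- match(start, sc$gene)
  if (is.na(start_i)) stop("start gene not in network: ", start)
  max_size <- min(max_size, max(bg$k))
  adj <- lapply(igraph::as_adj_list(network$graph), as.integer)
  nd <- if ("n_draws" %in% names(bg)) bg$n_draws[1] else Inf
  out <- grow_module_idx(start_i, adj, sc$weight, sc$z, sc$p, sc$gene,
                         bg$mu, bg$sigma, max_size, nd)
  structure(out, class = "subnetwork")
}

#' One stochastic search run
#'
#' Sets the run's RNG seed, calibrates a run-specific background, then grows
#' one module from every seed gene in RNG-shuffled order. Modules are kept if
#' their adjusted score strictly exceeds `min_score` and their size lies in
#' `[min_size, max_size]`; exact-duplicate gene sets are collapsed (first
#' kept) and survivors ranked by decreasing adjusted score (ties by gene-set
#' key, so ordering is deterministic given the seed).
#'
#' @param network A `gwas_network` from [smooth_scores()].
#' @param params A [search_params()] list.
#' @param seed Integer RNG seed for this run (the source of between-run
#'   stochasticity); `NULL` uses the current RNG stream.
#' @param background Optional shared background table; by default a fresh one
#'   is calibrated inside the run from its own RNG.
#' @return A list of class `search_run`: `seed`, `modules` (ranked
#'   `subnetwork` list), `top` (first module or `NULL`), `background`,
#'   `n_modules`.
#' @export
search_run <- function(network, params = search_params(), seed = NULL,
                       background = NULL) {
  sc <- network$scores
  seed_idx <- which(sc$seed)
  if (!length(seed_idx)) stop("network has no seed genes")
  run <- function() {
    bg <- background %||%
      calibrate_background(sc, k_max = params$max_size,
                           n_draws = params$bg_draws)
    max_size <- min(params$max_size, max(bg$k))
    adj <- lapply(igraph::as_adj_list(network$graph), as.integer)
    starts <- sample(seed_idx)
    mods <- lapply(starts, function(i) {
      structure(grow_module_idx(i, adj, sc$weight, sc$z, sc$p, sc$gene,
                                bg$mu, bg$sigma, max_size,
                                if ("n_draws" %in% names(bg)) bg$n_draws[1] else Inf),
                class = "subnetwork")
    })
    keep <- vapply(mods, function(m) {
      m$S > params$min_score && m$size >= params$min_size &&
        m$size <= params$max_size
    }, logical(1))
    mods <- mods[keep]
    if (length(mods)) {
      keys <- vapply(mods, function(m) set_key(m$genes), character(1))
      mods <- mods[!duplicated(keys)]
      keys <- keys[!duplicated(keys)]
      S <- vapply(mods, `[[`, numeric(1), "S")
      mods <- mods[order(-S, keys)]
      for (i in seq_along(mods)) mods[[i]]$rank <- i
    } else {
      warning("search_run: no module passed the score/size filters")
    }
    structure(list(seed = seed, modules = mods,
                   top = if (length(mods)) mods[[1]] else NULL,
                   background = bg, n_modules = length(mods)),
              class = "search_run")
  }
  with_seed_opt(seed, run())
}

#' @export
print.search_run <- function(x, ...) {
  cat(sprintf("search_run (seed %s): %d module(s)\n",
              x$seed %||% "<stream>", x$n_modules))
  if (!is.null(x$top)) {
    cat(sprintf("  top: %d genes, start %s, Z = %.3f, S = %.3f\n",
                x$top$size, x$top$start, x$top$Z, x$top$S))
  }
  invisible(x)
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork: %d genes (start %s), Z = %.3f, S = %.3f\n",
              x$size, x$start, x$Z, x$S))
  invisible(x)
}
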