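# Independent oracles used to freeze expected values; these deliberately use
# different code paths (enumeration, closed forms) than the implementation.

# All non-empty connected vertex subsets of a small graph (n <= 12),
# as a list of integer vectors.
oracle_connected_subsets <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 12)
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    verts <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    # BFS connectivity check
    seen <- verts[1]
    frontier <- verts[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(adj[frontier]), verts), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) == length(verts)) out[[length(out) + 1]] <- verts
  }
  out
}

# Exhaustive maximum adjusted score over all connected subsets of size <= kmax.
oracle_max_S <- function(network, bg, kmax = Inf) {
  subsets <- oracle_connected_subsets(network$graph)
  sc <- network$scores
  best <- -Inf
  for (s in subsets) {
    if (length(s) > kmax) next
    Z <- sum(sc$weight[s] * sc$z[s]) / sqrt(sum(sc$weight[s]^2))
    S <- (Z - bg$mu[length(s)]) / bg$sigma[length(s)]
    if (S > best) best <- S
  }
  best
}

# Hypergeometric upper tail by direct enumeration of the mass function.
oracle_hyper_p <- function(N, K, nq, ov) {
  j <- ov:min(K, nq)
  sum(choose(K, j) * choose(N - K, nq - j)) / choose(N, nq)
}

# Benjamini-Hochberg step-up by the textbook formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running <- Inf
  for (i in seq_len(n)) {
    idx <- o[i]
    rank_i <- n - i + 1
    running <- min(running, p[idx] * n / rank_i)
    adj[idx] <- min(1, running)
  }
  adj
}

# Pearson correlation written out long-hand.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
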