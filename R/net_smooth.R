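#' Select seed genes
#'
#' Genes with a gene-level p-value at or below the threshold (inclusive, the
#' nominal `p <= 0.05` by default) become seeds for network propagation.
#'
#' @param scores `data.frame` with columns `gene` and `p`.
#' @param threshold Seed p-value threshold (default 0.05).
#' @return Character vector of seed genes; errors if none qualify.
#' @export
select_seeds <- function(scores, threshold = 0.05) {
  stopifnot(nrow(scores) > 0)
  assert_prob(scores$p, "gene p")
  seeds <- scores$gene[scores$p <= threshold]
  if (!length(seeds)) {
    stop("no seed genes at p <= ", threshold, "; pipeline cannot proceed")
  }
  message(sprintf("select_seeds: %d of %d genes seeded (p <= %g)",
                  length(seeds), nrow(scores), threshold))
  seeds
}

#' Weight network edges from gene p-values
#'
#' Sets the weight of every edge (i, j) to `((1 - p_i) + (1 - p_j)) / 2`, so
#' edges between significant genes approach 1 and edges between null genes
#' approach 0.
#'
#' @param graph Undirected `igraph` whose vertices all carry a score.
#' @param scores `data.frame` with `gene`, `p` covering every vertex.
#' @return The graph with an edge attribute `weight` in `[0, 1]`.
#' @export
edge_weights <- function(graph, scores) {
  p <- stats::setNames(scores$p, scores$gene)
  vn <- igraph::V(graph)$name
  missing <- setdiff(vn, names(p))
  if (length(missing)) {
    stop("gene(s) without score in network: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  el <- igraph::as_edgelist(graph)
  igraph::E(graph)$weight <- ((1 - p[el[, 1]]) + (1 - p[el[, 2]])) / 2
  graph
}

#' Column-normalized walk operator
#'
#' Divides every non-zero column of the weighted adjacency matrix by its sum;
#' zero columns (isolated nodes) are left untouched.
#'
#' @param graph Weighted `igraph` (see [edge_weights()]).
#' @return A sparse column-(sub)stochastic matrix with vertex-name dimnames.
#' @export
column_normalize <- function(graph) {
  W <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE)
  cs <- Matrix::colSums(W)
  scale <- ifelse(cs > 0, 1 / cs, 0)
  Wn <- W %*% Matrix::Diagonal(x = scale)
  dimnames(Wn) <- dimnames(W)
  Wn
}

#' Random walk with restart
#'
#' Iterates `P(t) = (1 - r) * W %*% P(t-1) + r * P(0)` for `steps` synchronous
#' updates over the column-normalized operator, starting from `P(0)` with 1 on
#' every seed gene and 0 elsewhere. The result `P(T)` holds the node weights:
#' each node's topological proximity to the seed set.
#'
#' @param operator Column-normalized sparse operator from [column_normalize()].
#' @param seeds Character vector of seed gene names.
#' @param r Restart probability in `[0, 1]` (default 0.5).
#' @param steps Number of walk steps `T >= 0` (default 5).
#' @param p0 Optional explicit initial vector (overrides `seeds`).
#' @return Named non-negative numeric vector `P(T)` over all nodes.
#' @export
random_walk <- function(operator, seeds, r = 0.5, steps = 5, p0 = NULL) {
  if (r < 0 || r > 1) stop("restart ratio r must be in [0, 1]")
  if (steps < 0) stop("steps must be >= 0")
  vn <- rownames(operator)
  if (is.null(p0)) {
    if (!all(seeds %in% vn)) stop("seed gene(s) missing from operator")
    p0 <- stats::setNames(numeric(length(vn)), vn)
    p0[seeds] <- 1
  } else {
    stopifnot(length(p0) == length(vn))
    p0 <- stats::setNames(as.numeric(p0), vn)
  }
  pt <- p0
  t <- 0L
  while (t < steps) {
    pt <- (1 - r) * as.numeric(operator %*% pt) + r * p0
    names(pt) <- vn
    t <- t + 1L
  }
  pt
}

#' Map scores onto the network and smooth them
#'
#' End-to-end preparation of the working network: restricts the PPI graph to
#' genes possessing a gene-level p-value (discarded-node count is reported),
#' computes the probit z of each p, selects seeds, weights edges, column-
#' normalizes, and runs the random walk with restart. The result carries all
#' per-node quantities consumed by module scoring and search.
#'
#' @param graph Undirected PPI `igraph`.
#' @param scores `data.frame` with `gene`, `p`.
#' @param seed_threshold Seed selection threshold (default 0.05).
#' @param r,steps Random-walk parameters (defaults 0.5 and 5).
#' @return An object of class `gwas_network`: list with `graph` (weighted,
#'   restricted), `scores` (`gene`, `p`, `z`, `seed`, `weight` in vertex
#'   order), `operator` (normalized walk matrix), and `params`.
#' @export
smooth_scores <- function(graph, scores, seed_threshold = 0.05,
                          r = 0.5, steps = 5) {
  common <- intersect(igraph::V(graph)$name, scores$gene)
  dropped <- igraph::vcount(graph) - length(common)
  if (!length(common)) stop("no network gene carries a score")
  if (dropped > 0) {
    message(sprintf("smooth_scores: %d unscored network node(s) discarded",
                    dropped))
  }
  g <- igraph::induced_subgraph(graph, common)
  sc <- scores[match(igraph::V(g)$name, scores$gene), , drop = FALSE]
  assert_prob(sc$p, "gene p")
  seeds <- select_seeds(sc, seed_threshold)
  g <- edge_weights(g, sc)
  op <- column_normalize(g)
  w <- random_walk(op, seeds, r = r, steps = steps)
  out <- data.frame(gene = sc$gene, p = sc$p, z = z_transform(sc$p),
                    seed = sc$p <= seed_threshold,
                    weight = unname(w[sc$gene]),
                    stringsAsFactors = FALSE)
  structure(list(graph = g, scores = out, operator = op,
                 params = list(seed_threshold = seed_threshold, r = r,
                               steps = steps)),
            class = "gwas_network")
}

#' @export
print.gwas_network <- function(x, ...) {
  cat(sprintf(paste0("gwas_network: %d genes, %d edges, %d seeds ",
                     "(p <= %g), walk r = %g, T = %d\n"),
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              sum(x$scores$seed), x$params$seed_threshold,
              x$params$r, x$params$steps))
  invisible(x)
}
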