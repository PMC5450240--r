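#' Generate a scale-free surrogate PPI network
#'
#' Preferential attachment: `edges_per_node` initial unconnected nodes; each
#' later node attaches `edges_per_node` edges to distinct earlier nodes with
#' probability proportional to degree (the first arrival connects to all
#' initial nodes, guaranteeing connectivity). The resulting graph has exactly
#' `(n_nodes - edges_per_node) * edges_per_node` edges and the degree
#' heterogeneity typical of protein-interaction networks.
#'
#' @param n_nodes Number of genes (> `edges_per_node`).
#' @param edges_per_node Edges attached per incoming node (>= 1).
#' @param seed Optional RNG seed; the same seed reproduces the edge set.
#' @return An undirected connected `igraph` with vertex names `G0001`, ...
#' @export
generate_network <- function(n_nodes, edges_per_node = 2, seed = NULL) {
  m <- edges_per_node
  if (m < 1 || n_nodes <= m) stop("need n_nodes > edges_per_node >= 1")
  with_seed_opt(seed, {
    deg <- numeric(n_nodes)
    from <- integer(0); to <- integer(0)
    for (i in (m + 1):n_nodes) {
      targets <- if (i == m + 1) {
        seq_len(m)
      } else {
        sample.int(i - 1L, m, prob = deg[seq_len(i - 1L)])
      }
      from <- c(from, rep(i, m)); to <- c(to, targets)
      deg[i] <- deg[i] + m
      deg[targets] <- deg[targets] + 1
    }
    nm <- sprintf("G%04d", seq_len(n_nodes))
    g <- igraph::graph_from_edgelist(cbind(nm[from], nm[to]), directed = FALSE)
    igraph::simplify(g)
  })
}

#' Plant a significant module in a network
#'
#' Chooses a connected ground-truth subgraph of the requested size by a
#' seeded random walk (avoiding the degenerate star shapes a BFS ball would
#' give), then assigns gene-level p-values: planted genes draw from
#' `Uniform(p_in[1], p_in[2])`, background genes from
#' `Uniform(p_out[1], p_out[2])`.
#'
#' @param graph Connected `igraph` (e.g. from [generate_network()]).
#' @param module_size Planted module size (<= number of nodes).
#' @param p_in Length-2 p-value range for planted genes (default
#'   `c(0, 1e-4)`).
#' @param p_out Range for background genes (default `c(0, 1)`).
#' @param seed Optional RNG seed.
#' @return List with `scores` (`data.frame` `gene`, `p`) and `truth`
#'   (character vector of planted genes, inducing a connected subgraph).
#' @export
plant_module <- function(graph, module_size, p_in = c(0, 1e-4),
                         p_out = c(0, 1), seed = NULL) {
  n <- igraph::vcount(graph)
  if (module_size > n) stop("module_size exceeds network size")
  stopifnot(all(p_in >= 0), all(p_in <= 1), all(p_out >= 0), all(p_out <= 1))
  with_seed_opt(seed, {
    vn <- igraph::V(graph)$name
    adj <- lapply(igraph::as_adj_list(graph), as.integer)
    start <- sample.int(n, 1)
    truth <- start
    cur <- start
    guard <- 0L
    while (length(truth) < module_size) {
      nb <- adj[[cur]]
      cur <- nb[sample.int(length(nb), 1)]
      if (!(cur %in% truth)) truth <- c(truth, cur)
      guard <- guard + 1L
      if (guard > 1000L * module_size) {
        # walk is stuck in a tiny component
        stop("could not collect a connected subgraph of size ", module_size)
      }
      # occasional restart inside the collected set keeps the walk compact
      if (guard %% 25L == 0L) cur <- truth[sample.int(length(truth), 1)]
    }
    p <- stats::runif(n, p_out[1], p_out[2])
    p[truth] <- stats::runif(length(truth), p_in[1], p_in[2])
    list(scores = data.frame(gene = vn, p = p, stringsAsFactors = FALSE),
         truth = vn[truth])
  })
}

#' Set-overlap recovery metrics
#'
#' Jaccard, Dice, precision and recall of a recovered gene set against a
#' non-empty ground truth.
#'
#' @param found Recovered gene set (may be empty).
#' @param truth Ground-truth gene set (non-empty).
#' @return Named numeric vector `jaccard`, `dice`, `precision`, `recall`.
#' @export
recovery_metrics <- function(found, truth) {
  truth <- unique(truth)
  if (!length(truth)) stop("truth set must be non-empty")
  found <- unique(found)
  ov <- length(intersect(found, truth))
  c(jaccard = ov / length(union(found, truth)),
    dice = 2 * ov / (length(found) + length(truth)),
    precision = if (length(found)) ov / length(found) else 0,
    recall = ov / length(truth))
}
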