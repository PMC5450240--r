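# Programmatic fixtures shared across test files.

# Small graph from an edge list given as a two-column character matrix.
graph_from_pairs <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# A 5-clique of highly significant genes attached to a ring of null genes.
# Returns list(graph, scores, clique).
clique_periphery_fixture <- function(p_in = 1e-6, p_out = 0.9) {
  clique <- paste0("C", 1:5)
  ring <- paste0("R", 1:6)
  el <- t(utils::combn(clique, 2))
  ring_el <- cbind(ring, ring[c(2:6, 1)])
  bridge <- rbind(c("C1", "R1"), c("C3", "R4"))
  g <- igraph::graph_from_edgelist(rbind(el, ring_el, bridge),
                                   directed = FALSE)
  scores <- data.frame(gene = c(clique, ring),
                       p = c(rep(p_in, 5), rep(p_out, 6)),
                       stringsAsFactors = FALSE)
  list(graph = g, scores = scores, clique = clique)
}

# Prepared small working network (smoothing suppressed chatter).
smooth_quiet <- function(graph, scores, ...) {
  suppressMessages(smooth_scores(graph, scores, ...))
}

# Minimal hand-built objects for consensus unit tests: a network whose scores
# are all unit weight (so Z is the plain Stouffer statistic) and fake ranked
# runs from plain gene-set lists.
fake_network <- function(genes, p = NULL) {
  p <- p %||% rep(0.5, length(genes))
  g <- igraph::make_ring(length(genes))
  igraph::V(g)$name <- genes
  structure(list(
    graph = g,
    scores = data.frame(gene = genes, p = p, z = z_transform(p),
                        seed = p <= 0.05, weight = 1,
                        stringsAsFactors = FALSE),
    operator = NULL,
    params = list(seed_threshold = 0.05, r = 0.5, steps = 5)),
    class = "gwas_network")
}

fake_run <- function(gene_sets, seed = NA_integer_, k_max = 50) {
  mods <- lapply(seq_along(gene_sets), function(i) {
    structure(list(genes = gene_sets[[i]], start = gene_sets[[i]][1],
                   size = length(gene_sets[[i]]),
                   Z = NA_real_, S = 10 - i, rank = i),
              class = "subnetwork")
  })
  structure(list(seed = seed, modules = mods, top = mods[[1]],
                 background = data.frame(k = seq_len(k_max), mu = 0,
                                         sigma = 1, n_draws = 1e9),
                 n_modules = length(mods)),
            class = "search_run")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
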