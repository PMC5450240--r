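#' Fisher exact enrichment of a gene set in a pathway
#'
#' One-sided hypergeometric upper tail: the probability of observing at least
#' the seen overlap between query and pathway when the query is drawn
#' uniformly from the background. Genes outside the background are dropped
#' with a warning.
#'
#' @param query Query gene set.
#' @param pathway Pathway gene set.
#' @param background Background gene universe (non-empty).
#' @return List with `p`, `overlap_count`, `overlap_genes`, `pathway_size`,
#'   `query_size`.
#' @export
fisher_enrich <- function(query, pathway, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  qd <- setdiff(query, background); pd <- setdiff(pathway, background)
  if (length(qd) || length(pd)) {
    warning(sprintf("%d query and %d pathway gene(s) outside background dropped",
                    length(qd), length(pd)))
  }
  query <- intersect(unique(query), background)
  pathway <- intersect(unique(pathway), background)
  ov <- intersect(query, pathway)
  N <- length(background); K <- length(pathway); nq <- length(query)
  p <- stats::phyper(length(ov) - 1, K, N - K, nq, lower.tail = FALSE)
  list(p = p, overlap_count = length(ov), overlap_genes = sort(ov),
       pathway_size = K, query_size = nq)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvals P-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  assert_prob(pvals, "p-value")
  stats::p.adjust(pvals, method = "BH")
}

#' Rank-deviation z-score of pathway enrichments
#'
#' For each pathway, compares the observed rank of its Fisher p within the
#' library's p-vector against the rank distribution obtained from `n_null`
#' random query sets of the same size: `z = (observed - mean_null) / sd_null`.
#' Negative z means the pathway ranks better than expected for a random query
#' of that size.
#'
#' @param query Query gene set.
#' @param library A GMT-style named list of gene sets (>= 2 pathways).
#' @param background Background gene universe.
#' @param n_null Number of null query draws (default 1000).
#' @param seed Optional RNG seed.
#' @return Named numeric vector of z values (0, with a `"degenerate"`
#'   attribute, where the null rank distribution has zero spread).
#' @export
rank_zscore <- function(query, library, background, n_null = 1000,
                        seed = NULL) {
  if (length(library) < 2) stop("rank_zscore needs >= 2 pathways")
  background <- unique(background)
  query <- intersect(unique(query), background)
  sets <- lapply(library, intersect, background)
  N <- length(background); nq <- length(query)
  K <- lengths(sets)
  M <- vapply(sets, function(s) background %in% s, logical(N)) # N x P
  obs_cnt <- as.numeric(crossprod(M, background %in% query))
  obs_p <- stats::phyper(obs_cnt - 1, K, N - K, nq, lower.tail = FALSE)
  obs_rank <- rank(obs_p, ties.method = "average")
  with_seed_opt(seed, {
    null_ranks <- matrix(0, length(sets), n_null)
    for (d in seq_len(n_null)) {
      ind <- logical(N)
      ind[sample.int(N, nq)] <- TRUE
      cnt <- as.numeric(crossprod(M, ind))
      pnull <- stats::phyper(cnt - 1, K, N - K, nq, lower.tail = FALSE)
      null_ranks[, d] <- rank(pnull, ties.method = "average")
    }
    mu <- rowMeans(null_ranks)
    sg <- apply(null_ranks, 1, stats::sd)
    degen <- sg == 0
    z <- ifelse(degen, 0, (obs_rank - mu) / ifelse(degen, 1, sg))
    names(z) <- names(library)
    attr(z, "degenerate") <- names(library)[degen]
    z
  })
}

#' Combined enrichment score
#'
#' `c = ln(p_adj) * z`: the product of the natural log of the adjusted Fisher
#' p-value and the rank-deviation z-score. With `z < 0` and `p_adj < 1` the
#' score is positive, larger meaning stronger enrichment. `p_adj` must be
#' clamped above 0 upstream (the table builder clamps at `1e-300`).
#'
#' @param p_adj Adjusted p-value(s) in `(0, 1]`.
#' @param z Rank-deviation z-score(s).
#' @return The combined score(s).
#' @examples
#' combined_score(0.002277, -1.77) # ~10.77
#' @export
combined_score <- function(p_adj, z) {
  if (any(!is.finite(p_adj) | p_adj <= 0 | p_adj > 1)) {
    stop("p_adj must be in (0, 1]; clamp zeros upstream")
  }
  if (any(!is.finite(z))) stop("z must be finite")
  log(p_adj) * z
}

#' Pathway enrichment table for a query gene set
#'
#' Computes, for every pathway in the library: the overlap with the query,
#' the one-sided Fisher exact p, the Benjamini-Hochberg adjusted p, the
#' rank-deviation z-score, and the combined score `ln(p_adj) * z`. Rows are
#' sorted by increasing p.
#'
#' @param query Query gene set.
#' @param library Named list of pathway gene sets (e.g. from [read_gmt()]).
#' @param background Background universe; typically all genes of the working
#'   network.
#' @param n_null Null draws for the rank z-score (default 1000).
#' @param seed Optional RNG seed.
#' @return `data.frame` with columns `pathway`, `overlap`, `overlap_count`,
#'   `pathway_size`, `query_size`, `p`, `p_adj`, `z`, `combined`, `genes`.
#' @export
enrich_query <- function(query, library, background, n_null = 1000,
                         seed = NULL) {
  rows <- lapply(names(library), function(nm) {
    fe <- suppressWarnings(fisher_enrich(query, library[[nm]], background))
    data.frame(pathway = nm, overlap = sprintf("%d/%d", fe$overlap_count,
                                               fe$pathway_size),
               overlap_count = fe$overlap_count,
               pathway_size = fe$pathway_size, query_size = fe$query_size,
               p = fe$p, genes = paste(fe$overlap_genes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p)
  z <- rank_zscore(query, library, background, n_null = n_null, seed = seed)
  tab$z <- unname(z[tab$pathway])
  tab$combined <- combined_score(pmax(tab$p_adj, 1e-300), tab$z)
  tab <- tab[order(tab$p, tab$pathway),
             c("pathway", "overlap", "overlap_count", "pathway_size",
               "query_size", "p", "p_adj", "z", "combined", "genes")]
  rownames(tab) <- NULL
  tab
}
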