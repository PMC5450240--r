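#' Dice coefficient of two gene sets
#'
#' `DC(m, n) = 2 |m intersect n| / (|m| + |n|)`: symmetric, in `[0, 1]`, and
#' equal to 1 exactly when the sets coincide.
#'
#' @param m,n Character vectors (gene sets); not both empty.
#' @return The Dice coefficient.
#' @examples
#' dice(letters[1:3], letters[2:4]) # 2*2/6
#' @export
dice <- function(m, n) {
  m <- unique(m); n <- unique(n)
  if (!length(m) && !length(n)) stop("dice undefined for two empty sets")
  2 * length(intersect(m, n)) / (length(m) + length(n))
}

#' Most similar subnetwork in another run
#'
#' Finds the subnetwork of `run_b` maximizing the Dice coefficient with a
#' reference gene set. Ties are broken by the candidate's rank (higher
#' adjusted score first); ranks are reported 1-based within `run_b`.
#'
#' @param tn_genes Reference gene set (e.g. a top subnetwork).
#' @param run_b A `search_run` with at least one module.
#' @return List with `module` (the `subnetwork`), `rank`, `dc`.
#' @export
most_similar <- function(tn_genes, run_b) {
  if (!length(run_b$modules)) stop("run has no modules to match against")
  dc <- vapply(run_b$modules, function(m) dice(tn_genes, m$genes), numeric(1))
  best <- which.max(dc) # modules are rank-ordered: first max = best rank
  list(module = run_b$modules[[best]], rank = best, dc = dc[best])
}

#' Consensus module from one source run
#'
#' Intersects the top subnetwork of run `a` with its most similar subnetwork
#' from every other run, and rescores the intersection (raw Z from the shared
#' node weights; adjusted S against run `a`'s background).
#'
#' @param a Index of the source run.
#' @param runs List of >= 2 `search_run` objects with non-empty results.
#' @param network The `gwas_network` the runs were searched on.
#' @return A list of class `consensus_module`: `genes`, `source_run`,
#'   `matched` (data.frame `run_b`, `rank`, `dc`), `Z`, `S`, `size`.
#' @export
consensus_module <- function(a, runs, network) {
  if (length(runs) < 2) stop("consensus requires >= 2 runs")
  tn <- runs[[a]]$top
  if (is.null(tn)) stop("run ", a, " has no top subnetwork")
  genes <- tn$genes
  matched <- data.frame(run_b = integer(0), rank = integer(0), dc = numeric(0))
  for (b in seq_along(runs)[-a]) {
    sn <- most_similar(tn$genes, runs[[b]])
    genes <- intersect(genes, sn$module$genes)
    matched <- rbind(matched,
                     data.frame(run_b = b, rank = sn$rank, dc = sn$dc))
  }
  Z <- NA_real_; S <- NA_real_
  if (length(genes)) {
    Z <- network_zscore(genes, network$scores)
    S <- adjusted_score(Z, length(genes), runs[[a]]$background)
  } else {
    warning("consensus module from run ", a, " is empty")
  }
  structure(list(genes = genes, source_run = a, matched = matched,
                 Z = Z, S = S, size = length(genes)),
            class = "consensus_module")
}

#' Deduplicate consensus modules
#'
#' Merges consensus modules with identical gene sets, concatenating their
#' source runs; the first occurrence's scores are kept.
#'
#' @param cms List of `consensus_module` objects.
#' @return List of unique `consensus_module`s with `source_run` vectors.
#' @export
unique_modules <- function(cms) {
  if (!length(cms)) return(cms)
  keys <- vapply(cms, function(cm) set_key(cm$genes), character(1))
  out <- list()
  for (k in unique(keys)) {
    grp <- cms[keys == k]
    first <- grp[[1]]
    first$source_run <- unlist(lapply(grp, `[[`, "source_run"))
    out[[length(out) + 1]] <- first
  }
  out
}

#' Common subnetwork across consensus modules
#'
#' Intersects the gene sets of all (unique) consensus modules and, when a
#' graph is supplied, attaches the induced PPI edges for export.
#'
#' @param cms Non-empty list of `consensus_module`s.
#' @param graph Optional `igraph` to induce edges from.
#' @return List with `genes` and (if `graph` given) `edges` (two-column
#'   matrix).
#' @export
common_subnetwork <- function(cms, graph = NULL) {
  if (!length(cms)) stop("no consensus modules supplied")
  genes <- Reduce(intersect, lapply(cms, `[[`, "genes"))
  if (!length(genes)) warning("common subnetwork is empty")
  out <- list(genes = genes)
  if (!is.null(graph) && length(genes)) {
    sub <- igraph::induced_subgraph(graph, intersect(genes,
                                                     igraph::V(graph)$name))
    out$edges <- igraph::as_edgelist(sub)
  }
  out
}

#' Consensus analysis across runs
#'
#' Builds one consensus module per run with a non-empty result, deduplicates
#' them, and extracts the common subnetwork. Also assembles the run-by-run
#' match table (rank of the most similar subnetwork and its Dice coefficient)
#' for each consensus module.
#'
#' @param runs List of `search_run` objects.
#' @param network The `gwas_network` searched.
#' @return A list of class `consensus_set`: `cms`, `unique_cms`, `common`,
#'   `match_table` (long data.frame `source_run`, `run_b`, `rank`, `dc`).
#' @export
consensus_analysis <- function(runs, network) {
  ok <- which(vapply(runs, function(r) !is.null(r$top), logical(1)))
  if (length(ok) < 2) {
    stop("consensus requires >= 2 runs with at least one module each")
  }
  if (length(ok) < length(runs)) {
    warning(sprintf("%d run(s) without modules dropped from consensus",
                    length(runs) - length(ok)))
  }
  runs_ok <- runs[ok]
  cms <- lapply(seq_along(runs_ok), consensus_module, runs = runs_ok,
                network = network)
  for (i in seq_along(cms)) cms[[i]]$source_run <- ok[i]
  ucms <- unique_modules(cms)
  nonempty <- ucms[vapply(ucms, function(cm) cm$size > 0, logical(1))]
  common <- if (length(nonempty)) {
    common_subnetwork(nonempty, network$graph)
  } else {
    list(genes = character(0))
  }
  mt <- do.call(rbind, lapply(cms, function(cm) {
    cbind(source_run = cm$source_run[1], cm$matched)
  }))
  structure(list(cms = cms, unique_cms = ucms, common = common,
                 match_table = mt),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d CM(s), %d unique, common subnetwork of %d gene(s)\n",
              length(x$cms), length(x$unique_cms), length(x$common$genes)))
  for (cm in x$unique_cms) {
    cat(sprintf("  CM (runs %s): %d genes, Z = %.3f, S = %.3f\n",
                paste(cm$source_run, collapse = ","), cm$size, cm$Z, cm$S))
  }
  invisible(x)
}
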