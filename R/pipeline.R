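#' Run the full network analysis pipeline
#'
#' Orchestrates the network stage end to end: maps gene scores onto the PPI
#' network and smooths them ([smooth_scores()]), runs the greedy module
#' search once per seed ([search_run()]), extracts consensus modules and the
#' common subnetwork across runs ([consensus_analysis()]), and optionally
#' annotates every unique consensus module and the common subnetwork by
#' pathway enrichment ([enrich_query()]).
#'
#' @param graph Undirected PPI `igraph`.
#' @param gene_scores `data.frame` with `gene`, `p` (e.g. from
#'   [gene_test_all()] or [read_gene_scores()]).
#' @param seeds Integer RNG seeds, one search run each (default `1:10`).
#' @param seed_threshold Seed-gene p threshold (default 0.05).
#' @param r,steps Random-walk restart ratio and step count (defaults 0.5, 5).
#' @param params A [search_params()] list.
#' @param gmt Optional pathway library for enrichment.
#' @param n_null Null draws for the enrichment rank z-score.
#' @param enrich_seed RNG seed for the enrichment nulls (default first seed).
#' @return A list of class `gwasnet_pipeline`: `network`, `runs`,
#'   `consensus` (or `NULL` when fewer than two runs yielded modules),
#'   `enrichment` (named list of tables), `seeds`, `params`.
#' @export
run_pipeline <- function(graph, gene_scores, seeds = 1:10,
                         seed_threshold = 0.05, r = 0.5, steps = 5,
                         params = search_params(), gmt = NULL,
                         n_null = 1000, enrich_seed = NULL) {
  net <- smooth_scores(graph, gene_scores, seed_threshold = seed_threshold,
                       r = r, steps = steps)
  runs <- lapply(seeds, function(s) {
    run <- suppressWarnings(search_run(net, params = params, seed = s))
    message(sprintf("run seed %d: %d module(s)", s, run$n_modules))
    run
  })
  n_ok <- sum(vapply(runs, function(x) !is.null(x$top), logical(1)))
  message(sprintf("%d run result(s), %d with modules", length(runs), n_ok))
  cons <- NULL
  if (n_ok >= 2) {
    cons <- suppressWarnings(consensus_analysis(runs, net))
    message(sprintf("%d consensus module(s), %d unique, common subnetwork: %d gene(s)",
                    length(cons$cms), length(cons$unique_cms),
                    length(cons$common$genes)))
  } else {
    message("fewer than 2 runs with modules; consensus skipped")
  }
  enr <- NULL
  if (!is.null(gmt) && !is.null(cons)) {
    bgset <- igraph::V(net$graph)$name
    es <- enrich_seed %||% seeds[1]
    enr <- list()
    for (i in seq_along(cons$unique_cms)) {
      cm <- cons$unique_cms[[i]]
      if (cm$size > 0) {
        enr[[sprintf("CM%d", i)]] <-
          enrich_query(cm$genes, gmt, bgset, n_null = n_null, seed = es)
      }
    }
    if (length(cons$common$genes)) {
      enr[["common"]] <- enrich_query(cons$common$genes, gmt, bgset,
                                      n_null = n_null, seed = es)
    }
  }
  structure(list(network = net, runs = runs, consensus = cons,
                 enrichment = enr, seeds = seeds, params = params),
            class = "gwasnet_pipeline")
}

#' @export
print.gwasnet_pipeline <- function(x, ...) {
  print(x$network)
  nmod <- vapply(x$runs, `[[`, integer(1), "n_modules")
  cat(sprintf("runs (seeds %s): modules per run %s\n",
              paste(range(x$seeds), collapse = ".."),
              paste(nmod, collapse = "/")))
  if (!is.null(x$consensus)) print(x$consensus)
  if (!is.null(x$enrichment)) {
    cat(sprintf("enrichment tables: %s\n",
                paste(names(x$enrichment), collapse = ", ")))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Exports the run summary table (one row per run: seed, module count, top
#' subnetwork size/start/scores), the per-run module tables, consensus-module
#' gene tables with their run-match matrix, SIF/node/edge exports of every
#' unique consensus module and of the common subnetwork, enrichment tables,
#' and a provenance file of the parameters used.
#'
#' @param result A `gwasnet_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pipeline <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net <- result$network
  runs_tab <- do.call(rbind, lapply(seq_along(result$runs), function(i) {
    r <- result$runs[[i]]
    data.frame(seed = r$seed %||% NA_integer_, n_modules = r$n_modules,
               tn_size = if (is.null(r$top)) NA_integer_ else r$top$size,
               tn_start = if (is.null(r$top)) NA_character_ else r$top$start,
               tn_Z = if (is.null(r$top)) NA_real_ else r$top$Z,
               tn_S = if (is.null(r$top)) NA_real_ else r$top$S,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(runs_tab, file.path(dir, "runs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_along(result$runs)) {
    r <- result$runs[[i]]
    if (!length(r$modules)) next
    mt <- do.call(rbind, lapply(r$modules, function(m) {
      data.frame(rank = m$rank, size = m$size, start = m$start,
                 Z = m$Z, S = m$S, genes = paste(sort(m$genes), collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(mt, file.path(dir, sprintf("run%02d_modules.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$consensus)) {
    cons <- result$consensus
    utils::write.table(cons$match_table, file.path(dir, "consensus_matches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mods <- lapply(cons$unique_cms, function(cm) cm$genes)
    names(mods) <- sprintf("CM%d", seq_along(mods))
    mods <- mods[lengths(mods) > 0]
    if (length(cons$common$genes)) mods$common <- cons$common$genes
    if (length(mods)) {
      write_modules(mods, dir, net$graph, scores = net$scores)
    }
  }
  if (!is.null(result$enrichment)) {
    for (nm in names(result$enrichment)) {
      write_enrichment(result$enrichment[[nm]],
                       file.path(dir, sprintf("enrichment_%s.tsv", nm)))
    }
  }
  prm <- c(sprintf("seeds\t%s", paste(result$seeds, collapse = ",")),
           sprintf("seed_threshold\t%g", net$params$seed_threshold),
           sprintf("r\t%g", net$params$r),
           sprintf("steps\t%d", net$params$steps),
           sprintf("min_score\t%g", result$params$min_score),
           sprintf("min_size\t%d", result$params$min_size),
           sprintf("max_size\t%d", result$params$max_size),
           sprintf("bg_draws\t%d", result$params$bg_draws))
  writeLines(prm, file.path(dir, "params.tsv"))
  invisible(dir)
}
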