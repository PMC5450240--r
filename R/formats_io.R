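#' Read a protein-protein interaction network from an edge list
#'
#' Reads a two-column tab-delimited edge list (HPRD-style) or a SIF file and
#' returns an undirected simple [igraph][igraph::graph] object. Self-loops are
#' dropped with a warning; duplicate and reciprocal pairs collapse to a single
#' undirected edge.
#'
#' @param path Path to the network file.
#' @param format `"tab"` for a two-column edge list, `"sif"` for Cytoscape SIF
#'   (`node <tab> interaction <tab> node [node ...]`).
#' @param uppercase Upper-case all gene symbols (default `TRUE`), so that
#'   identifiers from differently-cased sources match.
#' @return An undirected simple `igraph` graph whose vertex names are gene
#'   symbols.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "B\tC"), f)
#' g <- read_ppi(f)
#' igraph::vcount(g) # 3
#' igraph::ecount(g) # 2
#' @export
read_ppi <- function(path, format = c("tab", "sif"), uppercase = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty network file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- lapply(fields, trimws)

  if (format == "tab") {
    nf <- vapply(fields, length, integer(1))
    # optional single header row of non-gene column labels
    if (nf[1] >= 2 && all(tolower(fields[[1]][1:2]) %in%
                          c("gene_a", "gene_b", "genea", "geneb",
                            "gene1", "gene2", "from", "to", "source", "target"))) {
      fields <- fields[-1]; nf <- nf[-1]; lineno <- lineno[-1]
    }
    if (!length(fields)) stop("no edge rows in ", path)
    bad <- which(nf < 2 | vapply(fields, function(f) any(!nzchar(f[1:2])), logical(1)))
    if (length(bad)) {
      stop(sprintf("malformed edge row at line %d of %s", lineno[bad[1]], path))
    }
    ea <- vapply(fields, `[`, character(1), 1L)
    eb <- vapply(fields, `[`, character(1), 2L)
  } else {
    nf <- vapply(fields, length, integer(1))
    bad <- which(nf < 3)
    if (length(bad)) {
      stop(sprintf("malformed SIF row (need >= 3 fields) at line %d of %s",
                   lineno[bad[1]], path))
    }
    ea <- unlist(lapply(fields, function(f) rep(f[1], length(f) - 2L)))
    eb <- unlist(lapply(fields, function(f) f[-(1:2)]))
  }

  if (uppercase) {
    ea <- toupper(ea); eb <- toupper(eb)
  }
  loops <- ea == eb
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop row(s)", sum(loops)))
    ea <- ea[!loops]; eb <- eb[!loops]
  }
  if (!length(ea)) stop("no non-loop edges in ", path)
  g <- igraph::graph_from_edgelist(cbind(ea, eb), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  message(sprintf("read_ppi: %d nodes, %d edges from %s",
                  igraph::vcount(g), igraph::ecount(g), basename(path)))
  g
}

#' Read a GMT pathway library
#'
#' @param path Path to a GMT file (`name <tab> description <tab> gene ...`).
#' @param uppercase Upper-case gene symbols (default `TRUE`).
#' @return A named list of character vectors (gene sets) with a
#'   `"description"` attribute holding per-pathway descriptions.
#' @export
read_gmt <- function(path, uppercase = TRUE) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  bad <- which(nf < 3)
  if (length(bad)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", lineno[bad[1]]))
  }
  nm <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate pathway name in GMT: ", nm[duplicated(nm)][1])
  }
  desc <- vapply(fields, `[`, character(1), 2L)
  sets <- lapply(fields, function(f) {
    g <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (uppercase) toupper(g) else g
  })
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT")
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' Read and write gene-level score tables
#'
#' A gene-score file is tab-delimited with columns `gene` and `p` (an optional
#' header is auto-detected by a non-numeric p field). Writing then reading
#' reproduces the table to 12 significant digits.
#'
#' @param path File path.
#' @param uppercase Upper-case gene symbols (default `TRUE`).
#' @return `read_gene_scores()`: a `data.frame` with columns `gene`, `p`.
#' @export
read_gene_scores <- function(path, uppercase = TRUE) {
  if (!file.exists(path)) stop("gene score file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("gene", "p"),
                          colClasses = c("character", "character"))
  if (!nrow(df)) stop("empty gene score file: ", path)
  if (is.na(suppressWarnings(as.numeric(df$p[1])))) df <- df[-1, , drop = FALSE]
  p <- suppressWarnings(as.numeric(df$p))
  if (anyNA(p)) stop("non-numeric p-value at row ", which(is.na(p))[1])
  gene <- if (uppercase) toupper(df$gene) else df$gene
  bad <- p < 0 | p > 1
  if (any(bad)) {
    stop("p-value outside [0,1] for gene ", gene[which(bad)[1]])
  }
  if (anyDuplicated(gene)) {
    stop("duplicate gene in score file: ", gene[duplicated(gene)][1])
  }
  data.frame(gene = gene, p = p, stringsAsFactors = FALSE)
}

#' @param scores A `data.frame` with columns `gene` and `p`.
#' @rdname read_gene_scores
#' @export
write_gene_scores <- function(scores, path) {
  stopifnot(all(c("gene", "p") %in% names(scores)))
  assert_prob(scores$p, "gene score p")
  con <- file(path, open = "wb") # LF endings on every platform
  on.exit(close(con))
  writeLines(c("gene\tp",
               paste(scores$gene, formatC(scores$p, digits = 12, format = "g"),
                     sep = "\t")), con)
  invisible(path)
}

#' Export modules as node tables, edge tables and SIF files
#'
#' Writes, for each module, `<name>_nodes.tsv` (gene plus any score columns),
#' `<name>_edges.tsv` and `<name>.sif` with the induced interactions (type
#' `"pp"`), ready for Cytoscape.
#'
#' @param modules A named list of modules; each module is either a character
#'   vector of genes or a list with a `genes` element.
#' @param dir Output directory (created if needed).
#' @param graph The PPI `igraph` used to induce edges.
#' @param scores Optional per-gene annotation `data.frame` with a `gene`
#'   column, joined into the node tables.
#' @return Invisibly, the vector of files written.
#' @export
write_modules <- function(modules, dir, graph, scores = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(names(modules)) || any(!nzchar(names(modules)))) {
    names(modules) <- sprintf("module%02d", seq_along(modules))
  }
  written <- character(0)
  for (nm in names(modules)) {
    m <- modules[[nm]]
    genes <- if (is.list(m)) m$genes else m
    genes <- intersect(genes, igraph::V(graph)$name)
    sub <- igraph::induced_subgraph(graph, genes)
    nodes <- data.frame(gene = genes, stringsAsFactors = FALSE)
    if (!is.null(scores)) {
      nodes <- merge(nodes, scores, by = "gene", all.x = TRUE, sort = TRUE)
    }
    nf <- file.path(dir, paste0(nm, "_nodes.tsv"))
    utils::write.table(nodes, nf, sep = "\t", quote = FALSE, row.names = FALSE)
    el <- igraph::as_edgelist(sub)
    ef <- file.path(dir, paste0(nm, "_edges.tsv"))
    utils::write.table(data.frame(gene_a = el[, 1], gene_b = el[, 2]),
                       ef, sep = "\t", quote = FALSE, row.names = FALSE)
    sf <- file.path(dir, paste0(nm, ".sif"))
    sif <- if (nrow(el)) paste(el[, 1], "pp", el[, 2], sep = "\t") else character(0)
    writeLines(sif, sf)
    written <- c(written, nf, ef, sf)
  }
  invisible(written)
}

#' Write an enrichment table
#'
#' @param rows Enrichment `data.frame` as returned by [enrich_query()].
#' @param path Output file.
#' @export
write_enrichment <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write background calibration tables
#'
#' Serializes the per-size background distribution of the network score as a
#' three-column tab table (`k`, `mu`, `sigma`) so a calibration can be reused
#' across runs.
#'
#' @param bg A background table from [calibrate_background()].
#' @param path File path.
#' @export
write_background <- function(bg, path) {
  utils::write.table(bg[, c("k", "mu", "sigma")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  bg <- utils::read.table(path, sep = "\t", header = TRUE)
  stopifnot(all(c("k", "mu", "sigma") %in% names(bg)))
  bg
}
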