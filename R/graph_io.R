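#' Read an interaction network from an edge-list file
#'
#' Supports two-column tab-separated edge lists and the Cytoscape SIF format
#' (`node<TAB>interaction<TAB>target [target ...]`). Lines starting with `#`
#' are comments. For TSV input a header row is auto-detected: if the first
#' row's tokens never appear as endpoints anywhere else in the file, it is
#' treated as a header and skipped. Any third (weight) column in TSV input is
#' ignored with a warning because the pipeline operates on the binary
#' adjacency matrix only.
#'
#' Duplicate edges collapse to a single edge; self-loops are retained until
#' [curate()]. Node identifiers are case-sensitive strings.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by file extension, default), `"tsv"` or `"sif"`.
#' @return An uncurated InteractionNetwork (undirected igraph with named
#'   nodes, possibly containing self-loops).
#' @export
read_edge_list <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) stop(sprintf("empty file (no data rows): %s", path))

  if (format == "sif") {
    edges <- list()
    singletons <- character()
    for (i in rows) {
      tok <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
      if (length(tok) == 1L) {
        singletons <- c(singletons, tok)
      } else if (length(tok) >= 3L) {
        edges[[length(edges) + 1L]] <- cbind(tok[1L], tok[3:length(tok)])
      } else {
        stop(sprintf("malformed SIF row at line %d: expected 1 or >=3 columns, got %d",
                     i, length(tok)))
      }
    }
    el <- if (length(edges)) do.call(rbind, edges) else
      matrix(character(), ncol = 2)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    extra <- setdiff(singletons, igraph::V(g)$name)
    if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  } else {
    parts <- strsplit(lines[rows], "\t", fixed = TRUE)
    ncols <- lengths(parts)
    if (any(ncols < 2L)) {
      bad <- rows[which(ncols < 2L)[1L]]
      stop(sprintf("malformed row at line %d: expected >= 2 tab-separated columns, got %d",
                   bad, ncols[which(ncols < 2L)[1L]]))
    }
    if (any(ncols > 2L)) {
      warning("input has more than 2 columns; extra columns (e.g. weights) are ignored")
    }
    el <- t(vapply(parts, function(p) trimws(p[1:2]), character(2)))
    # header auto-detection: first row's tokens occur as endpoints nowhere else
    if (nrow(el) > 1L) {
      first <- el[1L, ]
      rest <- el[-1L, , drop = FALSE]
      if (!any(first %in% as.vector(rest))) el <- rest
    }
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
  }
  # collapse duplicate edges, keep self-loops until curation
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  g
}

#' Curate an interaction network
#'
#' Removes self-loops, then nodes left with degree zero, matching the study's
#' curation step ("deletion of the isolated node(s)"). Idempotent. Counts of
#' removed loops and nodes are attached as attributes `n_loops_removed` and
#' `n_isolated_removed`.
#'
#' @param net An InteractionNetwork (igraph).
#' @return The curated network: simple, undirected, minimum degree >= 1.
#' @export
curate <- function(net) {
  stop_if_not_igraph(net)
  n_loops <- sum(igraph::which_loop(net))
  g <- igraph::simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  isolated <- which(igraph::degree(g) == 0)
  n_iso <- length(isolated)
  if (n_iso) g <- igraph::delete_vertices(g, isolated)
  if (igraph::vcount(g) == 0L) stop("network is empty after curation")
  attr(g, "n_loops_removed") <- n_loops
  attr(g, "n_isolated_removed") <- n_iso
  g
}

#' Write a network to disk
#'
#' TSV output is a headerless two-column edge list that round-trips exactly
#' through [read_edge_list()]. GraphML output uses igraph's writer.
#'
#' @param net A curated InteractionNetwork.
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  stop_if_not_igraph(net)
  if (igraph::ecount(net) == 0L) {
    stop("refusing to write a network with no edges (violates curation invariant)")
  }
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net, names = TRUE)
    writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  }
  invisible(path)
}
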