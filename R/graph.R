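#' Graph containers
#'
#' Lightweight containers used throughout the package. `directed_graph`
#' stores directed edges as ordered (from, to) pairs plus, optionally, a set
#' of undetermined (unordered) edges; the undetermined set is empty for this
#' package's own output and is only populated when representing a partially
#' directed graph estimated by some other method for evaluation.
#' `undirected_graph` stores unordered pairs in canonical (sorted) order.
#'
#' @param nodes character vector of node labels.
#' @param edges two-column character matrix/data.frame of edges (ordered for
#'   directed graphs, unordered for undirected ones); may be empty.
#' @param undetermined optional two-column matrix of unordered pairs.
#' @return an object of class `directed_graph` / `undirected_graph`.
#' @name graphs
NULL

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0) ||
      length(edges) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  m <- as.matrix(edges)
  if (ncol(m) != 2) stop("edges must have two columns")
  storage.mode(m) <- "character"
  dimnames(m) <- list(NULL, c("from", "to"))
  m
}

#' @rdname graphs
#' @export
directed_graph <- function(nodes, edges = NULL, undetermined = NULL) {
  ed <- as_edge_matrix(edges)
  un <- as_edge_matrix(undetermined)
  if (nrow(un)) {
    un <- t(apply(un, 1, sort))
    dimnames(un) <- list(NULL, c("from", "to"))
  }
  bad <- setdiff(c(as.vector(ed), as.vector(un)), nodes)
  if (length(bad)) stop("edge references unknown node(s): ",
                        paste(unique(bad), collapse = ", "))
  if (any(ed[, 1] == ed[, 2]) || (nrow(un) && any(un[, 1] == un[, 2]))) {
    stop("self-loops are not allowed")
  }
  ed <- unique(ed)
  un <- unique(un)
  if (nrow(ed) && nrow(un)) {
    key_d <- apply(ed, 1, function(e) paste(sort(e), collapse = "\r"))
    key_u <- paste(un[, 1], un[, 2], sep = "\r")
    if (any(key_d %in% key_u)) {
      stop("a pair cannot be both directed and undetermined")
    }
  }
  g <- structure(list(nodes = nodes, edges = ed, undetermined = un),
                 class = "directed_graph")
  if (nrow(un) == 0 && is.null(topological_order(g))) {
    stop("directed edges contain a cycle")
  }
  g
}

#' @rdname graphs
#' @export
undirected_graph <- function(nodes, edges = NULL) {
  ed <- as_edge_matrix(edges)
  bad <- setdiff(as.vector(ed), nodes)
  if (length(bad)) stop("edge references unknown node(s): ",
                        paste(unique(bad), collapse = ", "))
  if (any(ed[, 1] == ed[, 2])) stop("self-loops are not allowed")
  if (nrow(ed)) {
    ed <- t(apply(ed, 1, sort))
    dimnames(ed) <- list(NULL, c("from", "to"))
    ed <- unique(ed)
  }
  structure(list(nodes = nodes, edges = ed), class = "undirected_graph")
}

#' Topological order of a directed graph
#'
#' Kahn's algorithm; returns the node order or `NULL` if the directed part
#' contains a cycle (this doubles as the acyclicity test).
#'
#' @param g a `directed_graph`.
#' @return character vector of nodes in topological order, or `NULL`.
#' @export
topological_order <- function(g) {
  nodes <- g$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  children <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      fr <- g$edges[i, 1]; to <- g$edges[i, 2]
      indeg[[to]] <- indeg[[to]] + 1L
      children[[fr]] <- c(children[[fr]], to)
    }
  }
  queue <- nodes[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

#' Skeleton of a directed graph
#'
#' Drops directions (and merges undetermined edges) into an
#' `undirected_graph`.
#'
#' @param g a `directed_graph`.
#' @export
graph_skeleton <- function(g) {
  undirected_graph(g$nodes, rbind(g$edges, g$undetermined))
}

edge_keys <- function(m) {
  if (nrow(m) == 0) return(character(0))
  paste(m[, 1], m[, 2], sep = "\r")
}

pair_keys <- function(m) {
  if (nrow(m) == 0) return(character(0))
  apply(m, 1, function(e) paste(sort(e), collapse = "\r"))
}

#' Write a graph to a TSV edge list or DOT file
#'
#' The edge-list format has a header `src<TAB>dst<TAB>kind` with kind
#' `directed` or `undirected`; directed rows keep their orientation,
#' undirected/undetermined rows are written with endpoints sorted. Rows are
#' sorted lexicographically so output is bit-reproducible.
#'
#' @param g a `directed_graph` or `undirected_graph`.
#' @param path output path.
#' @param format `"edgelist"` or `"dot"`.
#' @export
write_graph <- function(g, path, format = c("edgelist", "dot")) {
  format <- match.arg(format)
  if (inherits(g, "undirected_graph")) {
    dir_edges <- matrix(character(0), ncol = 2)
    und_edges <- g$edges
  } else {
    dir_edges <- g$edges
    und_edges <- g$undetermined
  }
  if (format == "edgelist") {
    rows <- character(0)
    if (nrow(dir_edges)) {
      rows <- c(rows, paste(dir_edges[, 1], dir_edges[, 2], "directed",
                            sep = "\t"))
    }
    if (nrow(und_edges)) {
      rows <- c(rows, paste(und_edges[, 1], und_edges[, 2], "undirected",
                            sep = "\t"))
    }
    writeLines(c("src\tdst\tkind", sort(rows)), path)
  } else {
    name <- if (inherits(g, "undirected_graph")) "graph" else "digraph"
    lines <- c(paste(name, "G {"),
               paste0("  \"", sort(g$nodes), "\";"))
    if (nrow(dir_edges)) {
      lines <- c(lines, sort(paste0("  \"", dir_edges[, 1], "\" -> \"",
                                    dir_edges[, 2], "\";")))
    }
    if (nrow(und_edges)) {
      conn <- if (inherits(g, "undirected_graph")) " -- " else " -> "
      extra <- if (inherits(g, "undirected_graph")) ";" else " [dir=none];"
      lines <- c(lines, sort(paste0("  \"", und_edges[, 1], "\"", conn, "\"",
                                    und_edges[, 2], "\"", extra)))
    }
    writeLines(c(lines, "}"), path)
  }
  invisible(path)
}

#' Read a graph written by [write_graph]
#'
#' @param path edge-list TSV path.
#' @param nodes node set; if `NULL`, taken as the sorted union of endpoint
#'   names in the file.
#' @return `directed_graph` if any row is directed, else `undirected_graph`.
#' @export
read_graph <- function(path, nodes = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (is.null(nodes)) nodes <- sort(unique(c(tab$src, tab$dst)))
  dir_rows <- tab$kind == "directed"
  if (any(dir_rows) || nrow(tab) == 0) {
    directed_graph(nodes,
                   edges = tab[dir_rows, c("src", "dst"), drop = FALSE],
                   undetermined = tab[!dir_rows, c("src", "dst"), drop = FALSE])
  } else {
    undirected_graph(nodes, tab[, c("src", "dst"), drop = FALSE])
  }
}

#' @export
print.directed_graph <- function(x, ...) {
  cat("Directed graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " directed edge(s)", sep = "")
  if (nrow(x$undetermined)) cat(", ", nrow(x$undetermined), " undetermined")
  cat("\n")
  invisible(x)
}

#' @export
print.undirected_graph <- function(x, ...) {
  cat("Undirected graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edge(s)\n", sep = "")
  invisible(x)
}
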