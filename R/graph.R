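# Graph-side operations: structural validation, degree census, edge-partition
# extraction, count validation and edge-list file I/O. Graphs are undirected
# simple igraph objects; vertex labels are opaque (names when present,
# indices otherwise).

#' Check that a graph is a valid undirected simple graph
#'
#' The package works on undirected simple graphs: no self-loops, no parallel
#' edges, no direction, no weights. Isolated (degree-0) vertices are allowed;
#' indices whose kernels divide by a degree reject degree-0 endpoints at
#' computation time, but an isolated vertex never appears on an edge.
#'
#' @param g An igraph object.
#' @return `g`, invisibly, if valid; otherwise an error describing the first
#'   violated constraint.
#' @export
check_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("not an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("graph must be undirected", call. = FALSE)
  if (any(igraph::which_loop(g))) stop("graph has self-loops", call. = FALSE)
  if (any(igraph::which_multiple(g))) {
    stop("graph has duplicate edges", call. = FALSE)
  }
  invisible(g)
}

#' Degree census of a graph
#'
#' Tabulates how many vertices have each degree. The census always satisfies
#' the handshake lemma: the sum of degree times count equals twice the number
#' of edges.
#'
#' @param g An undirected simple igraph object.
#' @return A data frame with columns `degree` and `count`, sorted by degree,
#'   of class `degree_census`. Empty graph gives zero rows.
#' @export
#' @examples
#' degree_census(platonic_graph("octahedron"))  # all six vertices degree 4
degree_census <- function(g) {
  check_graph(g)
  d <- igraph::degree(g)
  if (length(d) == 0L) {
    out <- data.frame(degree = integer(0), count = integer(0))
  } else {
    tab <- table(d)
    out <- data.frame(degree = as.integer(names(tab)),
                      count = as.integer(tab))
  }
  class(out) <- c("degree_census", "data.frame")
  out
}

#' Edge partition of a graph by endpoint degree pairs
#'
#' Classifies the edges of a graph by the unordered pair of their endpoint
#' degrees — the central device that lets degree-based indices of large
#' parametric networks be computed without iterating over a concrete graph.
#'
#' @param g An undirected simple igraph object.
#' @return An [edge partition][as_edge_partition]: a data frame with columns
#'   `d1`, `d2` (`d1 <= d2`) and `count`, sorted by `(d1, d2)`, carrying the
#'   graph's vertex and edge counts as attributes.
#' @export
#' @examples
#' edge_partition(platonic_graph("icosahedron"))  # single class (5,5) x 30
edge_partition <- function(g) {
  check_graph(g)
  d <- igraph::degree(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  if (nrow(ends) == 0L) {
    return(as_edge_partition(data.frame(d1 = integer(0), d2 = integer(0),
                                        count = integer(0)),
                             n_vertices = igraph::vcount(g), n_edges = 0L))
  }
  da <- d[ends[, 1L]]
  db <- d[ends[, 2L]]
  key <- paste(pmin(da, db), pmax(da, db))
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  as_edge_partition(
    data.frame(d1 = as.integer(parts[, 1L]), d2 = as.integer(parts[, 2L]),
               count = as.integer(tab)),
    n_vertices = igraph::vcount(g), n_edges = igraph::ecount(g)
  )
}

#' Construct an edge partition from degree pairs and counts
#'
#' @param x A data frame with integer columns `d1`, `d2` and `count`; pairs
#'   are stored unordered and are canonicalised to `d1 <= d2` (rows mapping
#'   to the same unordered pair are merged).
#' @param n_vertices,n_edges Optional declared totals; `n_edges`, when given,
#'   must equal the sum of counts.
#' @return A data frame of class `edge_partition`, sorted by `(d1, d2)`.
#' @export
#' @examples
#' as_edge_partition(data.frame(d1 = c(4, 8), d2 = c(4, 4), count = c(16, 8)))
as_edge_partition <- function(x, n_vertices = NULL, n_edges = NULL) {
  stopifnot(is.data.frame(x), all(c("d1", "d2", "count") %in% names(x)))
  d1 <- pmin(x$d1, x$d2)
  d2 <- pmax(x$d1, x$d2)
  out <- stats::aggregate(list(count = x$count),
                          by = list(d1 = d1, d2 = d2), FUN = sum)
  out <- out[order(out$d1, out$d2), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$count < 0)) stop("negative edge count", call. = FALSE)
  if (!is.null(n_edges) && sum(out$count) != n_edges) {
    stop("partition counts sum to ", sum(out$count),
         ", declared n_edges is ", n_edges, call. = FALSE)
  }
  attr(out, "n_vertices") <- n_vertices
  attr(out, "n_edges") <- if (is.null(n_edges)) sum(out$count) else n_edges
  class(out) <- c("edge_partition", "data.frame")
  out
}

#' @export
as.data.frame.edge_partition <- function(x, ...) {
  data.frame(d1 = x$d1, d2 = x$d2, count = x$count)
}

#' @export
print.edge_partition <- function(x, ...) {
  cat("Edge partition:", sum(x$count), "edges in", nrow(x),
      "degree-pair class(es)\n")
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' Validate a graph against expected vertex and edge counts
#'
#' Report-based check used to verify generated networks against closed-form
#' count formulas (for example 5n+1 vertices and 12n edges for the
#' octahedron chain).
#'
#' @param g An igraph object.
#' @param n_vertices,n_edges Expected counts.
#' @return A list of class `count_report` with elements `pass` (logical) and
#'   `failures` (character vector describing each violated count).
#' @export
#' @examples
#' validate_counts(chain_graph("CHO", 3), 16, 36)$pass  # TRUE
validate_counts <- function(g, n_vertices, n_edges) {
  check_graph(g)
  failures <- character(0)
  if (igraph::vcount(g) != n_vertices) {
    failures <- c(failures, sprintf("vertex count: expected %d, found %d",
                                    as.integer(n_vertices), igraph::vcount(g)))
  }
  if (igraph::ecount(g) != n_edges) {
    failures <- c(failures, sprintf("edge count: expected %d, found %d",
                                    as.integer(n_edges), igraph::ecount(g)))
  }
  structure(list(pass = length(failures) == 0L, failures = failures),
            class = "count_report")
}

#' @export
print.count_report <- function(x, ...) {
  if (x$pass) cat("counts: pass\n")
  else cat("counts: FAIL\n ", paste(x$failures, collapse = "\n  "), "\n")
  invisible(x)
}

#' Read and write whitespace-separated edge-list files
#'
#' One edge per line as two whitespace-separated vertex labels; blank lines
#' and lines starting with `#` are ignored. Labels are kept as character
#' strings.
#'
#' @param path File path.
#' @return `read_edge_list()` returns an undirected simple igraph object
#'   (validated on load); `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop("malformed edge-list line(s): ",
         paste(utils::head(lines[nf != 2L], 3L), collapse = "; "),
         call. = FALSE)
  }
  el <- do.call(rbind, fields)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  check_graph(g)
}

#' @rdname read_edge_list
#' @param g An undirected simple igraph object.
#' @export
write_edge_list <- function(g, path) {
  check_graph(g)
  ends <- igraph::ends(g, igraph::E(g))
  writeLines(paste(ends[, 1L], ends[, 2L]), path)
  invisible(path)
}
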