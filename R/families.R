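# Parametric partition families for the two-dimensional sheet networks.
#
# The octahedral network OT_n and the icosahedral network IS_n are
# characterised by their degree-pair edge partitions, each class count a
# quadratic in the circumscribing order n:
#
#   OT_n (72 n^2 edges, 27 n^2 + 3 n vertices):
#     (4,4): 18n^2 + 12n   (4,8): 36n^2   (8,8): 18n^2 - 12n
#   IS_n (180 n^2 edges, 63 n^2 + 3 n vertices):
#     (5,5): 108n^2 + 18n  (5,10): 54n^2 - 6n  (10,10): 18n^2 - 12n
#
# The sheets themselves are rings of corner-sharing polyhedra whose exact
# adjacency is underdetermined by counts alone, so the package works with
# the partitions directly; all indices are functions of the partition.

.families <- list(
  OT = list(
    pairs = data.frame(d1 = c(4L, 4L, 8L), d2 = c(4L, 8L, 8L),
                       a2 = c(18L, 36L, 18L), a1 = c(12L, 0L, -12L),
                       a0 = c(0L, 0L, 0L)),
    vertex_poly = c(a2 = 27, a1 = 3, a0 = 0),
    edge_poly = c(a2 = 72, a1 = 0, a0 = 0)
  ),
  IS = list(
    pairs = data.frame(d1 = c(5L, 5L, 10L), d2 = c(5L, 10L, 10L),
                       a2 = c(108L, 54L, 18L), a1 = c(18L, -6L, -12L),
                       a0 = c(0L, 0L, 0L)),
    vertex_poly = c(a2 = 63, a1 = 3, a0 = 0),
    edge_poly = c(a2 = 180, a1 = 0, a0 = 0)
  )
)

#' Parametric edge-partition family of a sheet network
#'
#' @param kind `"OT"` (octahedral sheet network) or `"IS"` (icosahedral
#'   sheet network).
#' @return A data frame of class `partition_family` with columns `d1`, `d2`,
#'   `a2`, `a1`, `a0`: the count of edges in class (d1, d2) at order n is
#'   `a2 n^2 + a1 n + a0`. Attributes `vertex_poly` and `edge_poly` hold the
#'   family's total vertex- and edge-count quadratics, `family` the kind.
#' @export
#' @examples
#' partition_family("OT")
#' family_partition(partition_family("IS"), n = 1)   # counts 126, 48, 6
partition_family <- function(kind = c("OT", "IS")) {
  kind <- match.arg(kind)
  fam <- .families[[kind]]
  structure(fam$pairs, class = c("partition_family", "data.frame"),
            family = kind, vertex_poly = fam$vertex_poly,
            edge_poly = fam$edge_poly)
}

#' @export
as.data.frame.partition_family <- function(x, ...) {
  data.frame(d1 = x$d1, d2 = x$d2, a2 = x$a2, a1 = x$a1, a0 = x$a0)
}

#' Evaluate a partition family at a given order n
#'
#' @param family A [partition_family()] (or any data frame with columns
#'   `d1`, `d2`, `a2`, `a1`, `a0`).
#' @param n Integer dimension parameter, n >= 0 (all counts vanish at 0;
#'   the families are defined for n >= 1).
#' @return An [edge partition][as_edge_partition] with the evaluated counts;
#'   classes with zero count are kept (they are structural).
#' @export
family_partition <- function(family, n) {
  stopifnot(length(n) == 1L, n >= 0, n == as.integer(n))
  count <- family$a2 * n^2 + family$a1 * n + family$a0
  if (any(count < 0)) {
    stop("family yields negative class count at n = ", n, call. = FALSE)
  }
  vp <- attr(family, "vertex_poly")
  as_edge_partition(
    data.frame(d1 = family$d1, d2 = family$d2, count = count),
    n_vertices = if (!is.null(vp)) sum(vp * c(n^2, n, 1)),
    n_edges = sum(count)
  )
}

#' Degree census of a sheet-network family, as quadratics in n
#'
#' Solved from the edge partition via incidence consistency: for each degree
#' d, d times the number of degree-d vertices equals the number of edge
#' endpoints of degree d, i.e. the sum over classes containing d of the
#' class count times the multiplicity of d in the pair. The result satisfies
#' the handshake lemma against the family's edge-count quadratic and sums to
#' its vertex-count quadratic.
#'
#' @param kind `"OT"` or `"IS"`.
#' @return Data frame with columns `degree`, `a2`, `a1`, `a0` (the count of
#'   degree-`degree` vertices at order n is `a2 n^2 + a1 n + a0`).
#' @export
#' @examples
#' degree_census_family("OT")   # degree 4: 18n^2+6n; degree 8: 9n^2-3n
degree_census_family <- function(kind = c("OT", "IS")) {
  fam <- partition_family(match.arg(kind))
  degs <- sort(unique(c(fam$d1, fam$d2)))
  rows <- lapply(degs, function(d) {
    mult <- (fam$d1 == d) + (fam$d2 == d)
    co <- colSums(fam[, c("a2", "a1", "a0")] * mult) / d
    if (any(abs(co - round(co)) > 1e-9)) {
      stop("incidence totals for degree ", d,
           " are not divisible by the degree", call. = FALSE)
    }
    data.frame(degree = d, a2 = round(co[["a2"]]), a1 = round(co[["a1"]]),
               a0 = round(co[["a0"]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write edge partitions as JSON
#'
#' Format: `{"pairs": [{"d1": int, "d2": int, "count": int}, ...],
#' "n_vertices": int, "n_edges": int}` with the totals optional.
#'
#' @param path File path.
#' @return `read_partition_json()` returns an
#'   [edge partition][as_edge_partition]; `write_partition_json()` returns
#'   `path` invisibly.
#' @export
read_partition_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (is.null(doc$pairs)) stop("no 'pairs' field in ", path, call. = FALSE)
  as_edge_partition(as.data.frame(doc$pairs),
                    n_vertices = doc$n_vertices, n_edges = doc$n_edges)
}

#' @rdname read_partition_json
#' @param p An [edge partition][as_edge_partition].
#' @export
write_partition_json <- function(p, path) {
  doc <- list(pairs = data.frame(d1 = p$d1, d2 = p$d2, count = p$count))
  if (!is.null(attr(p, "n_vertices"))) doc$n_vertices <- attr(p, "n_vertices")
  if (!is.null(attr(p, "n_edges"))) doc$n_edges <- attr(p, "n_edges")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a partition family as JSON
#'
#' Format: `{"family": "OT", "pairs": [{"d1": ..., "d2": ..., "a2": ...,
#' "a1": ..., "a0": ...}], "vertex_poly": [...], "edge_poly": [...]}`.
#'
#' @param family A [partition_family()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_family_json <- function(family, path) {
  doc <- list(
    family = attr(family, "family"),
    pairs = as.data.frame(family)[, c("d1", "d2", "a2", "a1", "a0")],
    vertex_poly = unname(attr(family, "vertex_poly")),
    edge_poly = unname(attr(family, "edge_poly"))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
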