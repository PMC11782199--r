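# Concrete graph constructors: the octahedron and icosahedron (platonic
# skeletons) and their corner-sharing chains CHO_n / CHI_n, plus a
# deterministic suite of small fixture graphs for testing.

# Octahedron as K(2,2,2): vertices 1..6, antipodal pairs (1,2), (3,4),
# (5,6); every pair of non-antipodal vertices is adjacent. Entry/exit for
# chain gluing are the antipodal pair (1, 2).
octahedron_edges <- function() {
  anti <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  pairs <- utils::combn(6L, 2L)
  keep <- !apply(pairs, 2L, function(p) list(p) %in% anti)
  t(pairs[, keep, drop = FALSE])
}

# Icosahedron as a gyroelongated pentagonal bipyramid: apex 1, upper
# pentagon 2..6, lower pentagon 7..11, apex 12. Vertices 1 and 12 are
# antipodal (distance 3) and serve as chain entry/exit.
icosahedron_edges <- function() {
  up <- 2:6
  lo <- 7:11
  nxt <- function(i) c(i[-1L], i[1L])
  rbind(
    cbind(1L, up),                 # apex to upper pentagon
    cbind(up, nxt(up)),            # upper pentagon cycle
    cbind(lo, nxt(lo)),            # lower pentagon cycle
    cbind(up, lo),                 # antiprism band ...
    cbind(up, nxt(lo)),            # ... two lower neighbours per upper vertex
    cbind(12L, lo)                 # apex to lower pentagon
  )
}

#' Platonic solid skeleton graphs
#'
#' The octahedron graph (6 vertices, 12 edges, 4-regular; isomorphic to the
#' complete tripartite graph K(2,2,2)) and the icosahedron graph
#' (12 vertices, 30 edges, 5-regular). Both are regular, so every
#' irregularity index is zero on them; their chains and sheet networks are
#' not.
#'
#' @param kind `"octahedron"` or `"icosahedron"`.
#' @return An undirected simple igraph object with character vertex names.
#' @export
#' @examples
#' platonic_graph("octahedron")
platonic_graph <- function(kind = c("octahedron", "icosahedron")) {
  kind <- match.arg(kind)
  el <- if (kind == "octahedron") octahedron_edges() else icosahedron_edges()
  g <- igraph::graph_from_edgelist(
    matrix(as.character(el), ncol = 2L), directed = FALSE)
  check_graph(g)
  g
}

# Per-solid chain parameters: vertex count, entry/exit (an antipodal,
# hence non-adjacent, vertex pair — the shared vertex then reaches twice
# the base degree and no edge joins two shared vertices).
.chain_solids <- list(
  CHO = list(edges = quote(octahedron_edges()), nv = 6L, entry = 1L, exit = 2L),
  CHI = list(edges = quote(icosahedron_edges()), nv = 12L, entry = 1L, exit = 12L)
)

#' Corner-sharing chains of octahedra or icosahedra
#'
#' `chain_graph("CHO", n)` arranges n octahedra linearly, consecutive copies
#' sharing exactly one corner vertex; the shared corner lies on both solids
#' and so attains degree 8. It has 5n+1 vertices and 12n edges.
#' `chain_graph("CHI", n)` does the same with icosahedra (shared corners of
#' degree 10; 11n+1 vertices, 30n edges). Within each copy the shared
#' entry/exit corners are an antipodal (non-adjacent) pair, so no edge joins
#' two shared vertices; any non-adjacent corner pair gives the same degree
#' census.
#'
#' @param kind `"CHO"` (octahedron chain) or `"CHI"` (icosahedron chain).
#' @param n Number of polyhedron copies, n >= 1.
#' @return An undirected simple igraph object; vertex names are
#'   `"<copy>_<vertex>"` with shared corners carrying the label of the
#'   earlier copy.
#' @export
#' @examples
#' g <- chain_graph("CHO", 2)
#' degree_census(g)     # ten vertices of degree 4, one of degree 8
#' edge_partition(g)    # (4,4) x 16, (4,8) x 8
chain_graph <- function(kind = c("CHO", "CHI"), n) {
  kind <- match.arg(kind)
  if (length(n) != 1L || is.na(n) || n < 1 || n != as.integer(n)) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  solid <- .chain_solids[[kind]]
  base <- eval(solid$edges)
  blocks <- lapply(seq_len(n), function(i) {
    lab <- paste0(i, "_", seq_len(solid$nv))
    # the entry corner of copy i > 1 is the exit corner of copy i - 1
    if (i > 1L) lab[solid$entry] <- paste0(i - 1L, "_", solid$exit)
    matrix(lab[base], ncol = 2L)
  })
  g <- igraph::graph_from_edgelist(do.call(rbind, blocks), directed = FALSE)
  check_graph(g)
  g
}

#' Deterministic suite of small fixture graphs
#'
#' A named list of small graphs used for property checks: paths, cycles,
#' stars, complete graphs K2..K6, the two platonic solids, octahedron and
#' icosahedron chains up to length 4, and seeded Erdos-Renyi random graphs.
#' Fully deterministic: the same seed always yields the same list.
#'
#' @param seed Integer seed for the random fixtures.
#' @return Named list of igraph objects.
#' @export
fixture_graphs <- function(seed = 42L) {
  out <- list()
  for (k in 3:6) out[[paste0("path", k)]] <- igraph::make_ring(k, circular = FALSE)
  for (k in 3:6) out[[paste0("cycle", k)]] <- igraph::make_ring(k)
  for (k in c(3L, 5L)) out[[paste0("star", k)]] <-
    igraph::make_star(k + 1L, mode = "undirected")
  for (k in 2:6) out[[paste0("K", k)]] <- igraph::make_full_graph(k)
  out$octahedron <- platonic_graph("octahedron")
  out$icosahedron <- platonic_graph("icosahedron")
  for (k in 1:4) {
    out[[paste0("CHO", k)]] <- chain_graph("CHO", k)
    out[[paste0("CHI", k)]] <- chain_graph("CHI", k)
  }
  for (i in 1:4) {
    out[[paste0("gnp", i)]] <- local({
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed + i)
      g <- igraph::sample_gnp(10L, 0.4)
      # drop isolated vertices so every fixture supports index computation
      igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
    })
  }
  out
}

# Save/restore the RNG state so fixture generation never perturbs the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
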