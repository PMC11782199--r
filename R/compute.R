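# Index computation: from a concrete graph, from an edge partition, or
# symbolically (as quadratics in the dimension parameter n) from a
# partition family.

#' Compute irregularity indices of a graph
#'
#' Sums each selected per-edge kernel over the edges of `g` (times its
#' prefactor). Every index is nonnegative and is exactly zero on a regular
#' graph.
#'
#' @param g An undirected simple igraph object; every edge endpoint must
#'   have degree >= 1 (automatic), and kernels reject degree-0 explicitly.
#' @param indices Index identifiers (see [irr_indices()]) or `"all"`.
#' @return Named numeric vector, one element per requested index.
#' @export
#' @examples
#' irr_index(platonic_graph("icosahedron"), "AL")   # 0: the graph is regular
#' irr_index(chain_graph("CHO", 2), c("AL", "IRF"))
irr_index <- function(g, indices = "all") {
  check_graph(g)
  indices <- resolve_indices(indices)
  d <- igraph::degree(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  da <- d[ends[, 1L]]
  db <- d[ends[, 2L]]
  vapply(indices, function(id) kernel_sum(id, da, db), numeric(1))
}

#' Compute irregularity indices from an edge partition
#'
#' Evaluates `prefactor * sum(count * kernel(d1, d2))` over the degree-pair
#' classes. For any graph `g`,
#' `irr_index_partition(edge_partition(g), id)` equals `irr_index(g, id)`.
#'
#' @param p An [edge partition][as_edge_partition].
#' @param indices Index identifiers or `"all"`.
#' @return Named numeric vector.
#' @export
#' @examples
#' p <- family_partition(partition_family("OT"), n = 1)
#' irr_index_partition(p, "IRF")   # 576
irr_index_partition <- function(p, indices = "all") {
  stopifnot(inherits(p, "edge_partition") || is.data.frame(p))
  indices <- resolve_indices(indices)
  vapply(indices, function(id) kernel_sum(id, p$d1, p$d2, p$count), numeric(1))
}

#' Closed-form quadratic of an index on a partition family
#'
#' A partition family gives each degree-pair class an edge count that is a
#' quadratic a2 n^2 + a1 n + a0 in the dimension parameter n. Because every
#' index is linear in the class counts, the index itself is the quadratic
#' whose coefficients are the kernel-weighted sums of the class coefficients.
#'
#' @param family A [partition_family()].
#' @param index A single index identifier.
#' @return Object of class `closed_form`: numeric vector `c(a2, a1, a0)`.
#' @export
#' @examples
#' closed_form(partition_family("OT"), "IRDIF")   # 54 n^2
#' closed_form(partition_family("IS"), "IRRt")    # 135 n^2 - 15 n
closed_form <- function(family, index) {
  stopifnot(inherits(family, "partition_family"))
  index <- resolve_indices(index)
  stopifnot(length(index) == 1L)
  def <- .irr_kernel_defs[[index]]
  w <- def$prefactor * def$kernel(family$d1, family$d2)
  co <- c(a2 = sum(w * family$a2), a1 = sum(w * family$a1),
          a0 = sum(w * family$a0))
  structure(co, class = "closed_form", index = index,
            family = attr(family, "family"))
}

#' Evaluate a closed-form quadratic at given n
#'
#' @param cf A `closed_form` object (or any numeric `c(a2, a1, a0)`).
#' @param n Numeric vector of dimension parameters.
#' @return Numeric vector of values `a2 n^2 + a1 n + a0`.
#' @export
eval_closed_form <- function(cf, n) {
  unname(cf[[1L]] * n^2 + cf[[2L]] * n + cf[[3L]])
}

#' @export
print.closed_form <- function(x, digits = 6, ...) {
  lab <- paste0(attr(x, "index"),
                if (!is.null(attr(x, "family")))
                  paste0("(", attr(x, "family"), ")"))
  term <- function(v, s) {
    if (abs(v) < 1e-12) return(NULL)
    paste0(if (v < 0) "- " else "+ ", format(round(abs(v), digits)), s)
  }
  terms <- c(term(x[[1L]], " n^2"), term(x[[2L]], " n"), term(x[[3L]], ""))
  if (is.null(terms)) terms <- "0"
  terms <- paste(terms, collapse = " ")
  cat(lab, "=", sub("^\\+ ", "", terms), "\n")
  invisible(x)
}

#' Table of index values for a partition family over a range of n
#'
#' @param family A [partition_family()].
#' @param n Integer vector of dimension parameters (all >= 1); may be empty.
#' @param indices Index identifiers or `"all"`.
#' @return Data frame with one row per index (column `index`) and one column
#'   `n=<k>` per requested n, holding exact numeric values.
#' @export
#' @examples
#' index_table(partition_family("OT"), n = 1:5)
index_table <- function(family, n, indices = "all") {
  stopifnot(inherits(family, "partition_family"))
  if (length(n) > 0L) stopifnot(all(n >= 1), all(n == as.integer(n)))
  indices <- resolve_indices(indices)
  out <- data.frame(index = indices, stringsAsFactors = FALSE)
  for (k in n) {
    p <- family_partition(family, k)
    out[[paste0("n=", k)]] <- unname(irr_index_partition(p, indices))
  }
  out
}

#' Compare two partition families on one index
#'
#' Evaluates the index on both families for n = 1..n_max, reports per-n
#' signed differences (second minus first) and an overall dominance verdict.
#' A difference of exactly zero is a tie, not dominance.
#'
#' @param f1,f2 [partition_family()] objects.
#' @param index A single index identifier.
#' @param n_max Largest n (>= 1).
#' @return Data frame with columns `n`, `value1`, `value2`, `difference` and
#'   `leader` (`"f1"`, `"f2"` or `"tie"`), with attribute `verdict`, one of
#'   `"f2 dominates"`, `"f1 dominates"`, `"tie"` or `"mixed"`.
#' @export
#' @examples
#' cmp <- compare_families(partition_family("OT"), partition_family("IS"),
#'                         "IRDIF", n_max = 5)
#' attr(cmp, "verdict")   # "f2 dominates": the icosahedral net is more irregular
compare_families <- function(f1, f2, index, n_max) {
  stopifnot(n_max >= 1)
  index <- resolve_indices(index)
  stopifnot(length(index) == 1L)
  ns <- seq_len(n_max)
  v1 <- vapply(ns, function(k)
    irr_index_partition(family_partition(f1, k), index), numeric(1))
  v2 <- vapply(ns, function(k)
    irr_index_partition(family_partition(f2, k), index), numeric(1))
  diff <- v2 - v1
  leader <- ifelse(diff > 0, "f2", ifelse(diff < 0, "f1", "tie"))
  verdict <- if (all(diff > 0)) "f2 dominates"
    else if (all(diff < 0)) "f1 dominates"
    else if (all(diff == 0)) "tie"
    else "mixed"
  structure(data.frame(n = ns, value1 = v1, value2 = v2,
                       difference = diff, leader = leader),
            verdict = verdict, index = index)
}
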