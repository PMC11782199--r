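test_that("platonic skeletons have the right size and regularity", {
  oct <- platonic_graph("octahedron")
  expect_equal(igraph::vcount(oct), 6L)
  expect_equal(igraph::ecount(oct), 12L)
  expect_equal(unique(igraph::degree(oct)), 4L)
  expect_equal(as.data.frame(edge_partition(oct)),
               data.frame(d1 = 4L, d2 = 4L, count = 12L))
  # K(2,2,2) is the unique 4-regular graph on 6 vertices
  expect_true(igraph::isomorphic(oct, igraph::make_graph("Octahedral")))

  ico <- platonic_graph("icosahedron")
  expect_equal(igraph::vcount(ico), 12L)
  expect_equal(igraph::ecount(ico), 30L)
  expect_equal(unique(igraph::degree(ico)), 5L)
  expect_true(igraph::isomorphic(ico, igraph::make_graph("Icosahedron")))
})

test_that("chains have the closed-form vertex and edge counts for n <= 6", {
  for (n in 1:6) {
    expect_true(validate_counts(chain_graph("CHO", n), 5 * n + 1, 12 * n)$pass)
    expect_true(validate_counts(chain_graph("CHI", n), 11 * n + 1, 30 * n)$pass)
  }
  expect_error(chain_graph("CHO", 0), "n must be")
  expect_error(chain_graph("CHI", 2.5), "n must be")
})

test_that("a chain of one is the platonic solid itself", {
  expect_true(igraph::isomorphic(chain_graph("CHO", 1),
                                 platonic_graph("octahedron")))
  expect_true(igraph::isomorphic(chain_graph("CHI", 1),
                                 platonic_graph("icosahedron")))
})

test_that("chain edge partitions follow the shared-corner structure", {
  # each of the n-1 shared corners has doubled degree and contributes its
  # full edge star to the mixed class
  expect_equal(as.data.frame(edge_partition(chain_graph("CHI", 3))),
               data.frame(d1 = c(5L, 5L), d2 = c(5L, 10L),
                          count = c(70L, 20L)))
  for (n in 2:5) {
    cho <- as.data.frame(edge_partition(chain_graph("CHO", n)))
    expect_equal(cho$count[cho$d1 == 4 & cho$d2 == 8], 8L * (n - 1L))
    expect_equal(cho$count[cho$d1 == 4 & cho$d2 == 4], 12L * n - 8L * (n - 1L))
    chi <- as.data.frame(edge_partition(chain_graph("CHI", n)))
    expect_equal(chi$count[chi$d1 == 5 & chi$d2 == 10], 10L * (n - 1L))
  }
})

test_that("partition families carry the published coefficients and totals", {
  ot <- partition_family("OT")
  expect_equal(as.data.frame(ot),
               data.frame(d1 = c(4L, 4L, 8L), d2 = c(4L, 8L, 8L),
                          a2 = c(18L, 36L, 18L), a1 = c(12L, 0L, -12L),
                          a0 = c(0L, 0L, 0L)))
  expect_equal(colSums(ot[, c("a2", "a1", "a0")]),
               c(a2 = 72, a1 = 0, a0 = 0))

  is <- partition_family("IS")
  expect_equal(colSums(is[, c("a2", "a1", "a0")]),
               c(a2 = 180, a1 = 0, a0 = 0))
  expect_equal(family_partition(is, 1)$count, c(126, 48, 6))
  expect_equal(family_partition(ot, 0)$count, c(0, 0, 0))

  # evaluated counts are nonnegative integers for n = 1..8
  for (fam in list(ot, is)) for (n in 1:8) {
    cnt <- family_partition(fam, n)$count
    expect_true(all(cnt >= 0) && all(cnt == round(cnt)))
  }
})

test_that("family degree census satisfies handshake and incidence at n = 1..5", {
  for (kind in c("OT", "IS")) {
    fam <- partition_family(kind)
    cen <- degree_census_family(kind)
    vp <- attr(fam, "vertex_poly")
    ep <- attr(fam, "edge_poly")
    for (n in 1:5) {
      counts <- cen$a2 * n^2 + cen$a1 * n + cen$a0
      part <- family_partition(fam, n)
      expect_equal(sum(counts), sum(vp * c(n^2, n, 1)))
      expect_equal(sum(cen$degree * counts), 2 * sum(ep * c(n^2, n, 1)))
      for (i in seq_len(nrow(cen))) {
        d <- cen$degree[i]
        mult <- (part$d1 == d) + (part$d2 == d)
        expect_equal(sum(part$count * mult), d * counts[i])
      }
    }
  }
  expect_equal(degree_census_family("OT")$a2, c(18, 9))
  expect_equal(degree_census_family("IS")$a1, c(6, -3))
})

test_that("fixture suite is deterministic and covers the expected shapes", {
  fx1 <- fixture_graphs(seed = 42L)
  fx2 <- fixture_graphs(seed = 42L)
  expect_equal(names(fx1), names(fx2))
  for (nm in grep("^gnp", names(fx1), value = TRUE)) {
    expect_true(igraph::identical_graphs(fx1[[nm]], fx2[[nm]]))
  }
  star5 <- edge_partition(fx1$star5)
  expect_equal(as.data.frame(star5),
               data.frame(d1 = 1L, d2 = 5L, count = 5L))
  # fixture generation must not disturb the caller's RNG stream
  set.seed(7); a <- runif(1)
  set.seed(7); invisible(fixture_graphs()); b <- runif(1)
  expect_identical(a, b)
})
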