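test_that("kernel table has twelve symmetric, diagonal-null kernels", {
  ks <- irr_kernels()
  expect_length(ks, 12L)
  expect_equal(names(ks),
               c("IRDIF", "AL", "IRL", "IRLU", "IRLF", "IRF",
                 "IRLA", "IRD1", "IRA", "IRGA", "IRB", "IRRt"))
  for (id in names(ks)) {
    k <- ks[[id]]$kernel
    for (d in 1:10) {
      expect_equal(k(d, d), 0, info = paste(id, "diagonal at", d))
    }
    for (a in 1:8) for (b in 1:8) {
      expect_equal(k(a, b), k(b, a), info = paste(id, a, b))
      expect_gte(k(a, b), 0)
    }
  }
})

test_that("kernel spot values match hand computation", {
  ks <- irr_kernels()
  expect_equal(ks$IRF$kernel(4, 8), 16)
  expect_equal(ks$IRDIF$kernel(5, 10), 1.5)
  expect_equal(ks$AL$kernel(4, 8), 4)
  expect_equal(ks$IRL$kernel(4, 8), log(2))
  expect_equal(ks$IRLU$kernel(5, 10), 1)
  expect_equal(ks$IRLA$kernel(5, 10) * ks$IRLA$prefactor, 2/3)
  expect_equal(ks$IRRt$prefactor, 0.5)
  expect_error(irr_kernels("NOPE"), "unknown index")
})

test_that("graph computation matches brute-force oracle on fixtures", {
  fx <- fixture_graphs()
  for (nm in c("CHO2", "CHI2", "CHO3", "star5", "path4", "gnp1", "gnp2")) {
    g <- fx[[nm]]
    got <- irr_index(g)
    for (id in irr_indices()) {
      expect_lt(rel_err(got[[id]], oracle_index(g, id)), 1e-12)
    }
  }
  # frozen oracle values computed by hand from the chain structure:
  # CHO_2 has 8 edges of type (4,8); CHI_2 has 10 edges of type (5,10)
  expect_equal(unname(irr_index(fx$CHO2, "AL")), 32)
  expect_equal(unname(irr_index(fx$CHI2, "IRRt")), 25)
  expect_equal(unname(irr_index(fx$icosahedron, "AL")), 0)
})

test_that("every index vanishes on every regular fixture graph", {
  fx <- fixture_graphs()
  regular <- c("cycle3", "cycle4", "cycle5", "cycle6", "K2", "K3", "K4",
               "K5", "K6", "octahedron", "icosahedron", "CHO1", "CHI1")
  for (nm in regular) {
    vals <- irr_index(fx[[nm]])
    expect_equal(unname(vals), rep(0, 12), info = nm)
  }
})

test_that("partition computation agrees exactly with known cells and graphs", {
  ot1 <- family_partition(partition_family("OT"), 1)
  expect_equal(as.data.frame(ot1),
               data.frame(d1 = c(4, 4, 8), d2 = c(4, 8, 8),
                          count = c(30, 36, 6)))
  expect_equal(unname(irr_index_partition(ot1, "IRF")), 576)

  is2 <- family_partition(partition_family("IS"), 2)
  expect_equal(unname(irr_index_partition(is2, "IRLU")), 204)

  mono <- as_edge_partition(data.frame(d1 = 3, d2 = 3, count = 7))
  expect_equal(unname(irr_index_partition(mono)), rep(0, 12))

  # graph path and partition path agree on every fixture
  for (nm in names(fixture_graphs())) {
    g <- fixture_graphs()[[nm]]
    if (igraph::ecount(g) == 0) next
    expect_lt(max(rel_err(irr_index(g),
                          irr_index_partition(edge_partition(g)))),
              1e-12)
  }
})

test_that("degree-0 endpoints raise a domain error naming the index", {
  p <- data.frame(d1 = 0, d2 = 3, count = 1)
  class(p) <- c("edge_partition", "data.frame")
  expect_error(irr_index_partition(p, "IRL"), "IRL.*degree-0")
})

test_that("closed forms match partition evaluation and known quadratics", {
  ot <- partition_family("OT")
  is <- partition_family("IS")
  expect_equal(unclass(closed_form(ot, "IRDIF")),
               c(a2 = 54, a1 = 0, a0 = 0), ignore_attr = TRUE)
  expect_equal(unclass(closed_form(ot, "AL")),
               c(a2 = 144, a1 = 0, a0 = 0), ignore_attr = TRUE)
  expect_equal(unclass(closed_form(is, "IRRt")),
               c(a2 = 135, a1 = -15, a0 = 0), ignore_attr = TRUE)

  for (fam in list(ot, is)) {
    for (id in irr_indices()) {
      cf <- closed_form(fam, id)
      for (n in 1:5) {
        direct <- unname(irr_index_partition(family_partition(fam, n), id))
        expect_lt(rel_err(eval_closed_form(cf, n), direct), 1e-9)
      }
    }
  }
})

test_that("index table shapes and spot values are right", {
  tab <- index_table(partition_family("OT"), 3)
  expect_equal(tab[tab$index == "IRRt", "n=3"], 648)

  tab_is <- index_table(partition_family("IS"), 1)
  expect_equal(tab_is[tab_is$index == "IRD1", "n=1"], 48 * log(6))
  # the published cell (86.004432) carries a small printing artifact
  expect_lt(rel_err(tab_is[tab_is$index == "IRD1", "n=1"], 86.004432), 1e-4)

  empty <- index_table(partition_family("OT"), integer(0))
  expect_equal(names(empty), "index")
  expect_equal(nrow(empty), 12L)
})

test_that("family comparison yields per-n differences and a verdict", {
  ot <- partition_family("OT")
  is <- partition_family("IS")

  cmp <- compare_families(ot, is, "IRDIF", 5)
  expect_equal(attr(cmp, "verdict"), "f2 dominates")
  expect_equal(cmp$difference, 27 * (1:5)^2 - 9 * (1:5))

  tie <- compare_families(ot, ot, "AL", 3)
  expect_equal(attr(tie, "verdict"), "tie")
  expect_equal(unique(tie$leader), "tie")

  cmp2 <- compare_families(ot, is, "IRF", 2)
  expect_equal(cmp2$difference, c(624, 2796))
})

test_that("index identities and orderings hold on every computed input", {
  inputs <- c(lapply(names(fixture_graphs()), function(nm)
                irr_index(fixture_graphs()[[nm]])),
              lapply(1:5, function(n)
                irr_index_partition(family_partition(partition_family("OT"), n))),
              lapply(1:5, function(n)
                irr_index_partition(family_partition(partition_family("IS"), n))))
  for (vals in inputs) {
    expect_true(all(vals >= 0))
    expect_equal(vals[["AL"]], 2 * vals[["IRRt"]])
    expect_lte(vals[["IRLA"]], vals[["IRLU"]] + 1e-12)
    expect_gte(vals[["IRF"]], vals[["AL"]] - 1e-12)
  }
})
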