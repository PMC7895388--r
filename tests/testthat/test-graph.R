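test_that("toy region graph is the path D1 - D2 - D3", {
  g <- toy_region_graph()
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_true(igraph::are_adjacent(g, "D1", "D2"))
  expect_true(igraph::are_adjacent(g, "D2", "D3"))
  expect_false(igraph::are_adjacent(g, "D1", "D3"))
  st <- distance_stats(g)
  expect_equal(st$diameter, 2)
  expect_equal(sum(st$histogram$count), choose(3, 2))
})

test_that("region adjacency is symmetric and irreflexive", {
  cat0 <- main_catalog()
  labs <- cat0$regions$label
  expect_false(adjacent_regions(cat0, labs[1], labs[1]))
  g <- build_region_graph(cat0)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 0))
})

test_that("distance histogram covers all unordered pairs when connected", {
  cat0 <- main_catalog()
  st <- distance_stats(build_region_graph(cat0))
  expect_true(st$connected)
  expect_equal(sum(st$histogram$count), choose(st$n_nodes, 2))
  expect_true(all(st$histogram$distance >= 1))
})

test_that("wall witnesses separate into the two neighbouring regions", {
  cat0 <- main_catalog()
  walls <- cat0$walls[!cat0$walls$same_config, ]
  set.seed(16)
  pick <- walls[sample(nrow(walls), 25), ]
  for (k in seq_len(nrow(pick))) {
    ca <- cat0$cells[match(pick$cell_a[k], cat0$cells$id), ]
    cb <- cat0$cells[match(pick$cell_b[k], cat0$cells$id), ]
    # each cell's interior representative lies in its own region
    pa <- ca[, c("mu", "gamma", "eta", "kappa", "pi", "epsilon",
                 "theta1", "theta2")]
    pb <- cb[, c("mu", "gamma", "eta", "kappa", "pi", "epsilon",
                 "theta1", "theta2")]
    expect_equal(region_membership(cat0, pa), ca$region)
    expect_equal(region_membership(cat0, pb), cb$region)
    # and the regions are adjacent in the graph
    g <- build_region_graph(cat0)
    expect_true(igraph::are_adjacent(g, ca$region, cb$region))
  }
})

test_that("a diameter path links a lone high-symmetric state to an
           asymmetric-pair configuration", {
  cat0 <- main_catalog()
  g <- build_region_graph(cat0)
  d <- igraph::distances(g)
  diam <- max(d[is.finite(d)])
  ends <- which(d == diam, arr.ind = TRUE)
  labs <- rownames(d)
  found <- FALSE
  for (r in seq_len(nrow(ends))) {
    a <- cat0$regions[cat0$regions$label == labs[ends[r, 1]], ]
    b <- cat0$regions[cat0$regions$label == labs[ends[r, 2]], ]
    lone_high <- function(x) x$attractors == "8"
    has_pair <- function(x) x$n_asymmetric >= 2
    if ((lone_high(a) && has_pair(b)) || (lone_high(b) && has_pair(a))) {
      found <- TRUE; break
    }
  }
  expect_true(found)
})

test_that("GraphML export round-trips the edge set", {
  g <- toy_region_graph()
  path <- tempfile(fileext = ".graphml")
  export_graph(g, path, "graphml")
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g2), 3L)
  expect_equal(igraph::ecount(g2), 2L)
  el <- function(gr) {
    e <- igraph::as_edgelist(gr)
    sort(apply(e, 1, function(r) paste(sort(r), collapse = "-")))
  }
  expect_equal(el(g2), el(g))
  # DOT export writes a file
  pd <- tempfile(fileext = ".dot")
  export_graph(g, pd, "dot")
  expect_true(file.size(pd) > 0)
  expect_error(export_graph(g, pd, "gexf"))
})

test_that("main graph exports with node attributes intact", {
  cat0 <- main_catalog()
  g <- build_region_graph(cat0)
  path <- tempfile(fileext = ".graphml")
  export_graph(g, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g2), nrow(cat0$regions))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name, cat0$regions$label)
})
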