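test_that("connectivity threshold equals the maximum-spanning-tree bottleneck", {
  w <- diag(3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.8
  w[2, 3] <- w[3, 2] <- 0.7
  expect_equal(connectivity_threshold(fake_ibs(w)), 0.8)

  wc <- matrix(0.42, 4, 4)
  expect_equal(connectivity_threshold(fake_ibs(wc)), 0.42)
})

test_that("bottleneck threshold matches brute-force search over all weights", {
  set.seed(23)
  for (r in 1:20) {
    n <- 6
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2)
    w <- w + t(w)
    ibs <- fake_ibs(w)
    # brute force: largest unique weight whose >= graph is connected
    cand <- sort(unique(w[upper.tri(w)]), decreasing = TRUE)
    bf <- NA
    for (t in cand) {
      g <- igraph::graph_from_adjacency_matrix((w >= t) * 1, mode = "undirected",
                                               diag = FALSE)
      if (igraph::is_connected(g)) { bf <- t; break }
    }
    expect_equal(connectivity_threshold(ibs), bf)
  }
})

test_that("edge rules are exact and isolated nodes are retained", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.8
  w[2, 3] <- w[3, 2] <- 0.75
  w[1, 4] <- w[4, 1] <- 0.2
  ibs <- fake_ibs(w)

  net <- build_network(ibs, 0.75)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_equal(igraph::vcount(net$graph), 4)

  expect_equal(igraph::ecount(build_network(ibs, 0.75, rule = "gt")$graph), 2)
  expect_equal(igraph::ecount(build_network(ibs, 0)$graph), 6)
  expect_equal(igraph::ecount(build_network(ibs, 1, rule = "gt")$graph), 0)
})

test_that("star and path betweenness/diameter match closed forms", {
  star <- matrix(0, 10, 10)
  star[1, 2:10] <- star[2:10, 1] <- 1
  s <- summarize_network(build_network(adj_ibs(star), 0.5))
  expect_equal(s$betweenness$betweenness[1], 1.0)
  expect_equal(s$betweenness$id[1], "n01")
  expect_true(all(s$betweenness$betweenness[-1] == 0))
  expect_equal(s$diameter, 2)
  expect_equal(s$average_degree, 2 * 9 / 10)

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  sp <- summarize_network(build_network(adj_ibs(path), 0.5))
  expect_equal(sp$betweenness$betweenness[sp$betweenness$id == "n02"], 1.0)
  expect_equal(sp$diameter, 2)
})

test_that("betweenness and diameter match exhaustive enumeration on small graphs", {
  set.seed(29)
  for (r in 1:25) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, runif(1, 0.3, 0.8))
    if (sum(adj) == 0) next
    s <- summarize_network(build_network(adj_ibs(adj), 0.5))
    expected <- bf_betweenness(adj)
    got <- s$betweenness$betweenness[match(sprintf("n%02d", 1:n),
                                           s$betweenness$id)]
    expect_equal(got, expected, tolerance = 1e-12)
    expect_equal(s$diameter, bf_diameter(adj))
  }
})

test_that("hub removal fragments a star and removes the bridge of two triangles", {
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  hr <- hub_removal_analysis(build_network(adj_ibs(star), 0.5))
  expect_equal(hr$removed, "n01")
  expect_equal(hr$after$n_nodes, 1)
  expect_equal(hr$after$n_edges, 0)

  # triangles {1,2,3} and {5,6,7} joined through node 4
  adj <- matrix(0, 7, 7)
  for (e in list(c(1,2), c(1,3), c(2,3), c(5,6), c(5,7), c(6,7),
                 c(3,4), c(4,5))) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1
  }
  hr2 <- hub_removal_analysis(build_network(adj_ibs(adj), 0.5))
  expect_equal(hr2$removed, "n04")
  expect_equal(hr2$after$n_nodes, 3)
  expect_equal(hr2$after$diameter, 1)
})

test_that("removing a star-plus-rim hub strictly increases the diameter", {
  # hub connected to all 8 rim nodes; rim is a sparse cycle
  n <- 9
  adj <- matrix(0, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 1
  for (i in 2:(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
  adj[2, n] <- adj[n, 2] <- 1
  hr <- hub_removal_analysis(build_network(adj_ibs(adj), 0.5))
  expect_equal(hr$removed, "n01")
  expect_gt(hr$after$diameter, hr$before$diameter)
})

test_that("auto-threshold network is connected; one gap above disconnects it", {
  set.seed(31)
  for (r in 1:10) {
    g <- random_geno(12, 200)
    ibs <- ibs_matrix(g)
    t0 <- connectivity_threshold(ibs)
    net <- build_network(ibs, t0)
    expect_true(igraph::is_connected(net$graph))
    w <- ibs$ibs[upper.tri(ibs$ibs)]
    above <- sort(unique(w[w > t0]))
    if (length(above) > 0) {
      net2 <- build_network(ibs, above[1])
      expect_false(igraph::is_connected(net2$graph))
    }
  }
})

test_that("nearest-rank percentile highlighting follows the >= rule", {
  expect_equal(nearest_rank_percentile(c(0.8, 0.8, 0.8), 85), 0.8)
  expect_equal(nearest_rank_percentile(1:100, 85), 85)

  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w[1, 3] <- w[3, 1] <- w[2, 3] <- w[3, 2] <- 0.8
  edges <- network_edges(build_network(fake_ibs(w), 0.5))
  expect_true(all(edges$highlight))  # constant sample: all at the percentile
})

test_that("GraphML export round-trips nodes, edges and weights", {
  g <- random_geno(8, 150, seed = 37)
  ibs <- ibs_matrix(g)
  net <- build_network(ibs, connectivity_threshold(ibs))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net$graph))
  el1 <- igraph::as_edgelist(net$graph)
  el2 <- igraph::as_edgelist(back)
  key <- function(el) sort(paste(pmin(el[, 1], el[, 2]),
                                 pmax(el[, 1], el[, 2])))
  expect_equal(key(el2), key(el1))
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(net$graph)$weight),
               tolerance = 1e-12)
  expect_true("betweenness" %in% igraph::vertex_attr_names(back))

  # empty edge set still yields valid GraphML with all nodes
  net0 <- build_network(ibs, 1, rule = "gt")
  export_graph(net0, path)
  back0 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back0), 8)
  expect_equal(igraph::ecount(back0), 0)
})
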