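test_that("density and centralization match the textbook cases", {
  expect_equal(network_density(und_net(5, complete_edges(5))), 1.0)
  expect_equal(network_density(und_net(5, star_edges(5))), 0.4)
  # path A-B-C-D: 3 of 6 possible edges
  path4 <- und_net(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(network_density(path4), 0.5)

  expect_equal(degree_centralization(und_net(4, complete_edges(4))), 0)
  expect_equal(degree_centralization(und_net(7, complete_edges(7))), 0)
  for (n in 3:7) expect_equal(degree_centralization(und_net(n, star_edges(n))), 1)
  # path degrees 1,2,2,1 -> (1+0+0+1)/6
  expect_equal(degree_centralization(path4), 2 / 6)

  expect_error(network_density(und_net(1, NULL)), "fewer than 2")
  expect_error(degree_centralization(und_net(2, rbind(c(1, 2)))), "fewer than 3")
})

test_that("metrics agree with the adjacency-matrix oracle on random graphs", {
  set.seed(501)
  for (rep in 1:500) {
    n <- sample(3:6, 1)
    net <- random_und_net(n)
    A <- adj_of(net)
    expect_equal(network_density(net), density_oracle(A), tolerance = 1e-12)
    expect_equal(degree_centralization(net), centralization_oracle(A),
                 tolerance = 1e-12)
    expect_gte(network_density(net), 0)
    expect_lte(network_density(net), 1)
    expect_gte(degree_centralization(net), 0)
    expect_lte(degree_centralization(net), 1)
  }
})

test_that("metrics agree with igraph on a handful of graphs", {
  set.seed(502)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    net <- random_und_net(n)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    expect_equal(network_density(net), igraph::edge_density(g),
                 tolerance = 1e-12)
    expect_equal(degree_centralization(net),
                 igraph::centr_degree(g, loops = FALSE)$centralization,
                 tolerance = 1e-12)
  }
})

test_that("adding an edge raises density by exactly 2/(n(n-1))", {
  set.seed(503)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    all_e <- complete_edges(n)
    k <- sample(0:(nrow(all_e) - 1), 1)
    idx <- sample(nrow(all_e), k)
    before <- und_net(n, all_e[idx, , drop = FALSE])
    extra <- sample(setdiff(seq_len(nrow(all_e)), idx), 1)
    after <- und_net(n, all_e[c(idx, extra), , drop = FALSE])
    expect_equal(network_density(after) - network_density(before),
                 2 / (n * (n - 1)), tolerance = 1e-12)
  }
})

test_that("density extremes force zero centralization", {
  for (n in 3:7) {
    expect_equal(degree_centralization(und_net(n, complete_edges(n))), 0)
    expect_equal(degree_centralization(und_net(n, NULL)), 0)
  }
})

test_that("reciprocity counts only respondent-respondent ties", {
  # {A->B, B->A, A->C}: 2 of 3 ties returned
  expect_equal(network_reciprocity(dir_net(3, rbind(c(1, 2), c(2, 1), c(1, 3)))),
               2 / 3)
  # fully mutual 3-clique
  clique <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  expect_equal(network_reciprocity(dir_net(3, clique)), 1)
  # only tie points at a non-respondent: no assessable ties
  expect_true(is.na(network_reciprocity(
    dir_net(4, rbind(c(1, 4)), responded = c(T, T, T, F)))))
  # matches the enumerating oracle on random directed nets with non-response
  set.seed(504)
  for (rep in 1:100) {
    n <- sample(3:6, 1)
    responded <- runif(n) > 0.25
    pairs <- expand.grid(from = 1:n, to = 1:n)
    pairs <- pairs[pairs$from != pairs$to & responded[pairs$from], ]
    pick <- as.matrix(pairs[runif(nrow(pairs)) < 0.5, , drop = FALSE])
    net <- dir_net(n, pick, responded = responded)
    expect_equal(network_reciprocity(net), reciprocity_oracle(net))
  }
})

test_that("metrics_bundle assembles the four properties and degenerate cases", {
  pr <- complete_practice("PR1", 4)
  dn <- build_directed_network(pr, "DM")
  b <- metrics_bundle(dn, symmetrize(dn))
  expect_equal(b$n_nodes, 4)
  expect_equal(b$n_edges, 6)
  expect_equal(b$density, 1)
  expect_equal(b$centralization, 0)
  expect_equal(b$reciprocity, 1)

  hub <- practice_roster("PR2", list(
    resp_member("M1", c("M2", "M3", "M4"), role = "physician"),
    resp_member("M2"), resp_member("M3"), resp_member("M4")))
  dn2 <- build_directed_network(hub, "DM")
  b2 <- metrics_bundle(dn2, symmetrize(dn2))
  expect_equal(b2$n_edges, 3)
  expect_equal(b2$density, 0.5)
  expect_equal(b2$centralization, 1)

  empty <- practice_roster("PR3", list(resp_member("M1"), resp_member("M2"),
                                       resp_member("M3")))
  dn3 <- build_directed_network(empty, "DM")
  b3 <- metrics_bundle(dn3, symmetrize(dn3))
  expect_equal(b3$n_edges, 0)
  expect_equal(b3$density, 0)
  expect_equal(b3$centralization, 0)
  expect_true(is.na(b3$reciprocity))

  expect_error(metrics_bundle(dn2, symmetrize(dn3)), "same practice")
})

test_that("graphml export writes node attributes", {
  pr <- complete_practice("PR1", 3, nonresp = 3)
  un <- symmetrize(build_directed_network(pr, "DM"))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(un, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_setequal(igraph::vertex_attr_names(g),
                  c("name", "role", "responded", "id"))
})
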