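two_cliques <- function(size = 10) {
  n <- 2 * size
  w <- matrix(0, n, n)
  w[1:size, 1:size] <- 1
  w[(size + 1):n, (size + 1):n] <- 1
  diag(w) <- 0
  weighted_network(w)
}

test_that("Louvain splits two cliques with modularity 1/2", {
  set.seed(1)
  net <- two_cliques(10)
  p <- detect_louvain(net)
  expect_equal(n_distinct <- length(unique(p$membership)), 2)
  expect_equal(p$objective, 0.5)
  # communities coincide with the cliques
  expect_equal(ari(p, part(rep(1:2, each = 10))), 1)
})

test_that("Louvain objective matches an independent modularity evaluation", {
  set.seed(2)
  for (i in 1:10) {
    net <- random_network(sample(10:30, 1))
    p <- detect_louvain(net)
    g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    q_igraph <- igraph::modularity(g, p$membership,
                                   weights = igraph::E(g)$weight)
    expect_equal(p$objective, q_igraph, tolerance = 1e-12)
    expect_equal(p$objective, modularity_value(net, p), tolerance = 1e-12)
  }
})

test_that("Louvain never does worse than the trivial partition", {
  set.seed(3)
  w <- matrix(0.5, 12, 12); diag(w) <- 0
  p <- detect_louvain(weighted_network(w))
  expect_gte(p$objective, 0)
})

test_that("degenerate all-zero networks are rejected", {
  z <- weighted_network(matrix(0, 5, 5))
  expect_error(detect_louvain(z), "degenerate")
  expect_error(detect_spinglass(z), "degenerate")
})

test_that("spinglass finds the ground state of two disconnected cliques", {
  set.seed(4)
  net <- two_cliques(4)
  p <- detect_spinglass(net, max_communities = 4)
  expect_equal(length(unique(p$membership)), 2)
  expect_equal(ari(p, part(rep(1:2, each = 4))), 1)
  expect_equal(p$objective, brute_ground_state(net$weights, 4))
  expect_equal(p$objective, hamiltonian_value(net, p))
})

test_that("gamma near zero collapses spinglass to one community", {
  set.seed(5)
  net <- random_network(12)
  p <- detect_spinglass(net, max_communities = 4, gamma = 1e-9)
  expect_equal(length(unique(p$membership)), 1)
})

test_that("spinglass objective is self-consistent with direct H evaluation", {
  set.seed(6)
  for (i in 1:5) {
    net <- random_network(15)
    p <- detect_spinglass(net, max_communities = 3)
    expect_equal(p$objective, hamiltonian_value(net, p), tolerance = 1e-12)
  }
})

test_that("detection is invariant to node relabeling on separated structure", {
  set.seed(7)
  des <- sim_design(30, 3, within = c(30, 2), between = c(1, 30),
                    perturb_prob = 0)
  master <- make_master_assignment(des)
  net <- simulate_network(master, des$within, des$between)
  perm <- sample(30)
  net_p <- weighted_network(net$weights[perm, perm],
                            node_ids = net$node_ids[perm])
  for (det in list(detect_louvain,
                   function(n) detect_spinglass(n, max_communities = 4))) {
    p1 <- det(net)
    p2 <- det(net_p)
    # same partition up to relabeling, same objective
    m2 <- p2$membership[names(p1$membership)]
    expect_equal(ari(p1, partition(m2)), 1)
    expect_equal(p1$objective, p2$objective, tolerance = 1e-10)
  }
})

test_that("seeded detection runs are reproducible", {
  des <- sim_design(25, 3, within = c(7, 8), between = c(1.5, 8))
  set.seed(8); net <- simulate_network(make_master_assignment(des),
                                       des$within, des$between)
  set.seed(42); a <- detect_louvain(net)
  set.seed(42); b <- detect_louvain(net)
  expect_identical(a, b)
  set.seed(42); c1 <- detect_spinglass(net, 4)
  set.seed(42); c2 <- detect_spinglass(net, 4)
  expect_identical(c1, c2)
})

test_that("consensus community count recovers the planted number", {
  set.seed(9)
  des <- sim_design(40, 3, within = c(8, 8), between = c(1, 8),
                    perturb_prob = 0)
  nets <- replicate(3, simulate_network(make_master_assignment(des),
                                        des$within, des$between),
                    simplify = FALSE)
  expect_equal(consensus_community_count(nets, 3:6), 3L)
  expect_error(consensus_community_count(nets, integer(0)), "non-empty")
  # single network, single candidate
  k1 <- consensus_community_count(nets[1], 4)
  expect_true(k1 >= 1 && k1 <= 4)
})
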