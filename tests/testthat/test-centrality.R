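test_that("strength sums absolute incident weights", {
  W <- matrix(c(0, .5, -.3, .5, 0, 0, -.3, 0, 0), 3)
  expect_equal(unname(node_strength(W)), c(0.8, 0.5, 0.3))
  expect_equal(unname(node_strength(matrix(0, 4, 4))), rep(0, 4))
  set.seed(40)
  W19 <- rand_weighted_graph(19)
  loop_sum <- sapply(1:19, function(i) sum(abs(W19[i, ])))
  expect_lt(max(abs(node_strength(W19) - loop_sum)), 1e-12)
  expect_error(node_strength(matrix(c(0, 1, 2, 0), 2)), class = "bridgenet_input")
})

test_that("a path graph puts all betweenness on the middle node", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.7
  W[2, 3] <- W[3, 2] <- 0.2
  expect_equal(unname(node_betweenness(W)), c(0, 1, 0))
})

test_that("equal shortest paths split credit on the 4-cycle", {
  W <- matrix(0, 4, 4)
  for (ij in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
    W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- 0.4
  expect_equal(unname(node_betweenness(W)), rep(0.5, 4))
  expect_equal(unname(node_betweenness(W, normalize = TRUE)), rep(0.5 / 3, 4))
})

test_that("isolated nodes and degree-one nodes have zero betweenness", {
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.5
  bt <- node_betweenness(W)  # nodes 4, 5 isolated; 1, 3 leaves
  expect_equal(unname(bt[c(1, 3, 4, 5)]), rep(0, 4))
})

test_that("betweenness matches exhaustive enumeration on small graphs", {
  for (s in 1:20) {
    p <- sample(4:8, 1)
    W <- rand_weighted_graph(p, density = 0.5, seed = 400 + s)
    expect_lt(max(abs(node_betweenness(W) - bf_betweenness(W))), 1e-9)
  }
})

test_that("betweenness matches igraph on weighted graphs", {
  set.seed(41)
  for (s in 1:5) {
    W <- rand_weighted_graph(10, density = 0.6, seed = 500 + s)
    idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(idx, directed = FALSE)
    ig <- igraph::betweenness(g, weights = 1 / abs(W[idx]))
    mine <- node_betweenness(W)[seq_len(max(idx))]
    expect_equal(unname(mine), unname(ig), tolerance = 1e-9)
  }
})

test_that("the distance transform changes which paths are shortest", {
  # direct edge 0.5 vs a two-hop route through strong 0.9 edges:
  # 1/|w| favors the direct edge, 1-|w| favors the detour
  W <- matrix(0, 3, 3)
  W[1, 3] <- W[3, 1] <- 0.5
  W[1, 2] <- W[2, 1] <- 0.9
  W[2, 3] <- W[3, 2] <- 0.9
  expect_equal(unname(node_betweenness(W, distance = "inv_abs"))[2], 0)
  expect_equal(unname(node_betweenness(W, distance = "one_minus_abs"))[2], 1)
})

test_that("bridge expected influence sums signed cross-community weights", {
  nodes <- c("a1", "a2", "b1")
  W <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  W["a1", "a2"] <- W["a2", "a1"] <- 0.3
  W["a1", "b1"] <- W["b1", "a1"] <- 0.2
  comm <- c(a1 = "A", a2 = "A", b1 = "B")
  expect_equal(unname(bridge_expected_influence(W, comm)), c(0.2, 0, 0.2))
  # no cross edges -> all zero
  W2 <- W; W2["a1", "b1"] <- W2["b1", "a1"] <- 0
  expect_equal(max(abs(bridge_expected_influence(W2, comm))), 0)
  expect_error(bridge_expected_influence(W, c(a1 = "A", a2 = "A")),
               class = "bridgenet_input")
})

test_that("total BEI equals twice the sum of signed cross-community weights", {
  set.seed(42)
  W <- rand_weighted_graph(12)
  rownames(W) <- colnames(W) <- paste0("n", 1:12)
  comm <- setNames(rep(c("x", "y", "z"), each = 4), rownames(W))
  bei <- bridge_expected_influence(W, comm)
  cross <- outer(comm, comm, "!=") & upper.tri(W)
  expect_equal(sum(bei), 2 * sum(W[cross]), tolerance = 1e-12)
})

test_that("centralities transform correctly under rescaling of weights", {
  set.seed(43)
  W <- rand_weighted_graph(9)
  rownames(W) <- colnames(W) <- paste0("n", 1:9)
  comm <- setNames(rep(c("x", "y", "z"), each = 3), rownames(W))
  k <- 2.7
  expect_equal(node_strength(k * W), k * node_strength(W), tolerance = 1e-12)
  expect_equal(bridge_expected_influence(k * W, comm),
               k * bridge_expected_influence(W, comm), tolerance = 1e-12)
  expect_equal(node_betweenness(k * W), node_betweenness(W), tolerance = 1e-12)
})

test_that("relabeling nodes permutes all centralities identically", {
  set.seed(44)
  W <- rand_weighted_graph(8)
  rownames(W) <- colnames(W) <- paste0("n", 1:8)
  comm <- setNames(rep(c("x", "y"), each = 4), rownames(W))
  perm <- sample(8)
  Wp <- W[perm, perm]
  expect_equal(unname(node_strength(Wp)), unname(node_strength(W))[perm])
  expect_equal(unname(node_betweenness(Wp)),
               unname(node_betweenness(W))[perm], tolerance = 1e-12)
  expect_equal(unname(bridge_expected_influence(Wp, comm[perm])),
               unname(bridge_expected_influence(W, comm))[perm],
               tolerance = 1e-12)
})

test_that("the centrality table carries all measures for a fitted network", {
  spec <- synthetic_spec(n_per_group = c(old = 300))
  net <- suppressWarnings(ebic_glasso(preprocess(simulate_items(spec, "old"))))
  ct <- centrality_table(net)
  expect_setequal(names(ct), c("node", "domain", "strength", "betweenness",
                               "betweenness_normalized", "bei"))
  expect_equal(nrow(ct), 19)
  expect_equal(ct$strength, unname(node_strength(net$W)))
  expect_equal(ct$betweenness_normalized,
               ct$betweenness / (18 * 17 / 2), tolerance = 1e-12)
})

test_that("the two-step BEI variant adds neighbor influence", {
  nodes <- c("a1", "a2", "b1")
  W <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  W["a1", "a2"] <- W["a2", "a1"] <- 0.3
  W["a1", "b1"] <- W["b1", "a1"] <- 0.2
  comm <- c(a1 = "A", a2 = "A", b1 = "B")
  b1 <- bridge_expected_influence(W, comm)
  b2 <- bridge_expected_influence(W, comm, two_step = TRUE)
  # a1's cross edge to b1 gains b1's own expected influence (0.2)
  expect_equal(unname(b2["a1"] - b1["a1"]), 0.2 * sum(W["b1", ]), tolerance = 1e-12)
})
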