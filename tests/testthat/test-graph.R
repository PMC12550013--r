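test_that("kNN graph construction matches hand enumeration", {
  # colinear points 0, 1, 3: with k = 1, node 2 is nearest to both ends
  emb <- matrix(c(0, 1, 3), ncol = 1)
  g <- build_knn_graph(emb, k = 1L)
  expect_equal(g$nn[, 1], c(2L, 1L, 2L))
  # union-symmetrised candidate edges are 1-2 and 2-3, but their kNN sets
  # are disjoint, so the Jaccard weights vanish and the edges are dropped
  expect_equal(nrow(g$edges), 0L)

  # coincident points: tie broken by node index
  emb2 <- matrix(c(0, 0, 5, 5.4, 10, 10.1), ncol = 1)
  g2 <- build_knn_graph(emb2, k = 2L)
  expect_equal(g2$nn[1, ], c(2L, 3L))
  expect_equal(g2$nn[2, ], c(1L, 3L))
  # edge 1-2: N(1) = {2,3}, N(2) = {1,3} -> |int| = 1, weight 1/(4-1)
  e12 <- g2$edges[g2$edges$i == 1 & g2$edges$j == 2, ]
  expect_equal(e12$w, 1 / 3)

  # saturation: k = n - 1 yields the complete graph
  set.seed(4)
  emb3 <- matrix(rnorm(12), 6)
  g3 <- build_knn_graph(emb3, k = 5L)
  expect_equal(nrow(g3$edges), choose(6, 2))
  expect_true(all(g3$edges$w > 0 & g3$edges$w <= 1))
  expect_error(build_knn_graph(emb3, k = 6L), "parameter error")
})

test_that("modularity matches hand computations", {
  # two disjoint unit edges, partitioned by edge: Q = 2 * (1/2 - 1/4)
  g <- list(n = 4L, edges = data.frame(i = c(1L, 3L), j = c(2L, 4L),
                                       w = c(1, 1)))
  expect_equal(modularity(g, c(1, 1, 2, 2)), 0.5)
  # everything in one community: Q = w/W - 1 = 0
  expect_equal(modularity(g, c(1, 1, 1, 1)), 0)
  # planted two-block graph: structured labels beat random ones
  set.seed(9)
  emb <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  gb <- build_knn_graph(emb, k = 5L)
  truth <- rep(1:2, each = 20)
  expect_gt(modularity(gb, truth), modularity(gb, sample(truth)))
})

test_that("louvain separates disconnected cliques and is deterministic", {
  clique_edges <- function(nodes) {
    p <- t(combn(nodes, 2))
    data.frame(i = p[, 1], j = p[, 2], w = 1)
  }
  g <- structure(list(n = 8L,
                      edges = rbind(clique_edges(1:4), clique_edges(5:8))),
                 class = "jip_graph")
  p <- louvain(g, seed = 3L)
  expect_equal(p$n_communities, 2L)
  expect_equal(length(unique(p$labels[1:4])), 1L)
  expect_equal(length(unique(p$labels[5:8])), 1L)
  expect_identical(louvain(g, seed = 3L)$labels, p$labels)
  expect_gte(p$modularity, 0)
  # modularity trace never decreases across levels
  expect_true(all(diff(p$trace) >= -1e-12))
  expect_error(louvain(structure(list(n = 0L,
                                      edges = data.frame(i = integer(),
                                                         j = integer(),
                                                         w = numeric())),
                                 class = "jip_graph")), "empty")
})

test_that("louvain attains the exhaustive modularity maximum on toy graphs", {
  graphs <- list(
    # two 4-cliques joined by a weak bridge
    {
      p <- t(combn(1:4, 2)); q <- t(combn(5:8, 2))
      structure(list(n = 8L,
                     edges = rbind(data.frame(i = p[, 1], j = p[, 2], w = 1),
                                   data.frame(i = q[, 1], j = q[, 2], w = 1),
                                   data.frame(i = 4L, j = 5L, w = 0.2))),
                class = "jip_graph")
    },
    # two triangles and a path node
    structure(list(n = 7L,
                   edges = data.frame(i = c(1, 1, 2, 4, 4, 5, 3, 7),
                                      j = c(2, 3, 3, 5, 6, 6, 7, 4),
                                      w = c(1, 1, 1, 1, 1, 1, 0.5, 0.5))),
              class = "jip_graph"),
    # weighted star plus triangle
    structure(list(n = 6L,
                   edges = data.frame(i = c(1, 1, 1, 4, 4, 5),
                                      j = c(2, 3, 4, 5, 6, 6),
                                      w = c(2, 2, 0.3, 1, 1, 1))),
              class = "jip_graph")
  )
  for (g in graphs) {
    best <- best_partition_bruteforce(g)
    p <- louvain(g, seed = 7L)
    expect_equal(p$modularity, best$modularity, tolerance = 1e-9)
  }
})

test_that("louvain agrees with the igraph reference on a blob graph", {
  set.seed(12)
  emb <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 8), 30),
               matrix(rnorm(60, -8), 30))
  g <- build_knn_graph(emb, k = 8L)
  p <- louvain(g, seed = 1L)
  ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                      vertices = data.frame(name = 1:90))
  igraph::E(ig)$weight <- g$edges$w
  ref <- igraph::membership(igraph::cluster_louvain(ig))
  ref <- ref[as.character(1:90)]
  expect_equal(adjusted_rand_index(p$labels, ref), 1)
  # and the returned Q equals modularity(graph, labels)
  expect_equal(p$modularity, modularity(g, p$labels))
})

test_that("adjusted Rand index has its fixed points and matches mclust", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(1:6, rep(1, 6)), 0)
  set.seed(3)
  a <- sample(1:4, 60, TRUE)
  b <- sample(1:3, 60, TRUE)
  expect_equal(adjusted_rand_index(a, b),
               mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)[a]
  expect_equal(adjusted_rand_index(a, perm), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("LISI measures local label mixing", {
  set.seed(8)
  # one label everywhere: lower bound 1
  emb <- matrix(rnorm(80), 40)
  expect_equal(lisi(emb, rep("a", 40), perplexity = 10), rep(1, 40))
  # two labels perfectly interleaved on a line: near-complete mixing
  line <- matrix(seq_len(60), ncol = 1)
  lab <- rep(c("a", "b"), 30)
  expect_equal(mean(lisi(line, lab, perplexity = 10)), 2, tolerance = 0.1)
  # distant pure blobs: near 1 despite two labels
  blobs <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 50), 20))
  lab2 <- rep(c("a", "b"), each = 20)
  expect_equal(mean(lisi(blobs, lab2, perplexity = 8)), 1, tolerance = 0.05)
  expect_error(lisi(blobs, lab2, perplexity = 40), "perplexity")
})
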