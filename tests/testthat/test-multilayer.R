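test_that("the structural layer mirrors the refined matrix", {
  w <- mat_from_edges(4, i = c(1, 1, 2, 3), j = c(2, 3, 4, 4),
                      w = c(0.5, 1.62, 0.2, 0.9))
  lay <- build_structural_layer(cm_from_matrix(w))
  expect_equal(nrow(lay$edges), 4)
  expect_equal(lay$edges$w[lay$edges$i == 1 & lay$edges$j == 3], 1.62)
  empty <- build_structural_layer(cm_from_matrix(matrix(0, 3, 3)))
  expect_equal(nrow(empty$edges), 0)
})

test_that("average degree is 2|E|/n", {
  lay <- layer_graph(4, data.frame(i = c(1, 1, 2), j = c(2, 3, 4),
                                   w = c(1, 1, 1)), "structural")
  expect_equal(structural_average_degree(lay), 1.5)
  expect_equal(structural_average_degree(
    layer_graph(5, data.frame(i = integer(), j = integer(), w = numeric()),
                "structural")), 0)
  # n = 90 with 360 edges -> 8, constructed as a ring plus chords
  n <- 90
  i <- rep(seq_len(n), each = 8)
  j <- as.vector(vapply(seq_len(n), function(v) as.integer((v + 0:7) %% n + 1),
                        integer(8)))
  keep <- i < j
  e <- unique(data.frame(i = i[keep], j = j[keep]))
  e <- e[seq_len(360), ]
  e$w <- 1
  expect_equal(structural_average_degree(layer_graph(n, e, "structural")), 8)
})

test_that("functional layer keeps each node's strongest connections", {
  # dense 4-node matrix with distinct weights, k* = 1
  w <- mat_from_edges(4, i = c(1, 1, 1, 2, 2, 3), j = c(2, 3, 4, 3, 4, 4),
                      w = c(0.9, 0.2, 0.3, 0.8, 0.1, 0.4))
  lay <- build_functional_layer(cm_from_matrix(w, "functional"),
                                avg_s = 1, theta = 1)
  # brute-force nominations: argmax of each row
  noms <- lapply(1:4, function(i) which.max(replace(w[i, ], i, 0)))
  expected <- unique(t(apply(cbind(1:4, unlist(noms)), 1, sort)))
  got <- as.matrix(lay$edges[, c("i", "j")])
  expect_equal(nrow(lay$edges), nrow(expected))
  expect_true(all(paste(got[, 1], got[, 2]) %in%
                  paste(expected[, 1], expected[, 2])))
  expect_true(nrow(lay$edges) >= 2 && nrow(lay$edges) <= 4)

  # zero entries are never nominated
  w0 <- matrix(0, 3, 3)
  w0[1, 2] <- w0[2, 1] <- 0.5
  lay0 <- build_functional_layer(cm_from_matrix(w0, "functional"),
                                 avg_s = 4, theta = 0.5)
  expect_equal(nrow(lay0$edges), 1)  # node 3 contributes nothing

  # k* = max(1, round(theta * avg_s)), round half up
  wf <- cm_from_matrix(mat_from_edges(5, i = c(1, 1, 1, 1),
                                      j = 2:5, w = c(.4, .3, .2, .1)),
                       "functional")
  lay2 <- build_functional_layer(wf, avg_s = 8, theta = 0.5)  # k* = 4
  expect_equal(sum(lay2$edges$i == 1 | lay2$edges$j == 1), 4)
  # k* floors at 1: every leaf still nominates its single edge, so the
  # union keeps the whole star
  lay3 <- build_functional_layer(wf, avg_s = 0.2, theta = 0.5)
  expect_equal(nrow(lay3$edges), 4)

  # deterministic tie-break by ascending index
  wt <- cm_from_matrix(mat_from_edges(4, i = c(1, 1, 1), j = 2:4,
                                      w = c(.5, .5, .5)), "functional")
  l1 <- build_functional_layer(wt, avg_s = 1, theta = 1)
  expect_equal(l1$edges$j[l1$edges$i == 1][1], 2)
})

test_that("weak-neighbour counts use the layer mean, each edge counted once", {
  # node 1 has neighbour weights {0.1, 0.2, 0.9}; the extra edge (3,4,0.2)
  # brings the layer mean to exactly 0.35
  lay <- layer_graph(4, data.frame(i = c(1, 1, 1, 3), j = c(2, 3, 4, 4),
                                   w = c(0.1, 0.2, 0.9, 0.2)), "structural")
  expect_equal(mean(lay$edges$w), 0.35)
  expect_equal(weak_neighbor_count(lay, 1), 2)
  # isolated node
  lay2 <- layer_graph(3, data.frame(i = 1, j = 2, w = 1), "structural")
  expect_equal(weak_neighbor_count(lay2, 3), 0L)
  # all edges equal: w = mean satisfies <=, so |T_i| = degree(i)
  ring <- layer_graph(5, data.frame(i = c(1, 2, 3, 4, 1), j = c(2, 3, 4, 5, 5),
                                    w = rep(0.7, 5)), "structural")
  for (i in 1:5) expect_equal(weak_neighbor_count(ring, i), 2)
})

test_that("informativeness is ln(e + |T_i|), >= 1, permutation-equivariant", {
  expect_equal(log(exp(1) + 0), 1)
  W <- toy_weights()$s
  lay <- build_structural_layer(cm_from_matrix(W))
  info <- informativeness(lay)
  expect_equal(info, oracle_info(W), tolerance = 1e-12)
  expect_true(all(info >= 1))
  expect_equal(informativeness(
    layer_graph(3, data.frame(i = 1, j = 2, w = 5), "structural"))[3], 1)
  # spot values
  expect_equal(log(exp(1) + 3), 1.7435, tolerance = 1e-4)
  expect_equal(log(exp(1) + 2), 1.5514, tolerance = 1e-4)

  # relabeling nodes permutes the vector identically
  set.seed(5)
  perm <- sample(6)
  Wp <- W[perm, perm]
  infop <- informativeness(build_structural_layer(cm_from_matrix(Wp)))
  expect_equal(infop, info[perm], tolerance = 1e-12)
})

test_that("multilayer assembly stores informativeness per layer", {
  W <- toy_weights()
  s <- build_structural_layer(cm_from_matrix(W$s))
  f <- build_structural_layer(cm_from_matrix(W$f))
  f$modality <- "functional"
  net <- assemble_multilayer(s, f, theta = 0.5)
  expect_equal(net$info_s, oracle_info(W$s), tolerance = 1e-12)
  expect_equal(net$info_f, oracle_info(W$f), tolerance = 1e-12)
  expect_equal(net$avg_s, 2 * nrow(s$edges) / 6)

  # identical layers: identical informativeness
  net2 <- assemble_multilayer(s, s, theta = 0.5)
  expect_equal(net2$info_s, net2$info_f)

  # empty structural layer: info all ln(e) = 1
  s0 <- layer_graph(6, data.frame(i = integer(), j = integer(),
                                  w = numeric()), "structural")
  net3 <- assemble_multilayer(s0, f, theta = 0.5)
  expect_equal(net3$info_s, rep(1, 6))

  expect_error(assemble_multilayer(
    s, layer_graph(4, data.frame(i = 1, j = 2, w = 1), "functional")),
    "mismatch")
})

test_that("if a node's connections are all strong its informativeness is 1", {
  # one heavy edge at node 5-6 pushes the mean above node 1's edges only if
  # weights differ; with node 4 holding the single heaviest edge, |T_4| can
  # be 0 only when all its edges exceed the mean
  lay <- layer_graph(4, data.frame(i = c(1, 2, 1), j = c(2, 3, 4),
                                   w = c(0.1, 0.2, 5)), "structural")
  mw <- mean(lay$edges$w)
  expect_true(all(c(5) > mw))
  expect_equal(weak_neighbor_count(lay, 4), 0)
  expect_equal(informativeness(lay)[4], 1)
})
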