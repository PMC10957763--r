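test_that("alias sampling reproduces the target distribution in O(1) draws", {
  probs <- c(0.05, 0.1, 0.15, 0.2, 0.22, 0.28)
  tab <- alias_table(probs * 7)  # unnormalised input is fine
  # exact: the table's cell/alias masses reconstruct the distribution
  implied <- numeric(6)
  for (cell in 1:6) {
    implied[cell] <- implied[cell] + tab$prob[cell] / 6
    implied[tab$alias[cell]] <- implied[tab$alias[cell]] +
      (1 - tab$prob[cell]) / 6
  }
  expect_equal(implied, probs, tolerance = 1e-12)
  n <- 1e6
  x <- alias_sample(tab, n, seed = 1)
  expect_equal(attr(x, "rng_draws"), 2 * n)  # exactly two uniforms per draw
  freq <- tabulate(x, length(probs)) / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(freq - probs) < 3 * se))
  # determinism and input validation
  expect_identical(as.integer(alias_sample(tab, 100, seed = 3)),
                   as.integer(alias_sample(tab, 100, seed = 3)))
  expect_error(alias_table(c(-1, 2)), "nonnegative")
  expect_error(alias_table(numeric(0)), "nonnegative")
})

test_that("layer choice probabilities follow the informativeness ratio", {
  expect_equal(layer_choice_probs(1.3, 1.3),
               c(structural = 0.5, functional = 0.5))
  expect_equal(layer_choice_probs(1, 1),
               c(structural = 0.5, functional = 0.5))
  p <- layer_choice_probs(log(exp(1) + 2), 1)
  expect_equal(unname(p["structural"]),
               log(exp(1) + 2) / (log(exp(1) + 2) + 1), tolerance = 1e-12)
  expect_equal(unname(p["structural"]), 0.6081, tolerance = 1e-4)
  expect_equal(sum(p), 1)
  expect_error(layer_choice_probs(0, 1), "positive")
})

test_that("intra-layer distributions implement the biased second-order rule", {
  # current node 1 with neighbours: 2 (w=1, the previous node),
  # 3 (w=2, adjacent to previous), 4 (w=1, distance 2 from previous)
  W <- mat_from_edges(4, i = c(1, 1, 1, 2), j = c(2, 3, 4, 3),
                      w = c(1, 2, 1, 0.5))
  s <- build_structural_layer(cm_from_matrix(W))
  net <- assemble_multilayer(s, s, theta = 0.5)
  d <- intra_layer_distribution(net, "structural", current = 1, previous = 2,
                                p = 0.1, q = 1.6)
  raw <- c(`2` = 1 / 0.1, `3` = 2, `4` = 1 / 1.6)
  expect_equal(d, raw / sum(raw), tolerance = 1e-12)
  expect_equal(unname(d), c(0.7921, 0.1584, 0.0495), tolerance = 1e-4)

  # no previous edge in the layer: plain weight-proportional choice
  d0 <- intra_layer_distribution(net, "structural", current = 1,
                                 previous = NULL, p = 0.1, q = 1.6)
  expect_equal(unname(d0), c(1, 2, 1) / 4, tolerance = 1e-12)

  # p = q = 1 collapses to weight-proportional even with a previous edge
  d1 <- intra_layer_distribution(net, "structural", current = 1, previous = 2,
                                 p = 1, q = 1)
  expect_equal(unname(d1), c(1, 2, 1) / 4, tolerance = 1e-12)

  # distributions always sum to 1 over a grid of states
  W6 <- toy_weights()
  s6 <- build_structural_layer(cm_from_matrix(W6$s))
  f6 <- build_structural_layer(cm_from_matrix(W6$f))
  f6$modality <- "functional"
  net6 <- assemble_multilayer(s6, f6)
  for (lay in c("structural", "functional")) {
    Wl <- if (lay == "structural") W6$s else W6$f
    for (cur in 1:6) {
      for (prev in c(list(NULL), as.list(which(Wl[cur, ] > 0)))) {
        dd <- intra_layer_distribution(net6, lay, cur, prev,
                                       p = 0.1, q = 1.6)
        expect_equal(sum(dd), 1, tolerance = 1e-12)
      }
    }
  }
  expect_error(intra_layer_distribution(
    assemble_multilayer(
      layer_graph(3, data.frame(i = 1, j = 2, w = 1), "structural"),
      layer_graph(3, data.frame(i = 1, j = 2, w = 1), "functional")),
    "structural", current = 3), "isolated")
})

test_that("walks have the contracted length and handle isolation", {
  net <- toy_multilayer()
  wk <- simulate_walk(net, start = 1, walk_config(walk_length = 10, seed = 4))
  expect_length(wk, 11)
  expect_equal(wk[1], 1)
  expect_true(all(wk >= 1 & wk <= 6))

  # node isolated in both layers terminates immediately
  s <- layer_graph(3, data.frame(i = 1, j = 2, w = 1), "structural")
  net2 <- assemble_multilayer(s, s)
  expect_equal(simulate_walk(net2, 3, walk_config(seed = 1)), 3L)

  # node isolated in one layer is forced into the other
  f <- layer_graph(3, data.frame(i = c(1, 2), j = c(2, 3), w = c(1, 1)),
                   "functional")
  net3 <- assemble_multilayer(s, f)
  wks <- simulate_walk(net3, 3, walk_config(walk_length = 1, seed = 2),
                       n_walks = 50)
  expect_true(all(vapply(wks, function(x) x[2], integer(1)) == 2))
})

test_that("the corpus is complete, reproducible and shuffled per repetition", {
  net <- toy_multilayer()
  cfg <- walk_config(walk_length = 5, walks_per_node = 10, seed = 9)
  corp <- generate_corpus(net, cfg)
  expect_length(corp$walks, 6 * 10)
  starts <- vapply(corp$walks, `[`, integer(1), 1)
  expect_equal(as.vector(table(starts)), rep(10, 6))  # r walks per node
  # identical seed, identical corpus
  corp2 <- generate_corpus(net, cfg)
  expect_identical(corp$walks, corp2$walks)
  # different seed differs
  corp3 <- generate_corpus(net, walk_config(walk_length = 5,
                                            walks_per_node = 10, seed = 10))
  expect_false(identical(corp$walks, corp3$walks))
  # corpus file format: one whitespace-delimited walk per line
  path <- withr::local_tempfile(fileext = ".txt")
  write_corpus(corp, path)
  lines <- readLines(path)
  expect_length(lines, 60)
  expect_equal(as.integer(strsplit(lines[1], " ")[[1]]), corp$walks[[1]])
})

test_that("empirical first-step frequencies track the exact distribution", {
  # a light version of the acceptance check: one seed, one start node
  W <- toy_weights()
  net <- toy_multilayer()
  start <- 2
  nwalk <- 2e4
  wks <- simulate_walk(net, start, walk_config(p = 0.1, q = 1.6,
                                               walk_length = 1, seed = 21),
                       n_walks = nwalk)
  obs <- tabulate(vapply(wks, `[`, integer(1), 2), 6)
  expected <- oracle_first_step(W$s, W$f, start, p = 0.1, q = 1.6)
  expect_gt(chisq_gof_p(obs, expected), 0.01)
})
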