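test_that("x_neighbors finds vertices within x hops of the source set", {
  g1 <- g1_fixture()
  nb1 <- x_neighbors(g1, "a", 1)
  expect_equal(nb1$members, c("b", "c"))
  expect_equal(unname(nb1$best_value), c(1, 1))

  nb2 <- x_neighbors(g1, "a", 2)
  expect_equal(nb2$members, c("b", "c", "d"))
  expect_equal(unname(nb2$best_value[["d"]]), 2)

  g2 <- g2_fixture()
  expect_equal(x_neighbors(g2, "a", 5)$members, "b")
})

test_that("x_neighbors validates inputs and excludes sources", {
  g1 <- g1_fixture()
  expect_error(x_neighbors(g1, "nope", 1), class = "min_unknown_interactor")
  expect_error(x_neighbors(g1, "a", 0), class = "min_invalid_parameter")
  expect_error(x_neighbors(g1, "a", 1.5), class = "min_invalid_parameter")
  nb <- x_neighbors(g1, c("a", "b"), 2)
  expect_length(intersect(nb$members, c("a", "b")), 0)
})

test_that("x_subgraph induces over sources plus members", {
  g1 <- g1_fixture()
  sub <- x_subgraph(g1, "a", 1)
  expect_equal(interactor_ids(sub), c("a", "b", "c"))
  expect_equal(count_interactions(sub), 3L)

  expect_same_graph(x_subgraph(g1, interactor_ids(g1), 3), g1)

  subd <- x_subgraph(g1, "d", 1)
  expect_equal(interactor_ids(subd), c("c", "d"))
  expect_equal(count_interactions(subd), 1L)
})

test_that("x_weighted_neighbors applies the strict max-product threshold", {
  g1 <- g1_fixture()
  nb <- x_weighted_neighbors(g1, "a", 0.6)
  expect_equal(nb$members, c("b", "c"))
  expect_equal(nb$best_value, c(b = 0.9, c = 0.72))   # d best 0.432, excluded

  expect_length(x_weighted_neighbors(g1, "a", 0.95)$members, 0)

  ones <- build_graph(data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "d"),
                                 weight = c(1, 1, 1)),
                      vertices = c("a", "b", "c", "d", "iso"))
  nb1 <- x_weighted_neighbors(ones, "a", 0.5)
  expect_equal(nb1$members, c("b", "c", "d"))   # whole component minus source
})

test_that("x_weighted_neighbors validates mode and parameters", {
  g2 <- g2_fixture()
  expect_error(x_weighted_neighbors(g2, "a", 0.5), class = "min_wrong_mode")
  g1 <- g1_fixture()
  expect_error(x_weighted_neighbors(g1, "a", 0), class = "min_invalid_parameter")
  expect_error(x_weighted_neighbors(g1, "a", 1), class = "min_invalid_parameter")
  expect_error(x_weighted_neighbors(g1, "zz", 0.5),
               class = "min_unknown_interactor")
})

test_that("x_weighted_subgraph induces over the query and its members", {
  g1 <- g1_fixture()
  sub <- x_weighted_subgraph(g1, "a", 0.6)
  expect_equal(interactor_ids(sub), c("a", "b", "c"))

  lone <- x_weighted_subgraph(g1, "a", 0.95)
  expect_equal(interactor_ids(lone), "a")
  expect_equal(count_interactions(lone), 0L)
})

test_that("weighted membership and products equal the path-enumeration oracle", {
  for (seed in 1:20) {
    g <- rand_min(5 + seed %% 8, p = 0.35, labelled = TRUE, seed = 200 + seed)
    set.seed(300 + seed)
    i <- sample(interactor_ids(g), 1)
    x <- runif(1, 0.05, 0.9)
    nb <- x_weighted_neighbors(g, i, x)
    oracle <- oracle_max_product(g, i)
    expect_equal(nb$members, names(oracle)[oracle > x])
    expect_equal(unname(nb$best_value), unname(oracle[oracle > x]))
  }
})

test_that("neighborhoods shrink as x grows (anti-monotonicity)", {
  for (seed in 1:30) {
    g <- rand_min(12, p = 0.3, labelled = TRUE, seed = 400 + seed)
    set.seed(500 + seed)
    i <- sample(interactor_ids(g), 1)
    xs <- sort(runif(2, 0.05, 0.95))
    lo <- x_weighted_neighbors(g, i, xs[1])$members
    hi <- x_weighted_neighbors(g, i, xs[2])$members
    expect_true(all(hi %in% lo))

    k <- sort(sample(1:4, 2))
    lo_k <- x_neighbors(g, i, k[2])$members
    hi_k <- x_neighbors(g, i, k[1])$members
    expect_true(all(hi_k %in% lo_k))
  }
})

test_that("best_value for a direct neighbor is at least the edge weight", {
  g <- rand_min(10, p = 0.5, labelled = TRUE, seed = 7)
  i <- interactor_ids(g)[1]
  nb <- x_weighted_neighbors(g, i, 0.05)
  e <- g$edges
  direct <- rbind(data.frame(id = e$to[e$from == i], w = e$weight[e$from == i]),
                  data.frame(id = e$from[e$to == i], w = e$weight[e$to == i]))
  direct <- direct[direct$w > 0.05, ]
  for (k in seq_len(nrow(direct))) {
    expect_gte(nb$best_value[[direct$id[k]]], direct$w[k])
  }
})

test_that("results are invariant to partition count and executor", {
  for (p in c(1L, 2L, 7L)) {
    g <- rand_min(15, p = 0.3, labelled = TRUE, seed = 99, partitions = p)
    i <- interactor_ids(g)[3]
    ref <- x_weighted_neighbors(g, i, 0.3)
    par <- x_weighted_neighbors(g, i, 0.3, executor = "parallel", workers = 4)
    expect_identical(ref$members, par$members)
    expect_identical(ref$best_value, par$best_value)
  }
})
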