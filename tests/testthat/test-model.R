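test_that("build_graph collapses parallel edges keeping the maximum weight", {
  g <- build_graph(data.frame(from = c("a", "b"), to = c("b", "a"),
                              weight = c(0.9, 0.4)))
  expect_equal(count_interactions(g), 1L)
  expect_equal(g$edges$weight, 0.9)
  expect_equal(g$edges$from, "a")
  expect_equal(g$edges$to, "b")
})

test_that("build_graph drops self-loops with a warning counting them", {
  expect_warning(
    g <- build_graph(data.frame(from = c("a", "a"), to = c("a", "b"),
                                weight = c(0.5, 0.7))),
    "1 self-loop"
  )
  expect_equal(count_interactions(g), 1L)
  expect_equal(g$edges$weight, 0.7)
})

test_that("vertices not mentioned by any edge are kept isolated", {
  g <- build_graph(data.frame(from = "a", to = "b", weight = 0.9),
                   vertices = c("a", "b", "c"))
  expect_equal(count_interactors(g), 3L)
  expect_equal(count_interactions(g), 1L)
  expect_true("c" %in% interactor_ids(g))
})

test_that("invalid edge sets are rejected", {
  expect_error(
    build_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
                           weight = c(0.5, NA))),
    class = "min_invalid_input"
  )
  expect_error(
    build_graph(data.frame(from = "a", to = "b", weight = 1.5)),
    class = "min_invalid_input"
  )
  expect_error(
    build_graph(data.frame(from = "a\tb", to = "c")),
    class = "min_invalid_input"
  )
  expect_error(build_graph(NULL, NULL), class = "min_invalid_input")
  expect_error(build_graph(data.frame(from = "a", to = "b"), partitions = 0),
               class = "min_invalid_parameter")
})

test_that("interaction count never exceeds input rows; equal iff clean input", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 12L
    ids <- letters[1:6]
    from <- sample(ids, n, replace = TRUE)
    to <- sample(ids, n, replace = TRUE)
    g <- suppressWarnings(build_graph(data.frame(from = from, to = to),
                                      vertices = ids))
    expect_lte(count_interactions(g), n)
    clean <- sum(from != to) == n &&
      !anyDuplicated(paste(pmin(from, to), pmax(from, to)))
    if (clean) expect_equal(count_interactions(g), n)
    expect_true(mintools:::validate_min_graph(g))
  }
})

test_that("induced_subgraph keeps exactly the edges inside the node set", {
  g1 <- g1_fixture()
  sub <- induced_subgraph(g1, c("a", "b", "c"))
  expect_equal(interactor_ids(sub), c("a", "b", "c"))
  expect_equal(nrow(sub$edges), 3L)
  expect_setequal(paste(sub$edges$from, sub$edges$to),
                  c("a b", "b c", "a c"))

  expect_same_graph(induced_subgraph(g1, interactor_ids(g1)), g1)

  sub2 <- induced_subgraph(g1, c("a", "d"))
  expect_equal(count_interactors(sub2), 2L)
  expect_equal(count_interactions(sub2), 0L)
})

test_that("induced_subgraph is idempotent and rejects unknown ids", {
  g1 <- g1_fixture()
  once <- induced_subgraph(g1, c("a", "b", "c"))
  twice <- induced_subgraph(once, c("a", "b", "c"))
  expect_same_graph(once, twice)
  err <- expect_error(induced_subgraph(g1, c("a", "zzz")),
                      class = "min_unknown_interactor")
  expect_match(conditionMessage(err), "zzz")
})

test_that("partition count changes no observable structure", {
  for (p in c(1L, 2L, 7L, 16L)) {
    g <- g1_fixture(partitions = p)
    expect_equal(g$partitions, p)
    expect_true(all(g$edges$partition >= 0L & g$edges$partition < p))
    expect_same_graph(g, g1_fixture())
  }
  # partition assignment is a stable pure function of the canonical pair
  expect_identical(g1_fixture(7L)$edges$partition,
                   g1_fixture(7L)$edges$partition)
})
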