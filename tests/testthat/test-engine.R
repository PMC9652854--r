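test_that("min-label propagation labels components like union-find", {
  g2 <- g2_fixture()
  res <- run_supersteps(g2, prog_min_label(g2))
  labels <- interactor_ids(g2)[unlist(res$states)]
  expect_equal(unname(labels), c("a", "a", "c", "c", "c"))
  expect_lte(res$supersteps_executed, 3L)
})

test_that("a program that never sends halts after superstep 0", {
  g2 <- g2_fixture()
  prog <- superstep_program(
    initial_state = function(id) id,
    vprog = function(id, state, msg) state,
    send_msg = function(src, ss, dst, ds, w) NULL,
    merge_msg = function(a, b) a
  )
  res <- run_supersteps(g2, prog)
  expect_equal(res$supersteps_executed, 1L)
  expect_equal(res$states, as.list(setNames(interactor_ids(g2),
                                            interactor_ids(g2))))
})

test_that("max-product propagation reproduces exhaustive path products", {
  g1 <- g1_fixture()
  res <- run_supersteps(g1, prog_max_product("a", threshold = 0))
  expect_equal(res$states,
               list(a = 1.0, b = 0.9, c = 0.72, d = 0.432))
})

test_that("max_iterations caps the number of vprog rounds", {
  # path a-b-c-d-e as an unweighted chain
  g <- build_graph(data.frame(from = c("a", "b", "c", "d"),
                              to = c("b", "c", "d", "e")))
  prog <- prog_bfs("a")
  prog$max_iterations <- 2
  res <- run_supersteps(g, prog)
  expect_equal(res$supersteps_executed, 2L)
  # only one message round ran: d and e not yet reached
  expect_equal(res$states$b, 1)
  expect_equal(res$states$d, Inf)
})

test_that("serial and parallel executors agree for any workers/partitions", {
  for (seed in 1:5) {
    g <- rand_min(25, p = 0.15, labelled = TRUE, seed = seed,
                  partitions = c(1L, 2L, 7L)[seed %% 3 + 1])
    src <- interactor_ids(g)[1]
    for (prog_fn in list(function() prog_min_label(g),
                         function() prog_bfs(src),
                         function() prog_max_product(src, 0.1))) {
      ref <- run_supersteps(g, prog_fn(), executor = "serial")
      for (w in c(1L, 4L)) {
        got <- run_supersteps(g, prog_fn(), executor = "parallel",
                              workers = w)
        expect_identical(got, ref)
      }
    }
  }
})

test_that("repeated runs are deterministic", {
  g <- rand_min(30, p = 0.2, labelled = TRUE, seed = 42, partitions = 4L)
  a <- run_supersteps(g, prog_min_label(g), executor = "parallel", workers = 3)
  b <- run_supersteps(g, prog_min_label(g), executor = "parallel", workers = 3)
  expect_identical(a, b)
})

test_that("a non-commutative or non-associative merge is rejected", {
  err <- expect_error(
    superstep_program(
      initial_state = function(id) 0,
      vprog = function(id, s, m) s,
      send_msg = function(src, ss, dst, ds, w) NULL,
      merge_msg = function(a, b) a - b,
      sample_messages = list(1, 2, 5)
    ),
    class = "min_contract_violation"
  )
  expect_match(conditionMessage(err), "commutative")

  expect_error(
    superstep_program(
      initial_state = function(id) 0,
      vprog = function(id, s, m) s,
      send_msg = function(src, ss, dst, ds, w) NULL,
      merge_msg = function(a, b) 2 * min(a, b),   # commutative, not associative
      sample_messages = list(1, 2, 5)
    ),
    class = "min_contract_violation"
  )
})

test_that("min-label propagation matches the union-find oracle on random graphs", {
  for (seed in 1:25) {
    g <- rand_min(5 + (seed * 7) %% 26, p = 0.12, labelled = FALSE,
                  seed = seed)
    res <- run_supersteps(g, prog_min_label(g))
    labels <- setNames(interactor_ids(g)[unlist(res$states)],
                       interactor_ids(g))
    expect_identical(labels, oracle_components(g))
  }
})
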