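# Shared fixtures, built in code.
#
# G1: weighted 4-vertex graph (a,b,0.9) (b,c,0.8) (a,c,0.5) (c,d,0.6).
# G2: unweighted, two components {a,b} and {c,d,e}.
# G3: dispersion fixture u-s1..s4, v-s1..s4, u-v, s1-s2.

g1_fixture <- function(partitions = 1L) {
  build_graph(
    data.frame(from = c("a", "b", "a", "c"),
               to = c("b", "c", "c", "d"),
               weight = c(0.9, 0.8, 0.5, 0.6)),
    partitions = partitions
  )
}

g2_fixture <- function(partitions = 1L) {
  build_graph(
    data.frame(from = c("a", "c", "d"), to = c("b", "d", "e")),
    partitions = partitions
  )
}

g3_fixture <- function(partitions = 1L) {
  build_graph(
    data.frame(from = c(rep("u", 4), rep("v", 4), "u", "s1"),
               to = c(paste0("s", 1:4), paste0("s", 1:4), "v", "s2")),
    partitions = partitions
  )
}

# seeded Erdos-Renyi random MIN; possibly disconnected, isolated vertices kept
rand_min <- function(n, p = 0.3, labelled = TRUE, seed = 1L,
                     partitions = 1L) {
  set.seed(seed)
  ids <- sprintf("v%03d", seq_len(n))
  pairs <- utils::combn(ids, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  if (labelled && !any(keep)) keep[1L] <- TRUE   # a labelled graph needs an edge
  w <- if (labelled) stats::runif(sum(keep)) else rep(NA_real_, sum(keep))
  build_graph(
    data.frame(from = pairs[1L, keep], to = pairs[2L, keep], weight = w),
    vertices = ids, partitions = partitions
  )
}

graph_signature <- function(g) {
  list(v = g$vertices$id,
       e = g$edges[c("from", "to")],
       w = if (g$labelled) signif(g$edges$weight, 6) else NULL)
}

expect_same_graph <- function(a, b) {
  expect_identical(graph_signature(a), graph_signature(b))
}
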