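# Seeded synthetic MIN generation and independent brute-force oracles.
#
# The oracles deliberately share no traversal code with the engine-based
# implementations: they are plain enumerations (simple-path DFS, queue BFS,
# union-find, pair loop with reachability DFS) against which the superstep
# programs are validated.

#' Generate a synthetic molecular interaction network
#'
#' Builds a connected preferential-attachment graph: an initial clique on
#' `attach + 1` vertices, then each new vertex attaches to `attach` distinct
#' existing vertices chosen with probability proportional to degree. This
#' emulates the hub-dominated degree structure of real protein-protein
#' interaction networks (a few very high-degree hubs, many low-degree
#' interactors); only the qualitative shape is emulated, not any particular
#' database snapshot. Vertex ids are `"p000001"`, `"p000002"`, ...
#'
#' Generation is fully reproducible: equal parameters and seed yield
#' byte-identical graphs (the caller's RNG state is left untouched).
#'
#' @param n vertex count, at least 2.
#' @param attach edges per new vertex, at least 1 and less than `n`.
#' @param weights `"uniform"` (labels i.i.d. uniform on \[0, 1\]),
#'   `"beta"` (shape parameters in `weight_params`, default `c(2, 2)`), or
#'   `"constant"` (single value in `weight_params`, default 0.5).
#' @param weight_params numeric parameters of the weight distribution.
#' @param labelled draw edge confidence labels? If `FALSE` the graph is
#'   unlabelled.
#' @param seed integer RNG seed.
#' @param partitions edge partition count passed to [build_graph()].
#' @return a `min_graph` with `n` vertices.
#' @export
generate_min <- function(n, attach = 2L,
                         weights = c("uniform", "beta", "constant"),
                         weight_params = NULL, labelled = TRUE, seed = 1L,
                         partitions = 1L) {
  weights <- match.arg(weights)
  n <- as.integer(n)
  attach <- as.integer(attach)
  if (is.na(n) || n < 2L) abort_param("n must be an integer >= 2")
  if (is.na(attach) || attach < 1L) abort_param("attach must be >= 1")
  if (attach >= n) abort_param("attach must be smaller than n")

  m0 <- attach + 1L
  with_local_seed(as.integer(seed), {
    seed_pairs <- utils::combn(seq_len(m0), 2L)
    n_new <- n - m0
    m_total <- ncol(seed_pairs) + attach * n_new
    from <- integer(m_total)
    to <- integer(m_total)
    from[seq_len(ncol(seed_pairs))] <- seed_pairs[1L, ]
    to[seq_len(ncol(seed_pairs))] <- seed_pairs[2L, ]

    # multiset of edge endpoints; sampling from it is degree-proportional
    ends <- integer(2L * m_total)
    ne <- 2L * ncol(seed_pairs)
    ends[seq_len(ne)] <- c(seed_pairs)

    k <- ncol(seed_pairs)
    if (n_new > 0L) {
      for (v in (m0 + 1L):n) {
        targets <- integer(0)
        while (length(targets) < attach) {
          t <- ends[sample.int(ne, 1L)]
          if (!(t %in% targets)) targets <- c(targets, t)
        }
        for (t in targets) {
          k <- k + 1L
          from[k] <- v
          to[k] <- t
          ends[ne + 1L] <- v
          ends[ne + 2L] <- t
          ne <- ne + 2L
        }
      }
    }

    w <- if (!labelled) {
      rep(NA_real_, m_total)
    } else {
      switch(weights,
        uniform = stats::runif(m_total),
        beta = {
          p <- weight_params %||% c(2, 2)
          stats::rbeta(m_total, p[1L], p[2L])
        },
        constant = {
          v <- (weight_params %||% 0.5)[1L]
          if (v < 0 || v > 1) abort_param("constant weight must lie in [0, 1]")
          rep(v, m_total)
        })
    }

    ids <- sprintf("p%06d", seq_len(n))
    build_graph(
      data.frame(from = ids[from], to = ids[to], weight = w,
                 stringsAsFactors = FALSE),
      vertices = ids, partitions = partitions
    )
  })
}

# adjacency list shared by the oracles (plain data prep, not traversal logic)
oracle_adjacency <- function(g) {
  vids <- g$vertices$id
  adj <- stats::setNames(vector("list", length(vids)), vids)
  e <- g$edges
  for (k in seq_len(nrow(e))) {
    a <- e$from[k]; b <- e$to[k]; w <- e$weight[k]
    adj[[a]] <- rbind(adj[[a]], data.frame(id = b, w = w))
    adj[[b]] <- rbind(adj[[b]], data.frame(id = a, w = w))
  }
  adj
}

#' Oracle: best path products by exhaustive simple-path enumeration
#'
#' Reference implementation for the weighted neighborhood: for every vertex
#' reachable from `i`, the maximum over all simple paths of the product of
#' edge labels, found by explicit depth-first path enumeration. Exponential;
#' guarded to networks of at most 15 vertices.
#'
#' @param g a labelled `min_graph` with at most 15 vertices.
#' @param i source interactor id.
#' @return named numeric vector of best products for reachable vertices
#'   (source excluded; unreachable vertices absent).
#' @export
oracle_max_product <- function(g, i) {
  stopifnot(inherits(g, "min_graph"))
  if (!g$labelled) abort_wrong_mode("oracle_max_product requires labels")
  check_known(g, i)
  if (nrow(g$vertices) > 15L) {
    abort_param("oracle_max_product is exhaustive; |V| must be <= 15")
  }
  adj <- oracle_adjacency(g)
  best <- new.env(hash = TRUE)

  walk <- function(v, prod, visited) {
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      t <- nb$id[k]
      if (t %in% visited) next
      p <- prod * nb$w[k]
      if (p > get0(t, envir = best, inherits = FALSE, ifnotfound = -Inf)) {
        assign(t, p, envir = best)
      }
      walk(t, p, c(visited, t))
    }
  }
  walk(i, 1, i)
  out <- unlist(as.list(best))
  if (is.null(out)) return(stats::setNames(numeric(0), character(0)))
  out[csort(names(out))]
}

#' Oracle: k-hop distances by queue breadth-first search
#'
#' Reference implementation for the unlabelled neighborhood: classic
#' FIFO-queue BFS from the source set, truncated at depth `x`.
#'
#' @param g a `min_graph`.
#' @param S character vector of source ids.
#' @param x maximum hop distance (may be `Inf`).
#' @return named numeric vector of hop distances for non-source vertices
#'   within `x` hops.
#' @export
oracle_khop <- function(g, S, x) {
  stopifnot(inherits(g, "min_graph"))
  check_known(g, S)
  adj <- oracle_adjacency(g)
  dist <- stats::setNames(rep(Inf, nrow(g$vertices)), g$vertices$id)
  dist[S] <- 0
  queue <- as.list(S)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    if (dist[[v]] >= x) next
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (t in nb$id) {
      if (is.infinite(dist[[t]])) {
        dist[[t]] <- dist[[v]] + 1
        queue <- c(queue, t)
      }
    }
  }
  d <- dist[is.finite(dist) & dist > 0]
  d[csort(names(d))]
}

#' Oracle: connected components by union-find
#'
#' Reference implementation for [connected_components()]: disjoint-set
#' forest with path compression, one union per edge; each class is labelled
#' by its lexicographically smallest member.
#'
#' @param g a `min_graph`.
#' @return named character vector mapping interactor id to component id.
#' @export
oracle_components <- function(g) {
  stopifnot(inherits(g, "min_graph"))
  vids <- g$vertices$id
  parent <- seq_along(vids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ef <- match(g$edges$from, vids)
  et <- match(g$edges$to, vids)
  for (k in seq_along(ef)) {
    ri <- find(ef[k]); rj <- find(et[k])
    if (ri != rj) parent[ri] <- rj
  }
  root <- vapply(seq_along(vids), find, integer(1))
  # vids is C-locale sorted, so the minimum index per class is the min id
  minid <- tapply(seq_along(vids), root, min)
  stats::setNames(vids[minid[as.character(root)]], vids)
}

#' Oracle: Kleinberg dispersion by brute-force pair loop
#'
#' Reference implementation for [dispersion()]: for every unordered pair of
#' common neighbors of `u` and `v`, decide by depth-first reachability
#' (restricted to `u`'s neighbors minus `u`, `v`) whether the pair is
#' separated, and count the separated pairs.
#'
#' @param g a `min_graph`.
#' @param u,v distinct interactor ids present in `g`.
#' @return non-negative integer `K(u, v)`.
#' @export
oracle_dispersion <- function(g, u, v) {
  stopifnot(inherits(g, "min_graph"))
  check_known(g, c(u, v))
  if (u == v) abort_param("u and v must be distinct")
  adj <- oracle_adjacency(g)
  nb <- function(z) if (is.null(adj[[z]])) character() else adj[[z]]$id
  cn <- setdiff(intersect(nb(u), nb(v)), c(u, v))
  if (length(cn) < 2L) return(0L)

  keep <- setdiff(nb(u), c(u, v))
  reach <- function(s, t) {
    seen <- s
    stack <- list(s)
    while (length(stack)) {
      z <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (z == t) return(TRUE)
      for (w in intersect(nb(z), keep)) {
        if (!(w %in% seen)) {
          seen <- c(seen, w)
          stack <- c(stack, w)
        }
      }
    }
    FALSE
  }

  cn <- csort(cn)
  val <- 0L
  for (a in seq_len(length(cn) - 1L)) {
    for (b in (a + 1L):length(cn)) {
      if (!reach(cn[a], cn[b])) val <- val + 1L
    }
  }
  val
}
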