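# k-hop and weighted max-product-threshold neighborhoods, as superstep
# programs, plus their vertex-induced subgraphs.

new_neighborhood <- function(source_set, threshold, members, best_value,
                             weighted) {
  structure(
    list(source_set = source_set, threshold = threshold,
         members = members, best_value = best_value, weighted = weighted),
    class = "min_neighborhood"
  )
}

#' @export
print.min_neighborhood <- function(x, ...) {
  cat(sprintf("<min_neighborhood> %s of {%s} at x = %s: %d member(s)\n",
              if (x$weighted) "x-weighted-neighborhood" else "k-hop neighborhood",
              paste(x$source_set, collapse = ","),
              fmt6(x$threshold), length(x$members)))
  invisible(x)
}

#' k-hop neighbors of a set of interactors
#'
#' All interactors within `x` hops of the nearest member of `S`, excluding
#' `S` itself. Edge labels, if any, are ignored: this is the unlabelled
#' neighborhood, computed by the engine's cutoff BFS program.
#'
#' @param g a `min_graph`.
#' @param S character vector of source interactor ids, all present in `g`.
#' @param x positive integer hop limit.
#' @param executor,workers passed to [run_supersteps()].
#' @return a `min_neighborhood`: `members` (sorted ids) and `best_value`
#'   (named hop distances, each `<= x`).
#' @export
x_neighbors <- function(g, S, x, executor = c("serial", "parallel"),
                        workers = 1L) {
  stopifnot(inherits(g, "min_graph"))
  S <- unique(as.character(S))
  if (!length(S)) abort_param("S must contain at least one interactor id")
  check_known(g, S)
  x <- check_hops(x)

  res <- run_supersteps(g, prog_bfs(S, cutoff = x), executor = executor,
                        workers = workers)
  d <- unlist(res$states)
  members <- csort(setdiff(names(d)[is.finite(d) & d > 0], S))
  new_neighborhood(S, x, members, d[members], weighted = FALSE)
}

check_hops <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != floor(x)) {
    abort_param("x must be an integer >= 1 for unweighted neighborhoods")
  }
  as.integer(x)
}

#' k-hop neighborhood subgraph
#'
#' The vertex-induced subgraph of `g` on `S` together with its
#' [x_neighbors()] — all edges of `g` among the included vertices, not just
#' traversal trees.
#'
#' @inheritParams x_neighbors
#' @return a `min_graph`.
#' @export
x_subgraph <- function(g, S, x, executor = c("serial", "parallel"),
                       workers = 1L) {
  nb <- x_neighbors(g, S, x, executor = executor, workers = workers)
  induced_subgraph(g, c(nb$source_set, nb$members))
}

#' Weighted neighbors above a path-product threshold
#'
#' All interactors `v != i` for which some path from `i` to `v` has a product
#' of edge confidence labels strictly greater than `x`; `best_value` records
#' the maximum such product. Requires a labelled network. Computed by the
#' engine's max-product propagation program: because labels lie in \[0, 1\],
#' products never increase along a path, so the maximum over simple paths
#' equals the maximum over all walks and the propagation converges.
#'
#' @param g a labelled `min_graph`.
#' @param i the query interactor id.
#' @param x threshold in (0, 1); membership requires product `> x` (strict).
#' @param executor,workers passed to [run_supersteps()].
#' @return a `min_neighborhood`: `members` (sorted ids) and `best_value`
#'   (named best path products, each `> x`).
#' @export
x_weighted_neighbors <- function(g, i, x,
                                 executor = c("serial", "parallel"),
                                 workers = 1L) {
  stopifnot(inherits(g, "min_graph"))
  if (!g$labelled) {
    abort_wrong_mode("x_weighted_neighbors requires a labelled network")
  }
  check_scalar_id(i, "i")
  check_known(g, i)
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort_param("x must lie strictly between 0 and 1")
  }

  res <- run_supersteps(g, prog_max_product(i, threshold = x),
                        executor = executor, workers = workers)
  best <- unlist(res$states)
  members <- csort(setdiff(names(best)[best > x], i))
  new_neighborhood(i, x, members, best[members], weighted = TRUE)
}

#' Weighted neighborhood subgraph
#'
#' The vertex-induced subgraph of `g` on `i` together with its
#' [x_weighted_neighbors()].
#'
#' @inheritParams x_weighted_neighbors
#' @return a `min_graph`.
#' @export
x_weighted_subgraph <- function(g, i, x,
                                executor = c("serial", "parallel"),
                                workers = 1L) {
  nb <- x_weighted_neighbors(g, i, x, executor = executor, workers = workers)
  induced_subgraph(g, c(i, nb$members))
}
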