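# Kleinberg dispersion: how poorly connected the common neighborhood of a
# pair of interactors is inside the first endpoint's neighborhood.

#' Common neighbors of two interactors
#'
#' The intersection of the neighbor sets of `u` and `v`, excluding `u` and
#' `v` themselves.
#'
#' @param g a `min_graph`.
#' @param u,v distinct interactor ids present in `g`.
#' @return character vector of common neighbor ids, sorted (C locale).
#' @export
common_neighbors <- function(g, u, v) {
  stopifnot(inherits(g, "min_graph"))
  check_scalar_id(u, "u")
  check_scalar_id(v, "v")
  if (u == v) abort_param("u and v must be distinct")
  check_known(g, c(u, v))
  setdiff(intersect(interactor_neighbors(g, u), interactor_neighbors(g, v)),
          c(u, v))
}

#' Kleinberg dispersion of an interactor pair
#'
#' `K(u, v)` counts the pairs of common neighbors of `u` and `v` that fall in
#' different connected components of the subgraph induced by `u`'s neighbors
#' with `u` and `v` removed. It is 0 exactly when all common neighbors lie in
#' one component of that induced graph (or when there are fewer than two
#' common neighbors), and it quantifies how "not well"-connected the common
#' neighborhood is within `u`'s neighborhood. Note the statistic is not
#' symmetric: the induced graph is built from `u`'s neighbors, so `K(u, v)`
#' and `K(v, u)` may differ.
#'
#' By default each unordered pair `{s, t}` is counted once (the separating
#' indicator is symmetric); `counting = "ordered"` counts both `(s, t)` and
#' `(t, s)`, doubling the value.
#'
#' @param g a `min_graph`.
#' @param u,v distinct interactor ids present in `g`.
#' @param counting `"unordered"` (default) or `"ordered"` pair summation.
#' @param executor,workers passed to the components computation.
#' @return an object of class `min_dispersion` with fields `u`, `v`,
#'   `common_neighbors`, `cardinality` (`|C_uv|`) and `value` (`K(u, v)`).
#' @export
dispersion <- function(g, u, v, counting = c("unordered", "ordered"),
                       executor = c("serial", "parallel"), workers = 1L) {
  counting <- match.arg(counting)
  cn <- common_neighbors(g, u, v)
  k <- length(cn)

  value <- 0L
  if (k >= 2L) {
    cu <- setdiff(interactor_neighbors(g, u), c(u, v))
    h <- induced_subgraph(g, cu)
    labels <- connected_components(h, executor = executor, workers = workers)
    lab_cn <- labels[cn]
    total <- choose(k, 2)
    same <- sum(choose(table(lab_cn), 2))
    value <- as.integer(total - same)
  }
  if (counting == "ordered") value <- 2L * value

  structure(
    list(u = u, v = v, common_neighbors = cn, cardinality = k,
         value = value, counting = counting),
    class = "min_dispersion"
  )
}

#' @export
print.min_dispersion <- function(x, ...) {
  cat(sprintf("<min_dispersion> K(%s, %s) = %d over %d common neighbor(s) [%s pairs]\n",
              x$u, x$v, x$value, x$cardinality, x$counting))
  invisible(x)
}
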