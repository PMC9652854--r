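# Whole-network and per-interactor summary statistics.

#' Number of interactors
#' @param g a `min_graph`.
#' @return non-negative integer `|V|`.
#' @export
count_interactors <- function(g) {
  stopifnot(inherits(g, "min_graph"))
  nrow(g$vertices)
}

#' Number of interactions
#' @param g a `min_graph`.
#' @return non-negative integer `|E|`.
#' @export
count_interactions <- function(g) {
  stopifnot(inherits(g, "min_graph"))
  nrow(g$edges)
}

#' Write interactor ids to a text sink
#'
#' One id per line, lexicographically sorted (C locale).
#'
#' @param g a `min_graph`.
#' @param sink writable file path or connection.
#' @return invisibly, the number of rows written (`|V|`).
#' @export
list_interactors <- function(g, sink) {
  stopifnot(inherits(g, "min_graph"))
  ids <- g$vertices$id
  tryCatch({
    con <- if (inherits(sink, "connection")) sink else file(sink, "wb")
    if (!inherits(sink, "connection")) on.exit(close(con))
    writeLines(ids, con, sep = "\n")
  }, error = function(e) abort_io("cannot write interactor list: %s",
                                  conditionMessage(e)))
  invisible(length(ids))
}

#' Write interactions to a text sink
#'
#' Delegates to [write_edge_list()].
#'
#' @param g a `min_graph`.
#' @param sink writable file path or connection.
#' @return invisibly, the number of rows written (`|E|`).
#' @export
list_interactions <- function(g, sink) {
  write_edge_list(g, sink)
}

#' Network density
#'
#' The density of a MIN is `2|E| / (|V| (|V| - 1))`: the fraction of
#' realisable interactions that are present. Defined for at least two
#' interactors; equals 1 exactly on complete graphs.
#'
#' @param x a `min_graph`.
#' @param ... ignored.
#' @return real in \[0, 1\].
#' @export
density.min_graph <- function(x, ...) {
  nv <- nrow(x$vertices)
  if (nv < 2L) {
    abort_undefined_statistic("density is undefined for fewer than 2 interactors")
  }
  2 * nrow(x$edges) / (nv * (nv - 1))
}

#' Degree table
#'
#' The degree of an interactor is the number of interactions incident to it.
#' Rows are ordered by degree descending, then id ascending (C locale) — the
#' deterministic ordering used by [top_k_by_degree()]. Isolated interactors
#' appear with degree 0.
#'
#' @param g a `min_graph`.
#' @return data frame with columns `id`, `degree`.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "min_graph"))
  vids <- g$vertices$id
  deg <- tabulate(match(c(g$edges$from, g$edges$to), vids),
                  nbins = length(vids))
  ord <- corder(-deg, vids)
  data.frame(id = vids[ord], degree = deg[ord], stringsAsFactors = FALSE)
}

#' Top-k interactors by degree
#'
#' First `k` rows of the [degrees()] table. Ties at the cut are resolved by
#' the table's deterministic ordering (higher degree first, then ascending
#' id), so interactors tied with the k-th row but sorting after it are left
#' out. If the network has fewer than `k` interactors, all are returned.
#'
#' @param g a `min_graph`.
#' @param k positive integer.
#' @return data frame with columns `id`, `degree` and at most `k` rows.
#' @export
top_k_by_degree <- function(g, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort_param("k must be a positive integer")
  utils::head(degrees(g), k)
}

#' Harmonic closeness centrality
#'
#' The closeness of interactor `p` is the harmonic sum over all other
#' interactors of the reciprocal unweighted shortest-path (hop) distance,
#' `sum over y != p of 1 / d(y, p)`; an unreachable `y` contributes 0, the
#' only convention that keeps the statistic finite on disconnected networks.
#' Computed by the engine's BFS program from `p`.
#'
#' @param g a `min_graph`.
#' @param p an interactor id present in `g`.
#' @param executor,workers passed to [run_supersteps()].
#' @return non-negative real, at most `|V| - 1` (attained iff `p` is
#'   adjacent to every other interactor).
#' @export
closeness <- function(g, p, executor = c("serial", "parallel"), workers = 1L) {
  stopifnot(inherits(g, "min_graph"))
  check_scalar_id(p, "p")
  check_known(g, p)
  res <- run_supersteps(g, prog_bfs(p), executor = executor,
                        workers = workers)
  d <- unlist(res$states, use.names = FALSE)
  sum(1 / d[is.finite(d) & d > 0])
}
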