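# Connected components by min-label propagation, and the set-vs-partition
# queries built on them.

#' Connected components
#'
#' Labels every interactor with the id of its connected component, defined as
#' the lexicographically (C locale) smallest member id — the standard
#' label-propagation convention. Computed by the engine's min-label program:
#' two interactors share a label iff some path joins them.
#'
#' @param g a `min_graph`.
#' @param executor,workers passed to [run_supersteps()].
#' @return named character vector mapping interactor id to component id.
#' @export
connected_components <- function(g, executor = c("serial", "parallel"),
                                 workers = 1L) {
  stopifnot(inherits(g, "min_graph"))
  res <- run_supersteps(g, prog_min_label(g), executor = executor,
                        workers = workers)
  vids <- g$vertices$id
  stats::setNames(vids[unlist(res$states, use.names = FALSE)], vids)
}

# General-partition form of the closest-component query: given named blocks
# (a partition of some vertex universe) pick the block with the largest
# intersection with S, ties broken by the C-locale smaller block name.
closest_block <- function(blocks, S) {
  sizes <- vapply(blocks, function(b) length(intersect(b, S)), integer(1))
  nm <- csort(names(blocks))
  sizes <- sizes[nm]
  blocks[[nm[which.max(sizes)]]]
}

#' Component closest to a set of interactors
#'
#' The member set of the connected component sharing the largest number of
#' interactors with `S` (ties broken by the smaller component id).
#'
#' @param g a `min_graph`.
#' @param S non-empty character vector of interactor ids, all present in `g`.
#' @param executor,workers passed to [run_supersteps()].
#' @return character vector of the winning component's member ids, sorted.
#' @export
closest_component <- function(g, S, executor = c("serial", "parallel"),
                              workers = 1L) {
  stopifnot(inherits(g, "min_graph"))
  S <- unique(as.character(S))
  if (!length(S)) abort_param("S must be non-empty")
  check_known(g, S)
  labels <- connected_components(g, executor = executor, workers = workers)
  blocks <- split(names(labels), labels)
  csort(closest_block(blocks, S))
}

#' Intersection sizes per component
#'
#' For each distinct connected component of `g`, the size of its intersection
#' with `S`, including zero-size intersections; one row per component,
#' ordered by component id. The sizes sum to `|S|`.
#'
#' @param g a `min_graph`.
#' @param S character vector of interactor ids, all present in `g` (may be
#'   empty).
#' @param executor,workers passed to [run_supersteps()].
#' @return data frame with columns `component`, `size`.
#' @export
intersection_by_component <- function(g, S = character(),
                                      executor = c("serial", "parallel"),
                                      workers = 1L) {
  stopifnot(inherits(g, "min_graph"))
  S <- unique(as.character(S))
  check_known(g, S)
  labels <- connected_components(g, executor = executor, workers = workers)
  comp <- csort(unique(labels))
  size <- vapply(comp, function(cid) sum(labels[S] == cid), integer(1),
                 USE.NAMES = FALSE)
  data.frame(component = comp, size = size, stringsAsFactors = FALSE)
}
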