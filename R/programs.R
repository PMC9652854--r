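# Bundled superstep programs. All three propagate a bounded monotone state
# (min or max of products/sums of input values), so they halt and their
# results are independent of executor, worker count and partition layout.

#' Minimum-label propagation program
#'
#' Each vertex starts with its own label (its rank in the C-locale-sorted
#' vertex list) and repeatedly adopts the minimum label heard from a
#' neighbor. At convergence every connected component carries the label of
#' its lexicographically smallest member. Used by [connected_components()].
#'
#' @param g the `min_graph` the program will run on.
#' @return a [superstep_program()] whose final state at each vertex is the
#'   integer rank of its component id; decode with `interactor_ids(g)[state]`.
#' @export
prog_min_label <- function(g) {
  vids <- g$vertices$id
  rank <- new.env(hash = TRUE, size = max(length(vids), 1L))
  for (i in seq_along(vids)) assign(vids[i], i, envir = rank)
  superstep_program(
    initial_state = function(id) get(id, envir = rank, inherits = FALSE),
    vprog = function(id, state, msg) {
      if (is.null(msg)) state else min(state, msg)
    },
    send_msg = function(src, src_state, dst, dst_state, weight) {
      if (src_state < dst_state) {
        stats::setNames(list(src_state), dst)
      } else {
        NULL
      }
    },
    merge_msg = function(a, b) min(a, b),
    sample_messages = list(1L, 2L, 5L, 9L)
  )
}

#' Multi-source breadth-first search program
#'
#' Propagates hop distances from a source set, optionally cut off at a
#' maximum depth. Edge labels are ignored: distances are unweighted hop
#' counts. Used by [closeness()] and [x_neighbors()].
#'
#' @param sources character vector of source interactor ids (distance 0).
#' @param cutoff maximum distance to propagate (`Inf` for full BFS).
#' @return a [superstep_program()] whose final state at each vertex is its
#'   hop distance to the nearest source (`Inf` if unreachable).
#' @export
prog_bfs <- function(sources, cutoff = Inf) {
  src <- new.env(hash = TRUE, size = max(length(sources), 1L))
  for (s in sources) assign(s, TRUE, envir = src)
  superstep_program(
    initial_state = function(id) {
      if (isTRUE(get0(id, envir = src, inherits = FALSE,
                      ifnotfound = FALSE))) 0 else Inf
    },
    vprog = function(id, state, msg) {
      if (is.null(msg)) state else min(state, msg)
    },
    send_msg = function(src_id, src_state, dst, dst_state, weight) {
      d <- src_state + 1
      if (d <= cutoff && d < dst_state) {
        stats::setNames(list(d), dst)
      } else {
        NULL
      }
    },
    merge_msg = function(a, b) min(a, b),
    sample_messages = list(1, 2, 3, 7)
  )
}

#' Maximum path-product propagation program
#'
#' Propagates, from a single source, the best (maximum) product of edge
#' labels over paths, emitting a message along an edge only when the product
#' exceeds both `threshold` and the target's current best. Because labels lie
#' in \[0, 1\], products never increase along a path, so the maximum over
#' simple paths equals the maximum over all walks and the propagation
#' converges. Used by [x_weighted_neighbors()].
#'
#' @param source the source interactor id (state 1.0).
#' @param threshold minimum product worth propagating (strict `>`).
#' @return a [superstep_program()] whose final state at each vertex is the
#'   best path product from the source (0 if none exceeds the threshold).
#' @export
prog_max_product <- function(source, threshold = 0) {
  superstep_program(
    initial_state = function(id) if (id == source) 1.0 else 0.0,
    vprog = function(id, state, msg) {
      if (is.null(msg)) state else max(state, msg)
    },
    send_msg = function(src, src_state, dst, dst_state, weight) {
      p <- src_state * weight
      if (p > threshold && p > dst_state) {
        stats::setNames(list(p), dst)
      } else {
        NULL
      }
    },
    merge_msg = function(a, b) max(a, b),
    sample_messages = list(0.1, 0.5, 0.25, 0.9)
  )
}
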