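# Vertex-centric bulk-synchronous execution.
#
# The engine realizes the classic Pregel/GraphX schema on an undirected
# min_graph: computation proceeds in supersteps; within a superstep every
# active vertex folds its incoming messages with merge_msg, updates its state
# with vprog, and send_msg is then evaluated on edge triplets to produce the
# messages of the next superstep. Messages produced in superstep t are visible
# only in superstep t+1 (no asynchronous delivery). Execution halts when a
# superstep produces no messages, or when max_iterations vprog rounds have run.

#' Define a superstep program
#'
#' Bundles the three user functions of the vertex-centric schema — the vertex
#' program, the message generator and the message combiner — together with
#' its halting parameters, for execution by [run_supersteps()].
#'
#' Contract: `merge_msg` must be commutative and associative (message arrival
#' order is unspecified), and `vprog`/`send_msg` must be pure — the engine
#' may evaluate them in any order and, under the parallel executor, in forked
#' processes. If `sample_messages` is supplied, commutativity and
#' associativity of `merge_msg` are checked on randomized pairs/triples at
#' registration time and a contract-violation error is raised on failure.
#'
#' @param initial_state function `(vertex id) -> state`.
#' @param vprog function `(vertex id, state, merged message) -> new state`.
#'   At superstep 0 it is called at every vertex with `initial_message`.
#' @param send_msg function
#'   `(src id, src state, dst id, dst state, edge weight) -> messages`, where
#'   the result is `NULL` (no message) or a named list mapping target ids to
#'   message values. With `direction = "both"` (the undirected default) each
#'   edge is offered as two triplets per superstep, once in each orientation.
#' @param merge_msg commutative, associative function
#'   `(message, message) -> message`.
#' @param initial_message message delivered to every vertex at superstep 0;
#'   may be `NULL` as a neutral sentinel the vprog recognises.
#' @param max_iterations maximum number of vprog rounds (superstep 0 counts
#'   as one); `Inf` for unbounded.
#' @param direction one of `"both"`, `"out"` (canonical orientation only),
#'   `"in"` (reverse orientation only).
#' @param sample_messages optional list of representative messages used to
#'   spot-check the `merge_msg` algebra at registration.
#' @return an object of class `superstep_program`.
#' @seealso [prog_min_label()], [prog_bfs()], [prog_max_product()] for the
#'   bundled programs.
#' @export
superstep_program <- function(initial_state, vprog, send_msg, merge_msg,
                              initial_message = NULL, max_iterations = Inf,
                              direction = c("both", "out", "in"),
                              sample_messages = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.function(initial_state), is.function(vprog),
            is.function(send_msg), is.function(merge_msg))
  if (!(is.infinite(max_iterations) || (max_iterations >= 1))) {
    abort_param("max_iterations must be >= 1 (or Inf)")
  }
  if (!is.null(sample_messages) && length(sample_messages) >= 2L) {
    check_merge_algebra(merge_msg, sample_messages)
  }
  structure(
    list(initial_state = initial_state, vprog = vprog, send_msg = send_msg,
         merge_msg = merge_msg, initial_message = initial_message,
         max_iterations = max_iterations, direction = direction),
    class = "superstep_program"
  )
}

check_merge_algebra <- function(merge_msg, samples) {
  with_local_seed(190231L, {
    for (rep in seq_len(32L)) {
      abc <- samples[sample.int(length(samples), 3L, replace = TRUE)]
      a <- abc[[1L]]; b <- abc[[2L]]; c <- abc[[3L]]
      if (!isTRUE(all.equal(merge_msg(a, b), merge_msg(b, a)))) {
        abort_contract("merge_msg is not commutative on sampled messages")
      }
      if (!isTRUE(all.equal(merge_msg(merge_msg(a, b), c),
                            merge_msg(a, merge_msg(b, c))))) {
        abort_contract("merge_msg is not associative on sampled messages")
      }
    }
  })
  invisible(TRUE)
}

#' Run a superstep program over a network
#'
#' Executes `program` on `g` until no messages are produced or the program's
#' iteration cap is reached. Two executors share one observable contract: the
#' serial executor processes all triplets in a single process; the parallel
#' executor groups triplets by edge partition and evaluates partitions on
#' `workers` forked processes, exchanging messages at superstep barriers.
#' Because `merge_msg` is commutative and associative and partial results are
#' combined in fixed partition order, both executors return identical states
#' for any `workers >= 1` and any partition count.
#'
#' At superstep 0 every vertex is active: `vprog` runs everywhere with the
#' program's initial message and `send_msg` is evaluated on every triplet (as
#' in GraphX's Pregel loop). In later supersteps `vprog` runs only at
#' vertices that received a message, and `send_msg` only on triplets incident
#' to a vertex whose state changed (change is detected by exact comparison).
#'
#' @param g a `min_graph`.
#' @param program a [superstep_program()].
#' @param executor `"serial"` or `"parallel"`.
#' @param workers positive integer; forked worker count for the parallel
#'   executor (ignored by the serial one).
#' @return a list with components `states` (named list, one final state per
#'   vertex) and `supersteps_executed`.
#' @export
run_supersteps <- function(g, program, executor = c("serial", "parallel"),
                           workers = 1L) {
  stopifnot(inherits(g, "min_graph"), inherits(program, "superstep_program"))
  executor <- match.arg(executor)
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) abort_param("workers must be >= 1")

  vids <- g$vertices$id
  n <- length(vids)
  vindex <- new.env(hash = TRUE, size = max(n, 1L))
  for (i in seq_len(n)) assign(vids[i], i, envir = vindex)

  e <- g$edges
  m <- nrow(e)
  efrom <- match(e$from, vids)
  eto <- match(e$to, vids)
  ewt <- e$weight
  # incident edge indices per vertex
  inc <- split(c(seq_len(m), seq_len(m)),
               factor(c(efrom, eto), levels = seq_len(n)))

  states <- vector("list", n)
  for (i in seq_len(n)) {
    states[[i]] <- program$vprog(vids[i],
                                 program$initial_state(vids[i]),
                                 program$initial_message)
  }
  supersteps <- 1L

  dir <- program$direction
  send <- program$send_msg
  merge <- program$merge_msg

  # Evaluate send_msg on the given edge indices; return list(idx, vals) of
  # per-target merged messages (targets as integer vertex indices).
  collect <- function(eidx) {
    msgs <- vector("list", n)
    got <- logical(n)
    deliver <- function(out) {
      if (is.null(out) || !length(out)) return()
      tg <- names(out)
      for (k in seq_along(out)) {
        ti <- get0(tg[k], envir = vindex, inherits = FALSE,
                   ifnotfound = NULL)
        if (is.null(ti)) abort_contract("send_msg addressed unknown vertex '%s'",
                                        tg[k])
        if (got[ti]) {
          msgs[[ti]] <<- merge(msgs[[ti]], out[[k]])
        } else {
          msgs[[ti]] <<- out[[k]]
          got[ti] <<- TRUE
        }
      }
    }
    for (ei in eidx) {
      u <- efrom[ei]; v <- eto[ei]; w <- ewt[ei]
      su <- states[[u]]; sv <- states[[v]]
      if (dir != "in") deliver(send(vids[u], su, vids[v], sv, w))
      if (dir != "out") deliver(send(vids[v], sv, vids[u], su, w))
    }
    idx <- which(got)
    list(idx = idx, vals = msgs[idx])
  }

  gather <- function(eidx) {
    if (executor == "serial" || workers == 1L || g$partitions == 1L ||
        length(eidx) < 2L) {
      return(collect(eidx))
    }
    part <- e$partition[eidx]
    chunks <- split(eidx, part)            # ordered by partition index
    parts <- parallel::mclapply(chunks, collect, mc.cores = workers,
                                mc.preschedule = TRUE)
    failed <- vapply(parts, inherits, logical(1), "try-error")
    if (any(failed)) abort_contract("parallel executor worker failed")
    # combine partial message maps in fixed partition order
    msgs <- vector("list", n)
    got <- logical(n)
    for (p in parts) {
      for (k in seq_along(p$idx)) {
        ti <- p$idx[k]
        if (got[ti]) {
          msgs[[ti]] <- merge(msgs[[ti]], p$vals[[k]])
        } else {
          msgs[[ti]] <- p$vals[[k]]
          got[ti] <- TRUE
        }
      }
    }
    idx <- which(got)
    list(idx = idx, vals = msgs[idx])
  }

  active_edges <- seq_len(m)
  repeat {
    if (supersteps >= program$max_iterations) break
    if (!length(active_edges)) break
    inbox <- gather(active_edges)
    if (!length(inbox$idx)) break
    changed <- integer(0)
    for (k in seq_along(inbox$idx)) {
      i <- inbox$idx[k]
      new <- program$vprog(vids[i], states[[i]], inbox$vals[[k]])
      if (!identical(new, states[[i]])) {
        states[[i]] <- new
        changed <- c(changed, i)
      }
    }
    supersteps <- supersteps + 1L
    active_edges <- if (length(changed)) {
      unique(unlist(inc[changed], use.names = FALSE))
    } else {
      integer(0)
    }
  }

  names(states) <- vids
  list(states = states, supersteps_executed = supersteps)
}
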