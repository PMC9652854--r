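#' Build a molecular interaction network
#'
#' Constructs a `min_graph`, the in-memory representation of a molecular
#' interaction network (MIN): an undirected simple graph whose vertices are
#' interactors (identified by free-text ids, canonically `"db:accession"`,
#' e.g. `"uniprotkb:P04637"`) and whose edges are interactions, optionally
#' carrying a confidence label in \[0, 1\].
#'
#' Raw edges are cleaned deterministically at build time:
#' * endpoints are stored canonically with `from <= to` in C-locale byte order
#'   (undirected semantics);
#' * parallel edges (duplicate unordered pairs) collapse to a single edge
#'   keeping the maximum weight — MITAB files repeat pairs once per evidence
#'   line, and the maximum keeps the strongest evidence;
#' * self-loops are dropped with a warning giving their count;
#' * the edge table is sorted lexicographically, and each edge is assigned to
#'   one of `partitions` partitions by a stable hash of its canonical endpoint
#'   pair, so partitioned execution is reproducible across runs.
#'
#' A graph is either fully labelled (every edge has a weight) or fully
#' unlabelled; mixing weighted and unweighted edges is an error, as is any
#' weight outside \[0, 1\].
#'
#' @param edges a data frame whose first two columns are endpoint ids and
#'   whose optional third column (or a column named `weight`) holds confidence
#'   labels in \[0, 1\]; may have zero rows if `vertices` is given.
#' @param vertices optional character vector (or data frame with an `id`
#'   column) of interactor ids; ids not mentioned by any edge are kept as
#'   isolated vertices.
#' @param partitions positive integer number of edge partitions.
#' @return an object of class `min_graph`.
#' @examples
#' g <- build_graph(data.frame(from = c("a", "b", "a", "c"),
#'                             to   = c("b", "c", "c", "d"),
#'                             weight = c(0.9, 0.8, 0.5, 0.6)))
#' g
#' @export
build_graph <- function(edges = NULL, vertices = NULL, partitions = 1L) {
  partitions <- as.integer(partitions)
  if (is.na(partitions) || partitions < 1L) {
    abort_param("partitions must be a positive integer")
  }
  if ((is.null(edges) || nrow(edges) == 0L) && is.null(vertices)) {
    abort_invalid("need at least one edge or one vertex to build a graph")
  }

  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  weight <- if ("weight" %in% names(edges)) {
    as.numeric(edges[["weight"]])
  } else if (ncol(edges) >= 3L) {
    as.numeric(edges[[3L]])
  } else {
    rep(NA_real_, length(from))
  }

  extra <- NULL
  if (is.data.frame(vertices)) {
    if (!"id" %in% names(vertices)) {
      abort_invalid("vertex data frame must have an 'id' column")
    }
    extra <- vertices
    vertices <- as.character(vertices$id)
  }
  vertices <- as.character(vertices %||% character())

  check_ids(c(from, to, vertices))

  n_weighted <- sum(!is.na(weight))
  if (n_weighted > 0L && n_weighted < length(weight)) {
    abort_invalid(
      "mixed weighted and unweighted edges: %d of %d edges carry a weight",
      n_weighted, length(weight))
  }
  labelled <- n_weighted > 0L
  if (labelled && any(weight < 0 | weight > 1)) {
    abort_invalid("edge weights must lie in [0, 1]")
  }

  # canonical endpoint order under C-locale byte comparison
  code <- ccodes(c(from, to))
  m <- length(from)
  cf <- code[seq_len(m)]
  ct <- code[m + seq_len(m)]
  swap <- cf > ct
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp

  loops <- from == to
  if (any(loops)) {
    warning(sprintf("%d self-loop(s) removed", sum(loops)), call. = FALSE)
    from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
  }

  # collapse parallel edges, keeping the maximum weight
  key <- paste(from, to, sep = "\t")
  ord <- corder(key, -ifelse(is.na(weight), 0, weight))
  keep <- ord[!duplicated(key[ord])]
  keep <- keep[corder(from[keep], to[keep])]
  from <- from[keep]; to <- to[keep]; weight <- weight[keep]

  vids <- csort(unique(c(from, to, vertices)))
  vdf <- data.frame(id = vids, stringsAsFactors = FALSE)
  if (!is.null(extra) && ncol(extra) > 1L) {
    vdf <- merge(vdf, extra, by = "id", all.x = TRUE, sort = FALSE)
    vdf <- vdf[corder(vdf$id), , drop = FALSE]
    rownames(vdf) <- NULL
  }

  edf <- data.frame(
    from = from, to = to, weight = weight,
    partition = stable_hash(paste(from, to, sep = "\t"), partitions),
    stringsAsFactors = FALSE
  )

  structure(
    list(vertices = vdf, edges = edf, labelled = labelled,
         partitions = partitions),
    class = "min_graph"
  )
}

check_ids <- function(ids) {
  if (any(is.na(ids)) || any(!nzchar(ids))) {
    abort_invalid("interactor ids must be non-empty")
  }
  if (any(grepl("[\t\n]", ids))) {
    abort_invalid("interactor ids must not contain tab or newline characters")
  }
  invisible(ids)
}

#' @export
print.min_graph <- function(x, ...) {
  cat(sprintf(
    "<min_graph> %d interactors, %d interactions, %s, %d partition(s)\n",
    nrow(x$vertices), nrow(x$edges),
    if (x$labelled) "labelled" else "unlabelled", x$partitions))
  invisible(x)
}

#' Interactor ids of a network
#'
#' @param g a `min_graph`.
#' @return character vector of interactor ids, C-locale sorted.
#' @export
interactor_ids <- function(g) {
  stopifnot(inherits(g, "min_graph"))
  g$vertices$id
}

#' Adjacent interactors
#'
#' Returns the neighbors of an interactor: all vertices joined to it by an
#' interaction.
#'
#' @param g a `min_graph`.
#' @param id an interactor id present in `g`.
#' @return character vector of neighbor ids, C-locale sorted.
#' @export
interactor_neighbors <- function(g, id) {
  check_scalar_id(id, "id")
  check_known(g, id)
  csort(unique(c(g$edges$to[g$edges$from == id],
                 g$edges$from[g$edges$to == id])))
}

check_known <- function(g, ids) {
  missing <- setdiff(ids, g$vertices$id)
  if (length(missing)) abort_unknown_interactor(missing)
  invisible(ids)
}

#' Vertex-induced subgraph
#'
#' Extracts the subgraph of `g` on `node_set`: exactly those vertices, and
#' exactly the interactions of `g` with both endpoints in the set, weights
#' preserved. The operation is idempotent and keeps the partition layout of
#' the surviving edges.
#'
#' @param g a `min_graph`.
#' @param node_set character vector of interactor ids, all present in `g`.
#' @return a `min_graph`.
#' @export
induced_subgraph <- function(g, node_set) {
  stopifnot(inherits(g, "min_graph"))
  node_set <- unique(as.character(node_set))
  check_known(g, node_set)

  e <- g$edges
  keep <- e$from %in% node_set & e$to %in% node_set
  edf <- e[keep, , drop = FALSE]
  rownames(edf) <- NULL
  vids <- csort(node_set)
  vdf <- g$vertices[g$vertices$id %in% vids, , drop = FALSE]
  rownames(vdf) <- NULL

  structure(
    list(vertices = vdf, edges = edf,
         labelled = g$labelled, partitions = g$partitions),
    class = "min_graph"
  )
}

# Internal structural check used by the test suite.
validate_min_graph <- function(g) {
  stopifnot(
    inherits(g, "min_graph"),
    all(c(g$edges$from, g$edges$to) %in% g$vertices$id),
    !any(g$edges$from == g$edges$to),
    !anyDuplicated(paste(g$edges$from, g$edges$to, sep = "\t")),
    all(ccodes(g$edges$from, c(g$edges$from, g$edges$to)) <=
          ccodes(g$edges$to, c(g$edges$from, g$edges$to))),
    g$labelled == all(!is.na(g$edges$weight)) || nrow(g$edges) == 0L,
    all(g$edges$partition >= 0L & g$edges$partition < g$partitions)
  )
  if (g$labelled && nrow(g$edges)) {
    stopifnot(all(g$edges$weight >= 0 & g$edges$weight <= 1))
  }
  invisible(TRUE)
}
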