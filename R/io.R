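#' MITAB parsing dialect
#'
#' Describes how to pull endpoint ids and a confidence score out of a PSI-MI
#' TAB (MITAB 2.5+) file. Columns are 1-based. The confidence column holds
#' `|`-separated `key:value` items; `score_keys` are tried in order and the
#' first match supplies the edge weight (IntAct emits `intact-miscore:<v>`
#' among other scores, so first-match over a configured key list is
#' deterministic).
#'
#' @param id_column_a,id_column_b 1-based indices of the two interactor id
#'   columns (defaults 1 and 2).
#' @param confidence_column 1-based index of the confidence column
#'   (default 15, the MITAB 2.5 `Confidence value(s)` column).
#' @param score_keys ordered character vector of confidence key names to try.
#' @param header_detection skip the first line iff it starts with `"#"` or
#'   `"ID("`.
#' @return an object of class `mitab_dialect`.
#' @export
mitab_dialect <- function(id_column_a = 1L, id_column_b = 2L,
                          confidence_column = 15L,
                          score_keys = c("intact-miscore", "score"),
                          header_detection = TRUE) {
  cols <- c(id_column_a, id_column_b, confidence_column)
  if (any(cols < 1L) || anyDuplicated(cols)) {
    abort_param("MITAB column indices must be distinct and >= 1")
  }
  if (!length(score_keys)) abort_param("score_keys must be non-empty")
  structure(
    list(id_column_a = as.integer(id_column_a),
         id_column_b = as.integer(id_column_b),
         confidence_column = as.integer(confidence_column),
         score_keys = as.character(score_keys),
         header_detection = isTRUE(header_detection)),
    class = "mitab_dialect"
  )
}

read_text_lines <- function(path) {
  lines <- tryCatch(suppressWarnings(readLines(path, warn = FALSE)),
                    error = function(e) abort_io("cannot read '%s': %s",
                                                 path, conditionMessage(e)))
  sub("[ \t\r]+$", "", lines)
}

#' Read interactions from a MITAB file
#'
#' Parses a PSI-MI TAB 2.5/2.7 file into an interaction table plus the set of
#' interactor ids seen. Endpoint ids are the first `|`-separated token of the
#' two id columns (MITAB puts the primary identifier first). The weight is
#' the value of the first configured score key found in the confidence
#' column; rows where no key matches are unweighted. A parsed file must be
#' homogeneously weighted or unweighted: in an otherwise scored file, rows
#' lacking a score are dropped with a message giving their count.
#'
#' @param path path to a MITAB text file.
#' @param dialect a [mitab_dialect()].
#' @return a list with components `edges` (data frame `from`, `to`, `weight`;
#'   `weight` all `NA` for unweighted files) and `interactors` (character
#'   vector of ids in order of first appearance). Feed `edges` to
#'   [build_graph()], which applies the duplicate-collapse and self-loop
#'   rules.
#' @export
read_mitab <- function(path, dialect = mitab_dialect()) {
  lines <- read_text_lines(path)
  offset <- 0L
  if (length(lines) && dialect$header_detection &&
      (startsWith(lines[1L], "#") || startsWith(lines[1L], "ID("))) {
    lines <- lines[-1L]
    offset <- 1L
  }
  keep <- nzchar(lines)
  lineno <- which(keep) + offset
  lines <- lines[keep]
  if (!length(lines)) {
    return(list(edges = data.frame(from = character(), to = character(),
                                   weight = numeric()),
                interactors = character()))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(dialect$id_column_a, dialect$id_column_b,
              dialect$confidence_column)
  short <- lengths(fields) < need
  if (any(short)) {
    abort_invalid("MITAB parse error: line(s) %s have fewer than %d fields",
                  paste(lineno[short], collapse = ", "), need)
  }

  first_token <- function(x) sub("\\|.*$", "", x)
  from <- first_token(vapply(fields, `[[`, "", dialect$id_column_a))
  to <- first_token(vapply(fields, `[[`, "", dialect$id_column_b))
  conf <- vapply(fields, `[[`, "", dialect$confidence_column)

  weight <- vapply(conf, function(f) {
    if (f == "-" || !nzchar(f)) return(NA_real_)
    items <- strsplit(f, "|", fixed = TRUE)[[1L]]
    ikey <- sub(":.*$", "", items)
    ival <- sub("^[^:]*:", "", items)
    for (k in dialect$score_keys) {
      hit <- which(ikey == k)
      if (length(hit)) {
        v <- suppressWarnings(as.numeric(ival[hit[1L]]))
        if (!is.na(v)) return(v)
      }
    }
    NA_real_
  }, numeric(1), USE.NAMES = FALSE)

  scored <- !is.na(weight)
  if (any(scored) && !all(scored)) {
    message(sprintf("%d row(s) without a confidence score dropped", sum(!scored)))
    from <- from[scored]; to <- to[scored]; weight <- weight[scored]
  }

  list(edges = data.frame(from = from, to = to, weight = weight,
                          stringsAsFactors = FALSE),
       interactors = unique(c(rbind(from, to))))
}

#' Read interactions from a plain edge-list file
#'
#' Reads a 2+ column delimited text file (as produced by STRING-style dumps
#' or by [write_edge_list()]) into an interaction table. When
#' `weight_column` is given, the weight is the raw value divided by
#' `weight_scale` (`weight_scale = 1000` maps STRING 0-1000 combined scores
#' onto \[0, 1\]); a header line is skipped iff its weight field is
#' non-numeric. Scaled weights outside \[0, 1\] are an error naming the line.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator; `NULL` (default) splits on any run of
#'   spaces or tabs.
#' @param weight_column optional 1-based index of the weight column.
#' @param weight_scale positive divisor applied to raw weights.
#' @return data frame `from`, `to`, `weight` (all-`NA` weight when
#'   `weight_column` is `NULL`).
#' @export
read_edge_list <- function(path, delimiter = NULL, weight_column = NULL,
                           weight_scale = 1) {
  if (weight_scale <= 0) abort_param("weight_scale must be positive")
  lines <- read_text_lines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(from = character(), to = character(),
                      weight = numeric()))
  }

  fields <- if (is.null(delimiter)) {
    strsplit(lines, "[ \t]+")
  } else {
    strsplit(lines, delimiter, fixed = TRUE)
  }

  if (!is.null(weight_column)) {
    wc <- as.integer(weight_column)
    if (wc < 1L) abort_param("weight_column must be >= 1")
    # header iff first row's weight field is non-numeric
    if (lengths(fields)[1L] >= wc &&
        is.na(suppressWarnings(as.numeric(fields[[1L]][wc])))) {
      fields <- fields[-1L]
      lineno <- lineno[-1L]
    }
    if (!length(fields)) {
      return(data.frame(from = character(), to = character(),
                        weight = numeric()))
    }
  }

  short <- lengths(fields) < max(2L, if (is.null(weight_column)) 0L
                                 else as.integer(weight_column))
  if (any(short)) {
    abort_invalid("edge-list parse error: line(s) %s have too few fields",
                  paste(lineno[short], collapse = ", "))
  }

  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  weight <- rep(NA_real_, length(from))
  if (!is.null(weight_column)) {
    raw <- suppressWarnings(as.numeric(vapply(fields, `[[`, "",
                                              as.integer(weight_column))))
    if (any(is.na(raw))) {
      abort_invalid("non-numeric weight on line(s) %s",
                    paste(lineno[is.na(raw)], collapse = ", "))
    }
    weight <- raw / weight_scale
    bad <- weight < 0 | weight > 1
    if (any(bad)) {
      abort_invalid("weight outside [0, 1] after scaling on line(s) %s",
                    paste(lineno[bad], collapse = ", "))
    }
  }

  data.frame(from = from, to = to, weight = weight, stringsAsFactors = FALSE)
}

#' Write a network as a tab-separated edge list
#'
#' Writes one row per interaction, `id_a<TAB>id_b[<TAB>weight]`, endpoints in
#' canonical order and rows sorted lexicographically (C locale), weights
#' rendered with 6 significant digits. The output is byte-reproducible across
#' partition counts and runs, and `read_edge_list()` on the result rebuilds
#' an equal graph.
#'
#' @param g a `min_graph`.
#' @param path writable file path or connection.
#' @return invisibly, the number of rows written.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "min_graph"))
  lines <- edge_list_lines(g)
  ok <- tryCatch({
    con <- if (inherits(path, "connection")) path else file(path, "wb")
    if (!inherits(path, "connection")) on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    TRUE
  }, error = function(e) abort_io("cannot write edge list: %s",
                                  conditionMessage(e)))
  invisible(length(lines))
}

edge_list_lines <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(character())
  if (g$labelled) {
    paste(e$from, e$to, fmt6(e$weight), sep = "\t")
  } else {
    paste(e$from, e$to, sep = "\t")
  }
}
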