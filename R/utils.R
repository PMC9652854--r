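# Internal helpers: condition classes, C-locale ordering, stable hashing,
# numeric formatting. Nothing here is exported.

min_condition <- function(class, msg, ...) {
  structure(
    class = c(class, "min_error", "error", "condition"),
    list(message = msg, ...)
  )
}

abort_invalid <- function(msg, ...) {
  stop(min_condition("min_invalid_input", sprintf(msg, ...)))
}

abort_param <- function(msg, ...) {
  stop(min_condition("min_invalid_parameter", sprintf(msg, ...)))
}

abort_unknown_interactor <- function(ids) {
  stop(min_condition(
    "min_unknown_interactor",
    sprintf("unknown interactor(s): %s", paste(ids, collapse = ", ")),
    ids = ids
  ))
}

abort_io <- function(msg, ...) {
  stop(min_condition("min_io_error", sprintf(msg, ...)))
}

abort_contract <- function(msg, ...) {
  stop(min_condition("min_contract_violation", sprintf(msg, ...)))
}

abort_wrong_mode <- function(msg, ...) {
  stop(min_condition("min_wrong_mode", sprintf(msg, ...)))
}

abort_undefined_statistic <- function(msg, ...) {
  stop(min_condition(c("min_undefined_statistic", "min_invalid_input"),
                     sprintf(msg, ...)))
}

# C-locale (byte order) sorting so every deterministic ordering in the package
# is identical across platforms and LC_COLLATE settings.
csort <- function(x) sort(x, method = "radix")

corder <- function(...) order(..., method = "radix")

# Integer codes of ids in C-locale order; equal ids get equal codes.
ccodes <- function(x, universe = x) {
  match(x, csort(unique(universe)))
}

# Stable non-cryptographic string hash (31-polynomial mod a Mersenne prime),
# used to assign edges to partitions reproducibly across runs and platforms.
stable_hash <- function(keys, buckets) {
  if (buckets == 1L) return(integer(length(keys)))
  vapply(keys, function(k) {
    h <- 0
    for (b in utf8ToInt(k)) h <- (h * 31 + b) %% 2147483647
    as.integer(h %% buckets)
  }, integer(1), USE.NAMES = FALSE)
}

# 6 significant digits, no trailing zeros ("0.9", not "0.900000").
fmt6 <- function(x) as.character(signif(x, 6))

# Evaluate an expression under a fixed RNG state, restoring the caller's state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

check_scalar_id <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort_param("%s must be a single non-empty interactor id", what)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
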