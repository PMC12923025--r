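# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert <- function(cond, fmt, ...) if (!isTRUE(cond)) stopf(fmt, ...)

# Canonical unordered edge matrix: two integer columns, i < j, sorted, unique.
canonical_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  e <- matrix(as.integer(edges), ncol = 2L)
  swap <- e[, 1L] > e[, 2L]
  e[swap, ] <- e[swap, c(2L, 1L)]
  assert(all(e[, 1L] != e[, 2L]), "self-edges are not allowed")
  e <- unique(e)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  colnames(e) <- c("i", "j")
  e
}

edge_key <- function(edges) paste(edges[, 1L], edges[, 2L], sep = "-")

# Apply f to every numeric leaf of a nested list (parallel over extra trees).
tree_map <- function(f, x, ...) {
  rest <- list(...)
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) {
      out[[i]] <- do.call(tree_map, c(list(f, x[[i]]), lapply(rest, `[[`, i)))
    }
    out
  } else {
    do.call(f, c(list(x), rest))
  }
}

tree_leaves <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_leaves), use.names = FALSE) else list(x)
}

# Seeded evaluation that restores the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
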