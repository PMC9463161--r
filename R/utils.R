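# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

#' Derive a reproducible sub-seed
#'
#' Maps a master seed plus a purpose label (and optional step counter) to a
#' 32-bit seed. Every stochastic stage of the pipeline draws its own sub-seed
#' this way, so independent stages (batch sampling, dropout masks, generator
#' noise) consume disjoint random streams and a run is reproducible from a
#' single integer.
#'
#' @param seed master integer seed.
#' @param purpose character label of the random stream.
#' @param step optional non-negative step counter.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, purpose, step = 0L) {
  abort_if(!is.numeric(seed) || length(seed) != 1L || !is.finite(seed),
           "`seed` must be a single finite number")
  h <- sum(utf8ToInt(as.character(purpose)) * seq_along(utf8ToInt(as.character(purpose))))
  # all arithmetic kept in doubles well below 2^53, reduced mod a prime < 2^31
  m <- 2147483629
  x <- (abs(seed) %% m)
  x <- (x * 69069 + h * 30011) %% m
  x <- (x * 69069 + step * 9973 + 101) %% m
  as.integer(x)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# ---- parameter trees --------------------------------------------------------
# Network parameters are nested named lists whose leaves are numeric arrays.
# These helpers apply elementwise operations across whole trees (used by the
# optimizer, the historical-averaging regularizer, and tests).

tree_map <- function(f, x, ...) {
  dots <- list(...)
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (k in seq_along(x)) {
      out[[k]] <- do.call(tree_map, c(list(f, x[[k]]), lapply(dots, `[[`, k)))
    }
    out
  } else {
    do.call(f, c(list(x), dots))
  }
}

tree_reduce_sum <- function(f, x, y = NULL) {
  if (is.list(x)) {
    tot <- 0
    for (k in seq_along(x)) {
      tot <- tot + tree_reduce_sum(f, x[[k]], if (!is.null(y)) y[[k]])
    }
    tot
  } else {
    if (is.null(y)) sum(f(x)) else sum(f(x, y))
  }
}

tree_zeros_like <- function(x) tree_map(function(a) a * 0, x)

# flatten a parameter tree to one numeric vector (stable leaf order)
tree_flatten <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_flatten), use.names = FALSE) else as.numeric(x)
}

tree_count <- function(x) length(tree_flatten(x))

# check two trees have congruent structure and leaf dimensions
tree_congruent <- function(x, y) {
  if (is.list(x) != is.list(y)) return(FALSE)
  if (is.list(x)) {
    if (length(x) != length(y)) return(FALSE)
    all(vapply(seq_along(x), function(k) tree_congruent(x[[k]], y[[k]]), logical(1)))
  } else {
    identical(dim(x) %||% length(x), dim(y) %||% length(y))
  }
}
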