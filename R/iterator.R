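#' Block iterators
#'
#' The whole package is built around a pull-based iterator protocol: a
#' `maf_iterator` is a list with a `nxt` closure returning the next
#' [maf_block()] or `NULL` when the stream is exhausted. Every filter takes
#' an iterator and returns one, so chains compose without ever holding more
#' than a handful of blocks in memory.
#'
#' @param nxt a zero-argument function returning a `maf_block` or `NULL`.
#' @param close optional zero-argument finaliser (flush/close sinks).
#' @return an object of class `maf_iterator`.
#' @export
block_iterator <- function(nxt, close = NULL) {
  structure(list(nxt = nxt, close = close), class = "maf_iterator")
}

#' Pull the next block from an iterator
#' @param iter a `maf_iterator`.
#' @return a `maf_block` or `NULL` at end of stream.
#' @export
iter_next <- function(iter) {
  stopifnot(inherits(iter, "maf_iterator"))
  iter$nxt()
}

#' Close an iterator, releasing any resources
#' @param iter a `maf_iterator`.
#' @return invisibly `NULL`.
#' @export
iter_close <- function(iter) {
  if (!is.null(iter$close)) iter$close()
  invisible(NULL)
}

#' Materialize (part of) a stream into a list of blocks
#' @param iter a `maf_iterator`.
#' @param n maximum number of blocks to pull (default all).
#' @return list of `maf_block`.
#' @export
iter_collect <- function(iter, n = Inf) {
  out <- list()
  k <- 0L
  while (k < n) {
    b <- iter_next(iter)
    if (is.null(b)) break
    k <- k + 1L
    out[[k]] <- b
  }
  out
}

#' Drain a stream, counting blocks without keeping them
#' @param iter a `maf_iterator`.
#' @return integer count of blocks seen.
#' @export
iter_drain <- function(iter) {
  k <- 0L
  while (!is.null(iter_next(iter))) k <- k + 1L
  iter_close(iter)
  k
}

#' Wrap a list of blocks as an iterator
#' @param blocks list of `maf_block`.
#' @return a `maf_iterator`.
#' @export
iter_from_list <- function(blocks) {
  force(blocks)
  i <- 0L
  block_iterator(function() {
    if (i >= length(blocks)) return(NULL)
    i <<- i + 1L
    blocks[[i]]
  })
}

#' Instrumented pass-through iterator
#'
#' Counts how many blocks have been pulled from `source`; used by the
#' laziness tests to verify that downstream consumption does not read ahead.
#'
#' @param source a `maf_iterator`.
#' @return a `maf_iterator` with an extra `count()` member.
#' @export
iter_counting <- function(source) {
  force(source)   # closures must capture the iterator, not a lazy promise
  n <- 0L
  it <- block_iterator(function() {
    b <- iter_next(source)
    if (!is.null(b)) n <<- n + 1L
    b
  }, close = function() iter_close(source))
  it$count <- function() n
  class(it) <- c("counting_iterator", class(it))
  it
}

# Internal: iterator applying f(block) -> list of 0+ blocks, with optional
# flush() -> list of blocks called once at end of stream. Backbone of most
# filters.
iter_flatmap <- function(source, f, flush = NULL) {
  force(source); force(f)
  pending <- list()
  done <- FALSE
  block_iterator(function() {
    repeat {
      if (length(pending) > 0L) {
        b <- pending[[1L]]
        pending <<- pending[-1L]
        return(b)
      }
      if (done) return(NULL)
      nb <- iter_next(source)
      if (is.null(nb)) {
        done <<- TRUE
        if (!is.null(flush)) pending <<- flush()
      } else {
        pending <<- f(nb)
      }
    }
  }, close = function() iter_close(source))
}
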