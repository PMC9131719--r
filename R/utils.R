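# Run code under a temporary RNG state; the caller's stream is untouched.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seeds: fan a master seed out over named indices.
# Kept inside [1, 2^31 - 2] so the result is always a valid integer seed.
derive_seed <- function(seed, stream, index = 0L) {
  m <- 2147483647
  x <- (as.double(seed) %% m) * 48271 %% m
  x <- (x + as.double(stream) * 69621 + as.double(index) * 16807) %% m
  as.integer(x %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
#' @importFrom dplyr tibble
NULL

#' Turn a model object into a tidy tibble
#'
#' Re-exported generic; `dichoptr` provides methods for its fitted objects.
#' @param x An object.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' Re-exported generic; `dichoptr` provides methods for its fitted objects.
#' @param x An object.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
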