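#' @useDynLib mitobench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rlnorm setNames
#' @importFrom utils head tail write.table read.table
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

collapse <- function(x) paste(x, collapse = "")
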