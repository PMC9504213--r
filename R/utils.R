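# Internal helpers: seed plumbing and small utilities.

#' Null-coalescing operator
#' @param a,b `a` unless it is `NULL`, in which case `b`.
#' @name null-coalesce
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named sub-seed from a master seed
#'
#' All randomness in a run flows from one master seed; independent components
#' (data split, stream schedule, weight init, buffer sampling, augmentation)
#' draw from named sub-streams so that perturbing one leaves the others fixed.
#'
#' @param seed integer master seed.
#' @param name character tag of the sub-stream.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable row-wise softmax.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}
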