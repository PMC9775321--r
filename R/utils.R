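#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package calls never perturb user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a named substream seed from a master seed; keeps results of one
# stage stable when another stage changes its RNG consumption. Offsets are
# fixed per stage name; result stays inside 32-bit integer range.
subSeed <- function(seed, stream) {
  offsets <- c(data = 11L, init = 23L, augment = 37L, split = 53L,
               volume = 71L, epoch = 97L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 1103L + off * 9973L) %% 2147483629)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Recursive map over parallel parameter trees (leaves are numeric arrays).
pmapLeaves <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1L]])) {
    out <- do.call(Map, c(list(function(...) pmapLeaves(f, ...)), args))
    out
  } else {
    do.call(f, args)
  }
}

zeroLike <- function(p) pmapLeaves(function(a) {
  if (is.null(dim(a))) numeric(length(a)) else array(0, dim = dim(a))
}, p)

addTrees <- function(a, b) pmapLeaves(`+`, a, b)

scaleTree <- function(a, s) pmapLeaves(function(x) x * s, a)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(TRUE)
}
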