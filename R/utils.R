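# Internal helpers shared across modules.

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards
# so library calls never perturb user-level reproducibility.
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

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce h x w or h x w x 3 numeric image to h x w x 3 in [0, 1].
as_rgb <- function(img) {
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3L)
  if (dim(img)[3] == 3L) img else img[, , 1:3, drop = FALSE]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)
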