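# Evaluate code under a fixed RNG seed without disturbing the caller's
# RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# 0-based (x,y,z) coords -> 1-based linear index into an array of the
# given shape (raster order, x fastest).
.coords_to_index <- function(coords, shape) {
  coords[, 1] + shape[1] * (coords[, 2] + shape[2] * coords[, 3]) + 1L
}
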