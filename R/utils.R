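# Internal helpers shared across modules.

# Shift a matrix by (dr, dc), padding with `fill`. Used by the morphology
# and BFS routines so that 4-/8-connectivity is explicit and CPU-cheap.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) < 1L || length(cs) < 1L) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Neighbour offsets for a connectivity choice.
neighbour_offsets <- function(connectivity = 8L) {
  if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else if (connectivity == 8L) {
    out <- list()
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0L || dc != 0L) out[[length(out) + 1L]] <- c(dr, dc)
    out
  } else stop("connectivity must be 4 or 8")
}

# One binary dilation step under the given connectivity.
dilate_once <- function(mask, connectivity = 8L) {
  out <- mask
  for (off in neighbour_offsets(connectivity))
    out <- out | shift_mat(mask, off[1], off[2], FALSE)
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pixel-centre coordinate grids (0-based, row/column convention).
pixel_grid <- function(shape) {
  list(row = matrix(0:(shape[1] - 1), shape[1], shape[2]),
       col = matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE))
}

# Run `expr` under a local RNG stream so generators are reproducible
# without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Round half away from zero (so a countable target like round(200 * 0.35)
# is exact and platform-independent, unlike banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Quantise intensities in [0, 1] to the 16-bit grid used on disk, so that
# write -> read round-trips are bit-exact.
quantise16 <- function(x) round(clamp(x, 0, 1) * 65535) / 65535

`%||%` <- function(a, b) if (is.null(a)) b else a
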