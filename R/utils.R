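# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-up rounding used for all fractional-boundary -> voxel-index decisions.
# Depth positions are on a 0-based scale (0 = vitreous-most voxel centre).
round_half_up <- function(x) floor(x + 0.5)

stopifnot_scalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("'%s' must be in [%s, %s]", name, min, max), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(x)
}

# broadcast a (bscan x ascan) matrix to a (bscan, depth, ascan) array
bcast_bx <- function(m, n_depth) {
  aperm(array(m, c(nrow(m), ncol(m), n_depth)), c(1L, 3L, 2L))
}

# (depth) vector of 0-based voxel centre positions replicated to (b, z, x)
depth_grid <- function(n_bscans, n_depth, n_ascans) {
  array(rep(rep(0:(n_depth - 1L), each = n_bscans), n_ascans),
        c(n_bscans, n_depth, n_ascans))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
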