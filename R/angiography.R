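# Flow computation from repeated B-scans.

# axial rigid shift of a (depth x ascan) B-scan; positive moves content deeper
shift_axial <- function(m, s) {
  if (s == 0L) return(m)
  z <- nrow(m)
  out <- matrix(0, z, ncol(m))
  if (s > 0L) out[(1L + s):z, ] <- m[1:(z - s), ]
  else out[1:(z + s), ] <- m[(1L - s):z, ]
  out
}

#' Axially align repeated B-scans
#'
#' Rigidly shifts each repeat B-scan along depth to maximize its Pearson
#' cross-correlation with the first repeat at the same lateral location,
#' compensating axial bulk motion between repeats.  The shift is integer-pixel
#' and bounded by \code{max_shift_px}; ties prefer the smaller magnitude, and
#' degenerate (constant) scans get zero shift.  Full lateral/rotational motion
#' correction is out of scope.
#'
#' @param volume an \code{\link{acquisition_volume}}.
#' @param max_shift_px maximum |shift| in pixels (>= 0); 0 returns the input
#'   unchanged.
#' @return An aligned \code{acquisition_volume} with the applied shifts in
#'   \code{attr(, "shifts")} (repeats x B-scans; negative = toward vitreous).
#' @export
align_repeats <- function(volume, max_shift_px = 5L) {
  stopifnot(inherits(volume, "acquisition_volume"))
  stopifnot_scalar(max_shift_px, "max_shift_px", min = 0, integer = TRUE)
  g <- volume$geometry
  shifts <- matrix(0L, g$n_repeats, g$n_bscans)
  if (max_shift_px == 0L) {
    attr(volume, "shifts") <- shifts
    return(volume)
  }
  a <- volume$intensities
  cand <- 0:max_shift_px
  cand <- as.integer(c(0, rbind(-cand[-1], cand[-1])))  # 0, -1, 1, -2, 2, ...
  z <- g$n_depth
  for (b in seq_len(g$n_bscans)) {
    ref <- a[1L, b, , ]
    for (r in 2:g$n_repeats) {
      m <- a[r, b, , ]
      best <- 0L; best_cor <- -Inf
      for (s in cand) {
        if (abs(s) >= z) next
        if (s >= 0L) { x <- ref[(1L + s):z, ]; y <- m[1:(z - s), ] }
        else { x <- ref[1:(z + s), ]; y <- m[(1L - s):z, ] }
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        cc <- stats::cor(as.vector(x), as.vector(y))
        if (cc > best_cor + 1e-12) { best_cor <- cc; best <- s }
      }
      if (best != 0L) a[r, b, , ] <- shift_axial(m, best)
      shifts[r, b] <- best
    }
  }
  out <- acquisition_volume(a, g)
  attr(out, "shifts") <- shifts
  out
}

#' Speckle-variance flow volume
#'
#' Motion contrast from repeated B-scans: for every voxel, the temporal
#' variance of structural intensity across the N repeats,
#' \deqn{flow[b,z,x] = \frac{1}{N}\sum_r (I[r,b,z,x] - \bar I[b,z,x])^2.}
#' The divide-by-N (population) convention is used: the repeats are the full
#' set of observations, and the choice only rescales flow globally.  Variance
#' is computed on linear intensity as stored; log-compressed data must be
#' linearized first.
#'
#' @param volume an \code{\link{acquisition_volume}} with >= 2 (aligned) repeats.
#' @return A \code{\link{flow_volume}}.
#' @export
speckle_variance <- function(volume) {
  stopifnot(inherits(volume, "acquisition_volume"))
  a <- volume$intensities
  n <- dim(a)[1]
  if (n < 2L) stop("speckle variance requires >= 2 repeats", call. = FALSE)
  m <- colMeans(a, dims = 1)
  v <- colMeans(a * a, dims = 1) - m * m
  v <- pmax(v, 0)  # guard tiny negative rounding at zero variance
  prov <- list(method = "speckle_variance", n_repeats = n,
               variance = "population (divide by N)",
               shifts = attr(volume, "shifts"))
  flow_volume(v, volume$geometry, prov)
}

#' Mask flow where structural signal is absent
#'
#' Speckle variance is noisy wherever there is no tissue signal (vitreous,
#' deep shadow).  Voxels whose mean-over-repeats structural intensity falls
#' strictly below the \code{floor} quantile of that intensity distribution are
#' zeroed.  \code{floor = 0} leaves the flow unchanged.
#'
#' @param flow a \code{\link{flow_volume}}.
#' @param structural the matching \code{\link{acquisition_volume}}.
#' @param floor quantile in [0, 1).
#' @return A masked \code{flow_volume}.
#' @export
mask_low_signal <- function(flow, structural, floor = 0.05) {
  stopifnot(inherits(flow, "flow_volume"),
            inherits(structural, "acquisition_volume"))
  if (floor < 0 || floor >= 1) stop("'floor' must be in [0, 1)", call. = FALSE)
  m <- colMeans(structural$intensities, dims = 1)
  if (!identical(dim(m), dim(flow$flow)))
    stop("flow and structural volumes have different shapes", call. = FALSE)
  thr <- stats::quantile(m, floor, names = FALSE)
  v <- flow$flow
  v[m < thr] <- 0
  prov <- flow$provenance
  prov$mask_floor <- floor
  flow_volume(v, flow$geometry, prov)
}
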