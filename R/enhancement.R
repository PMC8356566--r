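# Per-slab display enhancement chain:
#   min-max normalization -> low-intensity-preserving threshold -> row-wise
#   contrast-limited adaptive histogram equalization (CLAHE).
# Every stage maps [0,1] -> [0,1].

#' Enhancement parameters
#'
#' Defaults follow the display chain the slabs were designed for: threshold
#' 0.25 (capillary signal lives in the low intensities; everything at or
#' above the threshold is saturated), 8 tiles across each row for the
#' row-wise CLAHE.  The clip limit (fraction of tile pixels a histogram bin
#' may hold before its excess is redistributed) and bin count are package
#' defaults in the usual range for CLAHE implementations.
#'
#' @param threshold intensity in (0, 1]; 1 disables thresholding.
#' @param tiles_per_row contiguous tiles per row (>= 1).
#' @param clip_limit histogram clip fraction (> 0).
#' @param n_bins histogram bins.
#' @param threshold_mode \code{"rescale"} clips at the threshold and rescales
#'   to [0, 1] (preserves all sub-threshold structure, saturates bright
#'   vessels); \code{"zero_above"} instead zeroes values at or above it.
#' @return list of class \code{enhance_params}.
#' @export
enhance_params <- function(threshold = 0.25, tiles_per_row = 8L,
                           clip_limit = 0.01, n_bins = 256L,
                           threshold_mode = c("rescale", "zero_above")) {
  stopifnot_scalar(threshold, "threshold", min = 1e-12, max = 1)
  stopifnot_scalar(tiles_per_row, "tiles_per_row", min = 1, integer = TRUE)
  stopifnot_scalar(clip_limit, "clip_limit", min = 1e-12)
  stopifnot_scalar(n_bins, "n_bins", min = 2, integer = TRUE)
  structure(list(threshold = threshold, tiles_per_row = as.integer(tiles_per_row),
                 clip_limit = clip_limit, n_bins = as.integer(n_bins),
                 threshold_mode = match.arg(threshold_mode)),
            class = "enhance_params")
}

#' Min-max normalization to [0, 1]
#'
#' \code{(x - min) / (max - min)}; a constant image maps to all zeros (the
#' documented degenerate rule).
#'
#' @param img numeric matrix of finite values.
#' @return matrix in [0, 1].
#' @export
normalize_minmax <- function(img) {
  if (anyNA(img) || any(!is.finite(img)))
    stop("image contains non-finite values", call. = FALSE)
  rng <- range(img)
  if (diff(rng) <= 0) return(array(0, dim(img)))
  (img - rng[1]) / diff(rng)
}

#' Low-intensity-preserving threshold
#'
#' Preserves intensities below the threshold: in the default \code{"rescale"}
#' mode values at or above \code{threshold} are clipped to it and the image is
#' rescaled by \code{1/threshold} back to [0, 1], keeping all sub-threshold
#' (capillary) structure while saturating bright vessels.  The alternative
#' \code{"zero_above"} mode zeroes values at or above the threshold instead.
#' \code{threshold = 1} is the identity.
#'
#' @param img matrix in [0, 1].
#' @param threshold intensity in (0, 1].
#' @param mode \code{"rescale"} (default) or \code{"zero_above"}.
#' @return matrix in [0, 1].
#' @export
threshold_preserve <- function(img, threshold = 0.25,
                               mode = c("rescale", "zero_above")) {
  mode <- match.arg(mode)
  stopifnot_scalar(threshold, "threshold", min = 1e-12, max = 1)
  if (any(img < 0) || any(img > 1))
    stop("image values must lie in [0, 1]", call. = FALSE)
  if (mode == "rescale") {
    pmin(img, threshold) / threshold
  } else {
    out <- img
    out[out >= threshold] <- 0
    out
  }
}

# 1-D CLAHE of a single row.
# Tiles partition the row contiguously; per tile the histogram (n_bins over
# [0,1]) is clipped at clip_limit * tile_size (fractional counts allowed) and
# the excess redistributed uniformly over all bins; the tile mapping is the
# CDF re-anchored so the lowest bin maps to black,
#   m(bin) = (cdf(bin) - cdf(1)) / (1 - cdf(1)),
# the usual histogram-equalization min-normalization (an all-black tile stays
# black).  Each pixel's output linearly interpolates the mappings of the two
# nearest tile centres (nearest tile alone beyond the outer centres).
clahe_row <- function(v, tiles, clip_limit, n_bins) {
  n <- length(v)
  tiles <- min(tiles, n)
  bin <- pmin(floor(v * n_bins), n_bins - 1L) + 1L
  tile_id <- ceiling(seq_len(n) * tiles / n)
  centers <- numeric(tiles)
  M <- matrix(0, n_bins, tiles)  # per-tile mapping bin -> [0,1]
  for (t in seq_len(tiles)) {
    idx <- which(tile_id == t)
    centers[t] <- mean(idx)
    counts <- tabulate(bin[idx], nbins = n_bins)
    limit <- clip_limit * length(idx)
    clipped <- pmin(counts, limit)
    clipped <- clipped + (sum(counts) - sum(clipped)) / n_bins
    cdf <- cumsum(clipped) / length(idx)
    M[, t] <- if (cdf[1L] < 1) (cdf - cdf[1L]) / (1 - cdf[1L]) else 0
  }
  if (tiles == 1L) return(clamp01(M[bin, 1L]))
  pos <- seq_len(n)
  t_right <- findInterval(pos, centers) + 1L   # first centre at or right of pos
  t_left <- t_right - 1L
  out <- numeric(n)
  inner <- t_left >= 1L & t_right <= tiles
  if (any(inner)) {
    tl <- t_left[inner]; tr <- t_right[inner]
    w <- (pos[inner] - centers[tl]) / (centers[tr] - centers[tl])
    bi <- bin[inner]
    out[inner] <- (1 - w) * M[cbind(bi, tl)] + w * M[cbind(bi, tr)]
  }
  lo <- t_left < 1L
  if (any(lo)) out[lo] <- M[cbind(bin[lo], 1L)]
  hi <- t_right > tiles
  if (any(hi)) out[hi] <- M[cbind(bin[hi], tiles)]
  clamp01(out)
}

#' Row-wise contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE independently to each image row as a 1-D signal partitioned
#' into \code{tiles_per_row} contiguous tiles (default 8): per-tile clipped
#' histogram equalization with uniform redistribution of the clipped excess,
#' and per-pixel linear interpolation between adjacent tile mappings.  The
#' output of row r depends only on row r.  Rows shorter than the tile count
#' are processed with one tile per pixel position available (with a warning).
#'
#' @param img matrix in [0, 1]; rows are the fast (A-scan) axis — transpose
#'   first if the acquisition is stored rotated.
#' @param params an \code{\link{enhance_params}}.
#' @return matrix in [0, 1].
#' @export
clahe_rows <- function(img, params = enhance_params()) {
  stopifnot(inherits(params, "enhance_params"))
  if (any(img < 0) || any(img > 1))
    stop("image values must lie in [0, 1]", call. = FALSE)
  tiles <- params$tiles_per_row
  if (ncol(img) < tiles) {
    warning(sprintf("rows have %d px < %d tiles; using %d tile(s)",
                    ncol(img), tiles, ncol(img)), call. = FALSE)
    tiles <- ncol(img)
  }
  out <- img
  for (r in seq_len(nrow(img)))
    out[r, ] <- clahe_row(img[r, ], tiles, params$clip_limit, params$n_bins)
  out
}

#' Full slab enhancement chain
#'
#' \code{\link{normalize_minmax}}, then \code{\link{threshold_preserve}}, then
#' \code{\link{clahe_rows}}, in that order.
#'
#' @param img raw projected en face slab (nonnegative matrix).
#' @param params an \code{\link{enhance_params}}.
#' @return enhanced matrix in [0, 1], with the parameters recorded in
#'   \code{attr(, "enhance")}.
#' @export
enhance_slab <- function(img, params = enhance_params()) {
  stopifnot(inherits(params, "enhance_params"))
  at <- attributes(img)
  out <- normalize_minmax(img)
  out <- threshold_preserve(out, params$threshold, params$threshold_mode)
  out <- clahe_rows(out, params)
  for (nm in setdiff(names(at), c("dim", "dimnames")))
    attr(out, nm) <- at[[nm]]
  attr(out, "enhance") <- unclass(params)
  out
}
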