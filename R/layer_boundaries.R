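# Baseline retinal boundary segmentation and manual-correction handling.
#
# The segmenter is a deliberately simple baseline: per B-scan, each junction
# is a minimum-cost path across A-scans on an axial-gradient cost image,
# searched inside an anatomically ordered band (ILM at the dark-to-bright
# vitreous/retina transition, IPL/INL and OPL/ONL at bright-to-dark
# transitions below the previous junction).  The pipeline contract is
# "boundaries in, slabs out": externally segmented and manually corrected
# boundaries imported via load_boundaries() are first-class citizens.

BIG_COST <- 1e9

# separable box-Gaussian blur with replicated edges
blur2d <- function(m, sigma_z, sigma_x) {
  k1 <- function(sigma) {
    if (sigma <= 0) return(1)
    h <- max(1L, ceiling(2.5 * sigma))
    k <- stats::dnorm(-h:h, sd = sigma)
    k / sum(k)
  }
  conv_rows <- function(m, k) {
    h <- (length(k) - 1L) %/% 2L
    if (h == 0L) return(m)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      off <- i - h - 1L
      idx <- pmin(pmax(seq_len(nrow(m)) + off, 1L), nrow(m))
      out <- out + k[i] * m[idx, , drop = FALSE]
    }
    out
  }
  m <- conv_rows(m, k1(sigma_z))
  t(conv_rows(t(m), k1(sigma_x)))
}

# per-column mean intensity over a depth window [z + lo, z + hi] (replicated
# edges), via cumulative sums
window_mean <- function(m, lo, hi) {
  nz <- nrow(m)
  cs <- apply(m, 2, cumsum)
  idx_hi <- pmin(pmax(seq_len(nz) + hi, 1L), nz)
  idx_lo <- pmin(pmax(seq_len(nz) + lo - 1L, 0L), nz)
  top <- cs[idx_hi, , drop = FALSE]
  bot <- rbind(0, cs)[idx_lo + 1L, , drop = FALSE]
  (top - bot) / pmax(idx_hi - idx_lo, 1L)
}

# edge score for a junction: local signed gradient plus band contrast
# (mean intensity a few px above vs below), which keeps thin bright vessels
# from masquerading as a layer junction — tissue below a vessel stays bright,
# below a true bright->dark junction it does not.  far_weight adds a bonus for
# brightness 6-16 px below the edge: the IPL/INL junction is followed by the
# dark INL and then the *bright* OPL band, whereas below the OPL/ONL junction
# the ONL stays dark — this is what separates the two bright->dark junctions
# when intermediate-plexus vessels blur the IPL/INL contrast.
edge_score <- function(sm, grad, direction, far_weight = 0) {
  above <- window_mean(sm, -3L, -1L)
  below <- window_mean(sm, 1L, 4L)
  s <- if (direction == "dark_to_bright") grad + 0.5 * (below - above)
       else -grad + 0.5 * (above - below)
  if (far_weight > 0) s <- s + far_weight * window_mean(sm, 6L, 16L)
  s
}

# min-cost path across columns of a (depth x ascan) cost image with
# |z(x+1) - z(x)| <= max_jump; ties prefer smaller jumps
dp_path <- function(cost, max_jump) {
  nz <- nrow(cost); nx <- ncol(cost)
  D <- cost[, 1L]
  P <- matrix(0L, nz, nx)
  jumps <- 0:max_jump
  jumps <- as.integer(c(0, rbind(-jumps[-1], jumps[-1])))
  for (x in 2:nx) {
    best <- rep(Inf, nz); arg <- integer(nz)
    for (dz in jumps) {
      src <- seq_len(nz) + dz
      ok <- src >= 1L & src <= nz
      cand <- rep(Inf, nz)
      cand[ok] <- D[src[ok]]
      upd <- cand < best - 1e-12
      best[upd] <- cand[upd]
      arg[upd] <- dz
    }
    D <- cost[, x] + best
    P[, x] <- seq_len(nz) + arg
  }
  z <- integer(nx)
  z[nx] <- which.min(D)
  for (x in nx:2) z[x - 1L] <- P[z[x], x]
  z
}

# parabolic sub-pixel refinement of a path on its cost image
refine_subpixel <- function(cost, z) {
  out <- as.numeric(z)
  nz <- nrow(cost)
  for (x in seq_along(z)) {
    k <- z[x]
    if (k <= 1L || k >= nz) next
    c0 <- cost[k - 1L, x]; c1 <- cost[k, x]; c2 <- cost[k + 1L, x]
    if (max(c0, c1, c2) > BIG_COST / 2) next
    den <- c0 - 2 * c1 + c2
    if (den <= 1e-12) next
    out[x] <- k + max(-0.5, min(0.5, 0.5 * (c0 - c2) / den))
  }
  out
}

#' Parameters for the baseline boundary segmenter
#'
#' Search bands are expressed in pixels below the previously found junction
#' (or as depth fractions for the ILM) and assume the ~4.37 um/px axial
#' sampling the defaults were chosen for; rescale them for other samplings.
#'
#' @param sigma_z,sigma_x Gaussian pre-smoothing (depth, lateral) in px.
#' @param max_jump maximum per-column path step in px.
#' @param ilm_band depth-fraction band searched for the ILM.
#' @param ipl_gap_px min/max px of the IPL/INL junction below the ILM.
#' @param opl_gap_px min/max px of the OPL/ONL junction below the IPL/INL.
#' @param depth_penalty cost added per pixel of depth inside the search band,
#'   so that among transitions of comparable strength the shallowest wins —
#'   each junction is anatomically the *first* strong transition below its
#'   predecessor (the RPE and OPL/ONL otherwise compete with the ILM and
#'   IPL/INL respectively).
#' @return list of class \code{segmentation_params}.
#' @export
segmentation_params <- function(sigma_z = 1.5, sigma_x = 2,
                                max_jump = 2L,
                                ilm_band = c(0.02, 0.75),
                                ipl_gap_px = c(8, 48),
                                opl_gap_px = c(8, 34),
                                depth_penalty = 0.002) {
  structure(list(sigma_z = sigma_z, sigma_x = sigma_x,
                 max_jump = as.integer(max_jump),
                 ilm_band = ilm_band, ipl_gap_px = ipl_gap_px,
                 opl_gap_px = opl_gap_px, depth_penalty = depth_penalty),
            class = "segmentation_params")
}

#' Segment the three slab-reference junctions
#'
#' Estimates the vitreous/ILM, IPL/INL and OPL/ONL junction surfaces from the
#' mean-over-repeats structural volume.  Per B-scan, each junction is the
#' minimum-cost path across A-scans on an edge-score cost combining the signed
#' axial gradient (dark-to-bright for the ILM, bright-to-dark for the other
#' two) with the band contrast above vs below the candidate edge, restricted
#' to a band below the previously found junction so the non-crossing order
#' holds by construction.  Paths get parabolic sub-pixel refinement.  A
#' degenerate constant B-scan yields flat traces at the band centres with a
#' warning.
#'
#' @param structural an \code{\link{acquisition_volume}}.
#' @param params a \code{\link{segmentation_params}}.
#' @return A \code{\link{boundary_set}}.
#' @export
segment_boundaries <- function(structural, params = segmentation_params()) {
  stopifnot(inherits(structural, "acquisition_volume"))
  g <- structural$geometry
  nz <- g$n_depth; nx <- g$n_ascans
  mvol <- colMeans(structural$intensities, dims = 1)  # (b, z, x)
  ilm <- matrix(0, g$n_bscans, nx)
  ipl <- matrix(0, g$n_bscans, nx)
  opl <- matrix(0, g$n_bscans, nx)
  n_degenerate <- 0L
  zi <- seq_len(nz)
  for (b in seq_len(g$n_bscans)) {
    m <- mvol[b, , ]
    if (diff(range(m)) < 1e-12) {
      n_degenerate <- n_degenerate + 1L
      ilm[b, ] <- mean(params$ilm_band) * (nz - 1)
      ipl[b, ] <- ilm[b, ] + mean(params$ipl_gap_px)
      opl[b, ] <- ipl[b, ] + mean(params$opl_gap_px)
      next
    }
    sm <- blur2d(m, params$sigma_z, params$sigma_x)
    grad <- (sm[pmin(zi + 1L, nz), ] - sm[pmax(zi - 1L, 1L), ]) / 2
    # ILM: first strong dark->bright transition inside the absolute band
    lo <- max(1L, floor(params$ilm_band[1] * nz))
    hi <- min(nz, ceiling(params$ilm_band[2] * nz))
    cost <- -edge_score(sm, grad, "dark_to_bright") +
      params$depth_penalty * pmax(zi - lo, 0)
    cost[zi < lo | zi > hi, ] <- BIG_COST
    p_ilm <- dp_path(cost, params$max_jump)
    ilm[b, ] <- refine_subpixel(cost, p_ilm) - 1  # 0-based depth positions
    # IPL/INL: bright->dark transition below the ILM, disambiguated from the
    # OPL/ONL by the bright OPL band a few pixels further down (far bonus)
    score_ipl <- edge_score(sm, grad, "bright_to_dark", far_weight = 0.5)
    band_lo <- p_ilm + params$ipl_gap_px[1]
    band_hi <- p_ilm + params$ipl_gap_px[2]
    depth_in_band <- pmax(outer(zi, band_lo, "-"), 0)
    cost <- -score_ipl + params$depth_penalty * depth_in_band
    cost[outer(zi, band_lo, "<") | outer(zi, band_hi, ">")] <- BIG_COST
    p_ipl <- dp_path(cost, params$max_jump)
    ipl[b, ] <- refine_subpixel(cost, p_ipl) - 1
    # OPL/ONL: next bright->dark transition below the IPL/INL
    score_opl <- edge_score(sm, grad, "bright_to_dark")
    band_lo <- p_ipl + params$opl_gap_px[1]
    band_hi <- p_ipl + params$opl_gap_px[2]
    depth_in_band <- pmax(outer(zi, band_lo, "-"), 0)
    cost <- -score_opl + params$depth_penalty * depth_in_band
    cost[outer(zi, band_lo, "<") | outer(zi, band_hi, ">")] <- BIG_COST
    p_opl <- dp_path(cost, params$max_jump)
    opl[b, ] <- refine_subpixel(cost, p_opl) - 1
  }
  if (n_degenerate > 0L)
    warning(sprintf("%d degenerate (constant) B-scan(s): flat surfaces at band centres",
                    n_degenerate), call. = FALSE)
  clip <- function(s) pmin(pmax(s, 0), nz - 1 - 1e-9)
  boundary_set(list(ILM = clip(ilm), IPL_INL = clip(ipl), OPL_ONL = clip(opl)),
               g, enforce_order = TRUE)
}

#' A manual boundary correction
#'
#' A replacement depth trace for one junction over a rectangular
#' (bscan, ascan) patch, as produced by expert review of automatic
#' segmentations.
#'
#' @param junction one of \code{"ILM"}, \code{"IPL_INL"}, \code{"OPL_ONL"}.
#' @param bscans,ascans 1-based index vectors of the patch.
#' @param depth_px replacement positions: scalar, vector (recycled across
#'   B-scans), or \code{length(bscans) x length(ascans)} matrix.
#' @return list of class \code{boundary_correction}.
#' @export
boundary_correction <- function(junction, bscans, ascans, depth_px) {
  junction <- match.arg(junction, JUNCTIONS)
  patch <- matrix(depth_px, length(bscans), length(ascans),
                  byrow = is.vector(depth_px) && length(depth_px) == length(ascans))
  structure(list(junction = junction, bscans = as.integer(bscans),
                 ascans = as.integer(ascans), depth_px = patch),
            class = "boundary_correction")
}

#' Apply manual corrections to a boundary set
#'
#' Each correction's replacement trace is spliced into its junction surface
#' with a linear cross-fade over \code{margin} rows/columns at patch edges
#' that lie strictly inside the surface (so full-surface replacements are
#' exact).  Afterwards the corrected junction is clamped between its
#' anatomical neighbours; clamped positions are counted as order violations,
#' reported via \code{message()} and returned in \code{attr(, "violations")}.
#'
#' @param boundaries a \code{\link{boundary_set}}.
#' @param corrections list of \code{\link{boundary_correction}} objects (an
#'   empty list returns the input unchanged).
#' @param margin cross-fade width in px (0 = hard splice).
#' @return A corrected \code{boundary_set}.
#' @export
apply_corrections <- function(boundaries, corrections, margin = 2L) {
  stopifnot(inherits(boundaries, "boundary_set"))
  if (length(corrections) == 0L) return(boundaries)
  g <- boundaries$geometry
  surfaces <- boundaries$surfaces
  total_viol <- 0L
  ramp <- function(n, fade_lo, fade_hi) {
    w <- rep(1, n)
    if (fade_lo && margin > 0L)
      w <- pmin(w, seq_len(n) / (margin + 1))
    if (fade_hi && margin > 0L)
      w <- pmin(w, rev(seq_len(n)) / (margin + 1))
    pmin(w, 1)
  }
  for (corr in corrections) {
    if (!inherits(corr, "boundary_correction"))
      stop("corrections must be boundary_correction objects", call. = FALSE)
    if (is.null(surfaces[[corr$junction]]))
      stop("unknown junction in correction: ", corr$junction, call. = FALSE)
    bs <- corr$bscans; as_ <- corr$ascans
    if (min(bs) < 1L || max(bs) > g$n_bscans ||
        min(as_) < 1L || max(as_) > g$n_ascans)
      stop("correction patch outside volume extent", call. = FALSE)
    s <- surfaces[[corr$junction]]
    wb <- ramp(length(bs), min(bs) > 1L, max(bs) < g$n_bscans)
    wa <- ramp(length(as_), min(as_) > 1L, max(as_) < g$n_ascans)
    W <- outer(wb, wa, pmin)
    s[bs, as_] <- (1 - W) * s[bs, as_] + W * corr$depth_px
    s <- pmin(pmax(s, 0), g$n_depth - 1 - 1e-9)
    # clamp the corrected junction between its neighbours
    i <- match(corr$junction, JUNCTIONS)
    before <- s
    if (i > 1L && !is.null(surfaces[[JUNCTIONS[i - 1L]]]))
      s <- pmax(s, surfaces[[JUNCTIONS[i - 1L]]])
    if (i < length(JUNCTIONS) && !is.null(surfaces[[JUNCTIONS[i + 1L]]]))
      s <- pmin(s, surfaces[[JUNCTIONS[i + 1L]]])
    total_viol <- total_viol + sum(abs(s - before) > 1e-9)
    surfaces[[corr$junction]] <- s
  }
  if (total_viol > 0L)
    message(sprintf("apply_corrections: clipped %d position(s) to preserve boundary order",
                    total_viol))
  out <- boundary_set(surfaces, g, enforce_order = TRUE)
  attr(out, "violations") <- total_viol
  out
}

# 2-D median filter with replicated edges
medfilt2 <- function(m, window) {
  k <- (window - 1L) %/% 2L
  if (k == 0L) return(m)
  nb <- nrow(m); na <- ncol(m)
  stack <- array(NA_real_, c(nb, na, window * window))
  s <- 0L
  for (di in -k:k) for (dj in -k:k) {
    s <- s + 1L
    ri <- pmin(pmax(seq_len(nb) + di, 1L), nb)
    cj <- pmin(pmax(seq_len(na) + dj, 1L), na)
    stack[, , s] <- m[ri, cj]
  }
  apply(stack, c(1, 2), stats::median)
}

#' Median-smooth boundary surfaces
#'
#' Applies a \code{window x window} 2-D median filter over (bscan, ascan) to
#' each surface, removing isolated segmentation spikes, then re-enforces the
#' non-crossing order.  \code{window = 1} is the identity.
#'
#' @param boundaries a \code{\link{boundary_set}}.
#' @param window odd window size >= 1.
#' @return A smoothed \code{boundary_set}.
#' @export
smooth_boundaries <- function(boundaries, window = 5L) {
  stopifnot(inherits(boundaries, "boundary_set"))
  stopifnot_scalar(window, "window", min = 1, integer = TRUE)
  if (window %% 2L == 0L) stop("'window' must be odd", call. = FALSE)
  surfaces <- lapply(boundaries$surfaces, medfilt2, window = window)
  boundary_set(surfaces, boundaries$geometry, enforce_order = TRUE)
}
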