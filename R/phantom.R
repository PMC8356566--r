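# Synthetic retinal phantom: layered reflectivity with a foveal pit, vessel
# tubes in three depth strata, per-repeat flow jitter at vessel voxels,
# optional INL cystoid spaces, and multiplicative speckle.  Everything the
# pipeline consumes has known ground truth, so each stage is testable without
# clinical data.

#' Phantom configuration
#'
#' The default geometry is the repeated-B-scan acquisition pattern scaled down
#' laterally (4 repeats per location, 64 B-scans x 128 A-scans instead of the
#' clinical 250-500 x 500, 160 depth px at 4.37 um/px) so that full-pipeline
#' runs stay fast while keeping the axial scale — and hence all pixel offsets —
#' identical to the clinical setting.  \code{stage = "term"} emulates a
#' three-layered perifoveal vasculature (around 40 weeks postmenstrual age);
#' \code{stage = "early"} (around 35 weeks) has dilated, tortuous superficial
#' vessels and no intermediate or deep plexus (their tube counts are forced
#' to zero).
#'
#' @param stage \code{"term"} or \code{"early"}.
#' @param n_repeats,n_bscans,n_ascans,depth_px scan geometry.
#' @param axial_pixel_depth_um axial sampling, um/px.
#' @param fovea include a foveal pit.
#' @param pit_width_px,pit_depth_px lateral sigma and depth of the pit.
#' @param n_scp,n_icp,n_dcp vessel tubes per plexus (term stage).
#' @param flow_amplitude s.d. of the per-repeat intensity jitter at flow
#'   voxels (same units as reflectivity; 0 disables flow).
#' @param speckle_sigma s.d. of the multiplicative speckle factor.
#' @param edema add dark cystoid spaces inside the INL.
#' @param n_cysts,cyst_size_px cyst count and (lateral, axial) semi-axes.
#' @param seed integer seed; all randomness derives from it.
#' @return list of class \code{phantom_config}.
#' @export
phantom_config <- function(stage = c("term", "early"),
                           n_repeats = 4L, n_bscans = 64L, n_ascans = 128L,
                           depth_px = 160L, axial_pixel_depth_um = 4.37,
                           fovea = TRUE, pit_width_px = 18, pit_depth_px = 26,
                           n_scp = 14L, n_icp = 12L, n_dcp = 12L,
                           flow_amplitude = 0.25, speckle_sigma = 0.05,
                           edema = FALSE, n_cysts = 6L, cyst_size_px = c(9, 4),
                           seed = 1L) {
  stage <- match.arg(stage)
  stopifnot_scalar(seed, "seed", min = 0, max = 2^31 - 100, integer = TRUE)
  stopifnot_scalar(flow_amplitude, "flow_amplitude", min = 0)
  stopifnot_scalar(speckle_sigma, "speckle_sigma", min = 0)
  if (stage == "early") { n_icp <- 0L; n_dcp <- 0L }
  geometry <- acquisition_geometry(n_repeats, n_bscans, n_ascans, depth_px,
                                   axial_pixel_depth_um)
  structure(list(stage = stage, geometry = geometry, fovea = fovea,
                 pit_width_px = pit_width_px, pit_depth_px = pit_depth_px,
                 n_scp = as.integer(n_scp), n_icp = as.integer(n_icp),
                 n_dcp = as.integer(n_dcp),
                 flow_amplitude = flow_amplitude, speckle_sigma = speckle_sigma,
                 edema = isTRUE(edema), n_cysts = as.integer(n_cysts),
                 cyst_size_px = cyst_size_px, seed = as.integer(seed)),
            class = "phantom_config")
}

# layer reflectivity levels (linear scale)
PHANTOM_LEVELS <- c(vitreous = 0.04, inner = 0.70, inl = 0.25, opl = 0.65,
                    onl = 0.18, rpe = 0.85, below = 0.10)

# rasterize a piecewise-constant depth profile with linear partial volume:
# voxel z (extent [z-0.5, z+0.5)) gets the length-weighted mean of the layer
# levels it straddles.  bounds: list of (B x X) matrices, vitreous->choroid;
# levels: length(bounds)+1 values.
rasterize_layers <- function(bounds, levels, nb, nz, nx) {
  zc <- depth_grid(nb, nz, nx)
  full <- list(array(-0.5, c(nb, nz, nx)))
  for (m in bounds) full <- c(full, list(bcast_bx(m, nz)))
  full <- c(full, list(array(nz - 0.5, c(nb, nz, nx))))
  s <- array(0, c(nb, nz, nx))
  for (i in seq_along(levels)) {
    a <- pmax(full[[i]], zc - 0.5)
    b <- pmin(full[[i + 1L]], zc + 0.5)
    s <- s + levels[i] * pmax(0, b - a)
  }
  s
}

# draw smooth random tubes in a plexus stratum; returns max-combined Gaussian
# weights in a (B, Z, X) array.  depth_at(b, x) gives the tube centre depth.
draw_tubes <- function(w, n_tubes, depth_at, radius_range, curvature,
                       faz_radius, nb, nz, nx) {
  if (n_tubes == 0L) return(w)
  bc <- (nb + 1) / 2; xc <- (nx + 1) / 2
  asp <- nb / nx  # lateral aspect: b axis is coarser
  for (k in seq_len(n_tubes)) {
    radius <- stats::runif(1, radius_range[1], radius_range[2])
    sig_l <- radius / 1.2
    sig_z <- 0.8 * sig_l
    hw <- ceiling(2.2 * sig_l); hz <- ceiling(2.2 * sig_z)
    # start on a random domain edge heading inward
    edge <- sample.int(4L, 1L)
    p <- switch(edge,
                c(stats::runif(1, 1, nb), 1),
                c(stats::runif(1, 1, nb), nx),
                c(1, stats::runif(1, 1, nx)),
                c(nb, stats::runif(1, 1, nx)))
    theta <- atan2(bc - p[1], xc - p[2]) + stats::rnorm(1, 0, 0.5)
    n_steps <- ceiling(1.6 * (nb + nx))
    for (s in seq_len(n_steps)) {
      theta <- theta + stats::rnorm(1, 0, curvature)
      p <- p + 0.8 * c(sin(theta), cos(theta))
      if (p[1] < 1 || p[1] > nb || p[2] < 1 || p[2] > nx) break
      # stay out of the foveal avascular zone (elliptical, b axis scaled)
      if (((p[1] - bc) / asp)^2 + (p[2] - xc)^2 < faz_radius^2) next
      bi <- round(p[1]); xi <- round(p[2])
      zc <- depth_at(bi, xi)
      zi0 <- round(zc)
      bw <- max(1L, bi - hw):min(nb, bi + hw)
      zw <- max(1L, zi0 - hz):min(nz, zi0 + hz)
      xw <- max(1L, xi - hw):min(nx, xi + hw)
      db <- (bw - p[1]) / asp  # isotropic lateral distance in A-scan px
      dz <- zw - 1 - zc        # voxel depth positions are 0-based
      dx <- xw - p[2]
      blob <- exp(-(outer(outer(db^2, dz^2 * (sig_l / sig_z)^2, "+"), dx^2, "+")
                    / (2 * sig_l^2)))
      w[bw, zw, xw] <- pmax(w[bw, zw, xw], blob)
    }
  }
  w
}

#' Generate a synthetic OCT-A phantom
#'
#' Builds a repeated-B-scan acquisition with known ground truth:
#' \itemize{
#'   \item layered reflectivity (bright inner retina and OPL, darker INL/ONL,
#'     bright RPE band) deformed by a smooth foveal pit;
#'   \item vessels as curved Gaussian-profile tubes — SCP spread through the
#'     ganglion-cell-layer band (with large, tortuous trunks in the early
#'     stage), ICP in a thin stratum just below the IPL/INL junction, DCP in
#'     the band above the OPL/ONL junction — all avoiding a foveal avascular
#'     zone (largest for the DCP);
#'   \item per-repeat Gaussian intensity jitter at vessel voxels (the flow
#'     signal speckle variance detects), vessels slightly hyperreflective;
#'   \item optional dark cystoid spaces inside the INL (macular edema);
#'   \item multiplicative speckle on every voxel and repeat.
#' }
#' All randomness derives deterministically from \code{config$seed} (one
#' sub-seed per component), so identical configs give identical phantoms.
#'
#' @param config a \code{\link{phantom_config}}.
#' @return list with \code{volume} (an \code{\link{acquisition_volume}}) and
#'   \code{truth} (class \code{phantom_truth}: \code{boundaries} — the true
#'   \code{\link{boundary_set}}; \code{vessel_labels} — integer
#'   (bscan, depth, ascan) array, 0 = none, 1:3 = SCP/ICP/DCP per
#'   \code{attr(, "plexus")}; \code{cyst_mask} — logical array).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$geometry
  nb <- g$n_bscans; nz <- g$n_depth; nx <- g$n_ascans; nr <- g$n_repeats
  axsc <- nz / 160  # axial scale relative to the reference 160-px design

  ## -- layers and pit (sub-seed 1) ------------------------------------------
  set.seed(config$seed + 1L)
  ilm0 <- 30 * axsc; ipl0 <- 70 * axsc; opl0 <- 90 * axsc
  opl_thick <- 8 * axsc
  rpe_top0 <- opl0 + 28 * axsc; rpe_bot0 <- rpe_top0 + 6 * axsc
  bc <- (nb + 1) / 2; xc <- (nx + 1) / 2
  sx <- config$pit_width_px; sb <- config$pit_width_px * nb / nx
  G <- if (config$fovea && config$pit_depth_px > 0) {
    outer(exp(-((seq_len(nb) - bc)^2) / (2 * sb^2)),
          exp(-((seq_len(nx) - xc)^2) / (2 * sx^2)))
  } else matrix(0, nb, nx)
  pit <- config$pit_depth_px * axsc
  ilm <- ilm0 + pit * G
  ipl <- ipl0 + 0.45 * pit * G
  opl <- opl0 + 0.12 * pit * G
  inl_opl <- opl - opl_thick
  rpe_top <- matrix(rpe_top0, nb, nx); rpe_bot <- matrix(rpe_bot0, nb, nx)
  S <- rasterize_layers(list(ilm, ipl, inl_opl, opl, rpe_top, rpe_bot),
                        unname(PHANTOM_LEVELS), nb, nz, nx)

  ## -- vessels (sub-seed 2) -------------------------------------------------
  set.seed(config$seed + 2L)
  early <- config$stage == "early"
  w_scp <- array(0, c(nb, nz, nx))
  w_icp <- array(0, c(nb, nz, nx))
  w_dcp <- array(0, c(nb, nz, nx))
  gap <- ipl - ilm
  w_scp <- draw_tubes(
    w_scp, config$n_scp,
    depth_at = function(b, x) ilm[b, x] + stats::runif(1, 0.25, 0.7) * gap[b, x],
    radius_range = if (early) c(2.2, 3.2) else c(1.3, 2.2),
    curvature = if (early) 0.30 else 0.10,
    faz_radius = 10, nb = nb, nz = nz, nx = nx)
  w_icp <- draw_tubes(
    w_icp, config$n_icp,
    depth_at = function(b, x) ipl[b, x] + 2 * axsc,
    radius_range = c(1.1, 1.6), curvature = 0.30,  # loop-like
    faz_radius = 10, nb = nb, nz = nz, nx = nx)
  w_dcp <- draw_tubes(
    w_dcp, config$n_dcp,
    depth_at = function(b, x) opl[b, x] - 4 * axsc,
    radius_range = c(1.1, 1.6), curvature = 0.18,  # dendritic processes
    faz_radius = 14, nb = nb, nz = nz, nx = nx)
  wmax <- pmax(w_scp, w_icp, w_dcp)
  labels <- array(0L, c(nb, nz, nx))
  vess <- wmax >= 0.35
  labels[vess & w_scp == wmax] <- 1L
  labels[vess & w_icp == wmax] <- 2L
  labels[vess & w_dcp == wmax] <- 3L
  attr(labels, "plexus") <- c("SCP", "ICP", "DCP")

  ## -- cysts (sub-seed 3) ---------------------------------------------------
  cyst_mask <- array(FALSE, c(nb, nz, nx))
  if (config$edema && config$n_cysts > 0L) {
    set.seed(config$seed + 3L)
    zg <- depth_grid(nb, nz, nx)
    for (k in seq_len(config$n_cysts)) {
      cb <- round(stats::runif(1, bc - 2.0 * sb, bc + 2.0 * sb))
      cx <- round(stats::runif(1, xc - 2.0 * sx, xc + 2.0 * sx))
      cb <- min(max(cb, 2L), nb - 1L); cx <- min(max(cx, 2L), nx - 1L)
      cz <- (ipl[cb, cx] + inl_opl[cb, cx]) / 2
      rx <- stats::runif(1, 0.6, 1) * config$cyst_size_px[1]
      rz <- min(stats::runif(1, 0.6, 1) * config$cyst_size_px[2] * axsc,
                (inl_opl[cb, cx] - ipl[cb, cx]) / 2)
      rb <- max(rx * nb / nx, 1.5)
      db2 <- ((seq_len(nb) - cb) / rb)^2
      dx2 <- ((seq_len(nx) - cx) / rx)^2
      dz2 <- ((0:(nz - 1) - cz) / rz)^2
      e2 <- outer(outer(db2, dz2, "+"), dx2, "+")
      inside <- e2 < 1
      S[inside] <- S[inside] * (0.08 + 0.92 * e2[inside]^2)  # near-black core
      cyst_mask <- cyst_mask | inside
    }
  }

  ## -- vessel reflectivity, flow jitter, speckle (sub-seeds 4, 5) -----------
  S <- S + 0.30 * wmax          # vessels slightly hyperreflective
  n_vox <- nb * nz * nx
  vol <- array(0, c(nr, nb, nz, nx))
  set.seed(config$seed + 4L)
  flow_noise <- array(stats::rnorm(nr * n_vox), c(nr, nb, nz, nx))
  set.seed(config$seed + 5L)
  speckle <- array(stats::rnorm(nr * n_vox), c(nr, nb, nz, nx))
  for (r in seq_len(nr)) {
    ir <- S + config$flow_amplitude * wmax * flow_noise[r, , , ]
    ir <- ir * (1 + config$speckle_sigma * speckle[r, , , ])
    vol[r, , , ] <- pmax(ir, 0)
  }

  truth <- structure(
    list(boundaries = boundary_set(list(ILM = ilm, IPL_INL = ipl,
                                        OPL_ONL = opl), g),
         vessel_labels = labels, cyst_mask = cyst_mask),
    class = "phantom_truth")
  list(volume = acquisition_volume(vol, g), truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  lv <- attr(x$vessel_labels, "plexus")
  cnt <- tabulate(x$vessel_labels, nbins = length(lv))
  cat("Phantom ground truth\n")
  cat("  vessel voxels:",
      paste(sprintf("%s=%d", lv, cnt), collapse = " "), "\n")
  cat(sprintf("  cyst voxels: %d\n", sum(x$cyst_mask)))
  invisible(x)
}

#' Score slab assignment of ground-truth flow voxels
#'
#' For every labeled vessel voxel, records which slab interval of the resolved
#' scheme surfaces contains it (intervals \code{[round(upper), round(lower))},
#' the deepest slab inclusive), and tabulates plexus labels against assigned
#' slabs.  Per-plexus recall is the fraction of a plexus' voxels falling in
#' the same-named slab — a quantitative stand-in for the visual criterion of
#' minimizing intermediate-plexus projections onto the deep slab.
#'
#' @param truth a \code{phantom_truth} from \code{\link{generate_phantom}}.
#' @param surfaces a \code{slab_surfaces} from \code{\link{resolve_surfaces}}.
#' @return list of class \code{slab_assignment}: \code{table} (plexus x slab
#'   counts, with an \code{outside} column), \code{recall} (named vector),
#'   \code{n} voxels scored.
#' @export
evaluate_slab_assignment <- function(truth, surfaces) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(surfaces, "slab_surfaces"))
  labels <- truth$vessel_labels
  plexus <- attr(labels, "plexus")
  idx <- which(labels > 0L, arr.ind = TRUE)
  slab_names <- names(surfaces)
  if (nrow(idx) == 0L) {
    tab <- matrix(0L, 0, length(slab_names) + 1L,
                  dimnames = list(NULL, c(slab_names, "outside")))
    return(structure(list(table = tab, recall = setNames(numeric(0), character(0)),
                          n = 0L), class = "slab_assignment"))
  }
  z0 <- idx[, 2] - 1L  # 0-based voxel depth
  flat <- cbind(idx[, 1], idx[, 3])
  assigned <- rep("outside", nrow(idx))
  k <- length(surfaces)
  for (i in seq_len(k)) {
    ru <- round_half_up(surfaces[[i]]$upper)[flat]
    rl <- round_half_up(surfaces[[i]]$lower)[flat] + if (i == k) 1L else 0L
    assigned[z0 >= ru & z0 < rl] <- slab_names[i]
  }
  lab <- factor(plexus[labels[idx]], levels = plexus)
  asg <- factor(assigned, levels = c(slab_names, "outside"))
  tab <- table(plexus = lab, slab = asg)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  recall <- vapply(rownames(tab), function(p) {
    if (p %in% colnames(tab)) tab[p, p] / sum(tab[p, ]) else NA_real_
  }, numeric(1))
  structure(list(table = tab, recall = recall, n = nrow(idx)),
            class = "slab_assignment")
}

#' @export
print.slab_assignment <- function(x, ...) {
  cat(sprintf("Slab assignment of %d ground-truth flow voxels\n", x$n))
  if (x$n > 0) {
    print(x$table)
    cat("recall:",
        paste(sprintf("%s=%.3f", names(x$recall), x$recall), collapse = " "),
        "\n")
  }
  invisible(x)
}
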