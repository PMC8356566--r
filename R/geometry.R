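#' Acquisition geometry of a repeated-B-scan OCT-A volume
#'
#' Describes the scan pattern of an OCT-A acquisition: the number of repeated
#' B-scans per lateral location (motion contrast needs at least two), the
#' lateral raster (B-scans x A-scans), and the axial sampling in micrometres
#' per pixel.  The default axial pixel depth of 4.37 um/px matches the
#' handheld swept-source scan pattern the pipeline was designed around, where
#' offset parameters are stepped in whole pixels (1 px = 4.37 um).
#'
#' The canonical voxel order everywhere in this package is
#' (repeat, bscan, depth, ascan), with depth index 0 on the vitreous side
#' increasing toward the choroid, so "above a junction" always means a
#' smaller depth index.
#'
#' @param n_repeats repeats per lateral location (>= 2).
#' @param n_bscans number of B-scan locations.
#' @param n_ascans A-scans per B-scan.
#' @param n_depth axial samples per A-scan.
#' @param axial_pixel_depth_um axial sampling, micrometres per pixel (> 0).
#' @param lateral_extent_mm length-2 numeric, scan extent (bscan, ascan) in mm.
#' @return An object of class \code{acquisition_geometry}.
#' @export
acquisition_geometry <- function(n_repeats, n_bscans, n_ascans, n_depth,
                                 axial_pixel_depth_um = 4.37,
                                 lateral_extent_mm = c(2.5, 2.5)) {
  stopifnot_scalar(n_repeats, "n_repeats", min = 2, integer = TRUE)
  stopifnot_scalar(n_bscans, "n_bscans", min = 1, integer = TRUE)
  stopifnot_scalar(n_ascans, "n_ascans", min = 1, integer = TRUE)
  stopifnot_scalar(n_depth, "n_depth", min = 1, integer = TRUE)
  stopifnot_scalar(axial_pixel_depth_um, "axial_pixel_depth_um", min = 1e-9)
  if (length(lateral_extent_mm) != 2L || any(!is.finite(lateral_extent_mm)))
    stop("'lateral_extent_mm' must be two finite numbers", call. = FALSE)
  structure(list(
    n_repeats = as.integer(n_repeats),
    n_bscans = as.integer(n_bscans),
    n_ascans = as.integer(n_ascans),
    n_depth = as.integer(n_depth),
    axial_pixel_depth_um = as.numeric(axial_pixel_depth_um),
    lateral_extent_mm = as.numeric(lateral_extent_mm)
  ), class = "acquisition_geometry")
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("OCT-A acquisition geometry\n")
  cat(sprintf("  %d repeats x %d B-scans x %d depth px x %d A-scans\n",
              x$n_repeats, x$n_bscans, x$n_depth, x$n_ascans))
  cat(sprintf("  axial sampling %.3f um/px; lateral extent %.2f x %.2f mm\n",
              x$axial_pixel_depth_um,
              x$lateral_extent_mm[1], x$lateral_extent_mm[2]))
  invisible(x)
}

#' Raw OCT-A acquisition volume
#'
#' Bundles a 4-D array of nonnegative structural reflectivities, indexed
#' (repeat, bscan, depth, ascan), with its \code{\link{acquisition_geometry}}.
#' Intensities must be finite and nonnegative; any log-compressed export must
#' be linearized by the caller before flow computation, since speckle
#' variance is defined on linear intensity.
#'
#' @param intensities 4-D numeric array, (repeat, bscan, depth, ascan).
#' @param geometry an \code{acquisition_geometry} matching \code{dim(intensities)}.
#' @return An object of class \code{acquisition_volume}.
#' @export
acquisition_volume <- function(intensities, geometry) {
  if (!inherits(geometry, "acquisition_geometry"))
    stop("'geometry' must be an acquisition_geometry", call. = FALSE)
  d <- dim(intensities)
  if (length(d) != 4L)
    stop("'intensities' must be a 4-D array (repeat, bscan, depth, ascan)",
         call. = FALSE)
  expect <- c(geometry$n_repeats, geometry$n_bscans,
              geometry$n_depth, geometry$n_ascans)
  if (!identical(as.integer(d), expect))
    stop(sprintf(
      "array shape (%s) does not match geometry (%s)",
      paste(d, collapse = "x"), paste(expect, collapse = "x")), call. = FALSE)
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop("intensities contain non-finite voxels", call. = FALSE)
  if (any(intensities < 0))
    stop("intensities must be nonnegative", call. = FALSE)
  structure(list(intensities = intensities, geometry = geometry),
            class = "acquisition_volume")
}

#' @export
print.acquisition_volume <- function(x, ...) {
  cat("OCT-A acquisition volume\n")
  print(x$geometry)
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Flow (angiography) volume
#'
#' Per-voxel motion-contrast values indexed (bscan, depth, ascan), as produced
#' by \code{\link{speckle_variance}}.  Flow values are nonnegative;
#' \code{provenance} records how they were computed (alignment shifts,
#' variance convention, masking).
#'
#' @param flow 3-D nonnegative numeric array (bscan, depth, ascan).
#' @param geometry the source \code{acquisition_geometry}.
#' @param provenance list of processing settings.
#' @return An object of class \code{flow_volume}.
#' @export
flow_volume <- function(flow, geometry, provenance = list()) {
  d <- dim(flow)
  if (length(d) != 3L)
    stop("'flow' must be a 3-D array (bscan, depth, ascan)", call. = FALSE)
  expect <- c(geometry$n_bscans, geometry$n_depth, geometry$n_ascans)
  if (!identical(as.integer(d), expect))
    stop("flow shape does not match geometry", call. = FALSE)
  if (anyNA(flow) || any(flow < 0))
    stop("flow values must be finite and nonnegative", call. = FALSE)
  structure(list(flow = flow, geometry = geometry, provenance = provenance),
            class = "flow_volume")
}

#' @export
print.flow_volume <- function(x, ...) {
  cat("OCT-A flow volume (speckle variance)\n")
  cat(sprintf("  %d B-scans x %d depth px x %d A-scans; flow range [%.4g, %.4g]\n",
              dim(x$flow)[1], dim(x$flow)[2], dim(x$flow)[3],
              min(x$flow), max(x$flow)))
  invisible(x)
}

# canonical junction names, vitreous -> choroid
JUNCTIONS <- c("ILM", "IPL_INL", "OPL_ONL")

#' Retinal boundary surfaces
#'
#' Holds the three anatomical junction surfaces used as slab references:
#' the vitreous/inner-limiting-membrane junction (\code{ILM}), the inner
#' plexiform / inner nuclear layer junction (\code{IPL_INL}) and the outer
#' plexiform / outer nuclear layer junction (\code{OPL_ONL}).  Each surface
#' is a (bscan x ascan) matrix of fractional depth positions on the 0-based
#' depth scale.  Construction enforces the anatomical non-crossing order
#' ILM <= IPL_INL <= OPL_ONL at every lateral position.
#'
#' @param surfaces named list of (bscan x ascan) numeric matrices; names must
#'   be a subset of \code{c("ILM", "IPL_INL", "OPL_ONL")}.
#' @param geometry an \code{acquisition_geometry}; depth positions must lie
#'   within \code{[0, n_depth)}.
#' @param enforce_order clip violating positions (vitreous to choroid) instead
#'   of erroring; the number of clipped positions is kept in
#'   \code{attr(, "order_violations")}.
#' @return An object of class \code{boundary_set}.
#' @export
boundary_set <- function(surfaces, geometry, enforce_order = FALSE) {
  if (is.null(names(surfaces)) || !all(names(surfaces) %in% JUNCTIONS))
    stop("surface names must be among: ", paste(JUNCTIONS, collapse = ", "),
         call. = FALSE)
  surfaces <- surfaces[intersect(JUNCTIONS, names(surfaces))]  # canonical order
  dm <- c(geometry$n_bscans, geometry$n_ascans)
  for (nm in names(surfaces)) {
    s <- surfaces[[nm]]
    if (!is.matrix(s) || !identical(as.integer(dim(s)), as.integer(dm)))
      stop(sprintf("surface '%s' must be a %dx%d matrix", nm, dm[1], dm[2]),
           call. = FALSE)
    if (anyNA(s) || any(s < 0) || any(s >= geometry$n_depth))
      stop(sprintf("surface '%s' has positions outside [0, %d)",
                   nm, geometry$n_depth), call. = FALSE)
  }
  violations <- 0L
  if (length(surfaces) > 1L) {
    nms <- names(surfaces)
    for (i in seq_along(nms)[-1L]) {
      bad <- surfaces[[nms[i]]] < surfaces[[nms[i - 1L]]]
      if (any(bad)) {
        if (!enforce_order)
          stop(sprintf("non-crossing order violated: %s < %s at %d positions",
                       nms[i], nms[i - 1L], sum(bad)), call. = FALSE)
        violations <- violations + sum(bad)
        surfaces[[nms[i]]][bad] <- surfaces[[nms[i - 1L]]][bad]
      }
    }
  }
  structure(list(surfaces = surfaces, geometry = geometry),
            class = "boundary_set", order_violations = violations)
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("Retinal boundary set\n")
  for (nm in names(x$surfaces)) {
    s <- x$surfaces[[nm]]
    cat(sprintf("  %-8s depth %.2f-%.2f px (%dx%d)\n",
                nm, min(s), max(s), nrow(s), ncol(s)))
  }
  invisible(x)
}
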