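# Volume, boundary and image I/O.
#
# Two volume containers are supported:
#   * HDF5 (lossless): single 4-D dataset "volume" + geometry attributes.
#   * multi-page TIFF (quantized): one 16-bit page per (repeat, bscan) pair,
#     repeat-major page order, with a JSON sidecar carrying the geometry and
#     the intensity scale divided out for storage.
# A JSON sidecar (<path>.json), when present, overrides embedded metadata:
# an explicit sidecar is taken as user intent.

AXIS_CODES <- c(r = "repeat", b = "bscan", z = "depth", a = "ascan")

parse_layout <- function(layout) {
  ax <- strsplit(layout, "")[[1]]
  if (length(ax) != 4L || !setequal(ax, names(AXIS_CODES)))
    stop("'layout' must name the four axes r, b, z, a exactly once (e.g. \"rbza\")",
         call. = FALSE)
  match(names(AXIS_CODES), ax)  # permutation: canonical <- stored
}

sidecar_path <- function(path) paste0(path, ".json")

geometry_to_list <- function(g) {
  list(n_repeats = g$n_repeats, n_bscans = g$n_bscans, n_ascans = g$n_ascans,
       n_depth = g$n_depth, axial_pixel_depth_um = g$axial_pixel_depth_um,
       lateral_extent_mm = g$lateral_extent_mm)
}

geometry_from_list <- function(l) {
  acquisition_geometry(
    n_repeats = l$n_repeats, n_bscans = l$n_bscans, n_ascans = l$n_ascans,
    n_depth = l$n_depth,
    axial_pixel_depth_um = l$axial_pixel_depth_um %||% 4.37,
    lateral_extent_mm = as.numeric(l$lateral_extent_mm %||% c(2.5, 2.5)))
}

is_h5 <- function(path) grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)
is_tiff <- function(path) grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)

#' Load an OCT-A acquisition volume
#'
#' Reads a 4-D acquisition from HDF5 (dataset \code{volume} with geometry
#' attributes) or multi-page TIFF (with mandatory JSON sidecar), permutes the
#' stored axis order to the canonical (repeat, bscan, depth, ascan) order, and
#' validates the result.  Canonicalization is a pure permutation: the voxel
#' multiset is unchanged.
#'
#' @param path file to read (.h5/.hdf5 or .tif/.tiff).
#' @param layout four-letter axis-order descriptor of the stored array using
#'   codes r (repeat), b (bscan), z (depth), a (ascan); ignored when the file
#'   records its own layout.
#' @return An \code{\link{acquisition_volume}}.
#' @export
load_volume <- function(path, layout = "rbza") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  side <- NULL
  if (file.exists(sidecar_path(path)))
    side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)

  if (is_h5(path)) {
    arr <- rhdf5::h5read(path, "volume")
    att <- rhdf5::h5readAttributes(path, "volume")
    rhdf5::h5closeAll()
    meta <- att
    if (!is.null(side)) meta[names(side)] <- side  # sidecar wins on conflict
    layout <- as.character(meta$layout %||% layout)
    geom_meta <- meta
  } else if (is_tiff(path)) {
    if (is.null(side))
      stop("multi-page TIFF volumes require a JSON sidecar: ",
           sidecar_path(path), call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nz <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    R <- side$n_repeats; B <- side$n_bscans
    if (length(pages) != R * B)
      stop(sprintf("expected %d pages (%d repeats x %d B-scans), found %d",
                   R * B, R, B, length(pages)), call. = FALSE)
    arr <- array(0, c(R, B, nz, nx))
    for (r in seq_len(R)) for (b in seq_len(B))
      arr[r, b, , ] <- pages[[(r - 1L) * B + b]]
    scale <- side$intensity_scale %||% 1
    arr <- arr * scale
    layout <- "rbza"
    geom_meta <- side
  } else stop("unsupported volume container: ", path, call. = FALSE)

  perm <- parse_layout(layout)
  if (!identical(perm, 1:4)) arr <- aperm(arr, perm)
  if (anyNA(arr) || any(!is.finite(arr)))
    stop("volume contains non-finite voxels", call. = FALSE)
  geom <- acquisition_geometry(
    n_repeats = as.integer(geom_meta$n_repeats %||% dim(arr)[1]),
    n_bscans = as.integer(geom_meta$n_bscans %||% dim(arr)[2]),
    n_ascans = as.integer(geom_meta$n_ascans %||% dim(arr)[4]),
    n_depth = as.integer(geom_meta$n_depth %||% dim(arr)[3]),
    axial_pixel_depth_um = as.numeric(geom_meta$axial_pixel_depth_um %||% 4.37),
    lateral_extent_mm = as.numeric(geom_meta$lateral_extent_mm %||% c(2.5, 2.5)))
  acquisition_volume(arr, geom)
}

#' Save an OCT-A acquisition volume
#'
#' HDF5 output is lossless (doubles, canonical axis order, geometry stored as
#' dataset attributes).  TIFF output quantizes to 16 bits after dividing by
#' the volume maximum; the scale is recorded in the JSON sidecar so that
#' reloading recovers intensities up to quantization.
#'
#' @param volume an \code{\link{acquisition_volume}}.
#' @param path destination (.h5/.hdf5 lossless, or .tif/.tiff quantized).
#' @return \code{path}, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "acquisition_volume"))
  g <- volume$geometry
  if (is_h5(path)) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createDataset(path, "volume", dim(volume$intensities),
                           storage.mode = "double", level = 0, chunk = NULL)
    rhdf5::h5write(volume$intensities, path, "volume")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "volume")
    meta <- c(geometry_to_list(g), list(layout = "rbza"))
    for (nm in names(meta)) rhdf5::h5writeAttribute(meta[[nm]], did, nm)
    rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
    rhdf5::h5closeAll()
  } else if (is_tiff(path)) {
    a <- volume$intensities
    scale <- max(a, 1e-12)
    q <- floor(a / scale * 65535 + 0.5)          # round half-up
    a01 <- pmin((q + 0.5) / 65535, 1)            # compensates writeTIFF truncation
    pages <- vector("list", g$n_repeats * g$n_bscans)
    for (r in seq_len(g$n_repeats)) for (b in seq_len(g$n_bscans))
      pages[[(r - 1L) * g$n_bscans + b]] <- a01[r, b, , ]
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    jsonlite::write_json(
      c(geometry_to_list(g),
        list(layout = "rbza", page_order = "repeat_major",
             intensity_scale = scale)),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else stop("unsupported volume container: ", path, call. = FALSE)
  invisible(path)
}

#' Read boundary surfaces from CSV or JSON
#'
#' The CSV carrier has header \code{junction,bscan,ascan,depth_px} with
#' 0-based \code{bscan}/\code{ascan} indices and fractional 0-based depth
#' positions; the JSON carrier holds the same records.  Every named junction
#' must cover the full lateral grid.
#'
#' @param path .csv or .json file.
#' @param geometry optional \code{acquisition_geometry}; when absent a minimal
#'   carrier geometry is inferred from the table extents.
#' @return A \code{\link{boundary_set}}.
#' @export
load_boundaries <- function(path, geometry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- as.data.frame(tab)
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("junction", "bscan", "ascan", "depth_px")
  if (!all(need %in% names(tab)))
    stop("boundary table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tab$junction %in% JUNCTIONS))
    stop("unknown junction name(s): ",
         paste(setdiff(unique(tab$junction), JUNCTIONS), collapse = ", "),
         call. = FALSE)
  nb <- max(tab$bscan) + 1L; na <- max(tab$ascan) + 1L
  if (is.null(geometry)) {
    geometry <- acquisition_geometry(
      n_repeats = 2L, n_bscans = nb, n_ascans = na,
      n_depth = as.integer(ceiling(max(tab$depth_px))) + 1L)
  }
  if (any(tab$bscan < 0) || any(tab$ascan < 0) ||
      nb > geometry$n_bscans || na > geometry$n_ascans)
    stop("boundary indices out of range for geometry", call. = FALSE)
  surfaces <- list()
  for (j in unique(tab$junction)) {
    sub <- tab[tab$junction == j, ]
    if (nrow(sub) != geometry$n_bscans * geometry$n_ascans)
      stop(sprintf("junction '%s' does not cover the full %dx%d grid", j,
                   geometry$n_bscans, geometry$n_ascans), call. = FALSE)
    m <- matrix(NA_real_, geometry$n_bscans, geometry$n_ascans)
    m[cbind(sub$bscan + 1L, sub$ascan + 1L)] <- sub$depth_px
    surfaces[[j]] <- m
  }
  boundary_set(surfaces, geometry)
}

#' Write boundary surfaces to CSV or JSON
#'
#' Lossless round-trip companion of \code{\link{load_boundaries}}: depth
#' positions are written at full precision as fractional pixels.
#'
#' @param boundaries a \code{\link{boundary_set}}.
#' @param path destination .csv or .json file.
#' @return \code{path}, invisibly.
#' @export
save_boundaries <- function(boundaries, path) {
  stopifnot(inherits(boundaries, "boundary_set"))
  g <- boundaries$geometry
  rows <- lapply(names(boundaries$surfaces), function(j) {
    s <- boundaries$surfaces[[j]]
    data.frame(junction = j,
               bscan = rep(0:(g$n_bscans - 1L), times = g$n_ascans),
               ascan = rep(0:(g$n_ascans - 1L), each = g$n_bscans),
               depth_px = as.vector(s))
  })
  tab <- do.call(rbind, rows)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, digits = NA)
  } else {
    utils::write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Save an en face image
#'
#' Writes a grayscale slab (matrix) or RGB composite (3-channel array) with
#' values in [0, 1].  Quantization is round-to-nearest: value v maps to
#' integer \code{floor(v * (2^bits - 1) + 0.5)}.  PNG supports 8 bits; TIFF
#' supports 8 or 16 bits.
#'
#' @param image numeric matrix or (rows x cols x 3) array, values in [0, 1].
#' @param path destination .png, .tif or .tiff file.
#' @param bit_depth 8 or 16 (16 for TIFF only).
#' @return \code{path}, invisibly.
#' @export
save_enface <- function(image, path, bit_depth = 8L) {
  if (anyNA(image) || any(image < 0) || any(image > 1))
    stop("image values must lie in [0, 1]", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  maxq <- 2^bit_depth - 1
  q <- floor(unclass(image) * maxq + 0.5)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (bit_depth != 8L)
      stop("PNG output supports bit_depth = 8 only; use TIFF for 16-bit",
           call. = FALSE)
    png::writePNG(q / maxq, path)
  } else if (is_tiff(path)) {
    tiff::writeTIFF(pmin((q + 0.5) / maxq, 1), path,
                    bits.per.sample = as.integer(bit_depth))
  } else stop("unsupported image format: ", path, call. = FALSE)
  invisible(path)
}

#' Load an en face image
#'
#' @param path .png, .tif or .tiff file.
#' @param as_integer return raw integer sample values instead of [0, 1].
#' @return numeric matrix or array, in [0, 1] unless \code{as_integer}.
#' @export
load_enface <- function(path, as_integer = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (as_integer) img <- round(img * 255)
    img
  } else if (is_tiff(path)) {
    tiff::readTIFF(path, as.is = as_integer)
  } else stop("unsupported image format: ", path, call. = FALSE)
}
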