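# Anatomically referenced offset slabs and en face projection.
#
# Sign convention (matching the depth axis, vitreous -> choroid): an offset
# "above" a junction is negative (toward the vitreous), "below" is positive.
# Slab intervals are half-open [upper, lower) on the 0-based depth scale,
# except the outer boundary of the deepest slab which is inclusive, so a
# scheme's slabs partition the ILM -> OPL/ONL band exactly.  Fractional
# boundary positions are converted to voxel indices by half-up rounding.

#' Convert a micrometre offset to whole pixels
#'
#' Offsets are tested in whole-pixel increments (1 px = 4.37 um at the default
#' axial sampling); this converts a micrometre offset to its pixel count and
#' rejects values that are not within 0.01 px of a whole pixel, which guards
#' against unit mix-ups (e.g. passing pixels where micrometres are expected).
#'
#' @param offset_um signed offset in micrometres.
#' @param axial_pixel_depth_um axial sampling in um/px (> 0).
#' @return integer pixel count (negative = above / toward the vitreous).
#' @export
offset_um_to_px <- function(offset_um, axial_pixel_depth_um = 4.37) {
  stopifnot_scalar(axial_pixel_depth_um, "axial_pixel_depth_um", min = 1e-9)
  px_real <- offset_um / axial_pixel_depth_um
  px <- round(px_real)
  if (any(abs(px_real - px) > 0.01))
    stop(sprintf(
      "offset %g um is not a whole number of %g um pixels (residual %.4f px); check units",
      offset_um[which.max(abs(px_real - px))], axial_pixel_depth_um,
      max(abs(px_real - px))), call. = FALSE)
  as.integer(px)
}

#' A slab boundary: reference junction plus pixel offset
#'
#' @param reference junction name (\code{"ILM"}, \code{"IPL_INL"},
#'   \code{"OPL_ONL"}).
#' @param offset_px signed whole-pixel offset; negative = above the junction
#'   (toward the vitreous).
#' @param axial_pixel_depth_um axial sampling used to derive
#'   \code{offset_um = offset_px * axial_pixel_depth_um}.
#' @return list of class \code{slab_boundary}.
#' @export
slab_boundary <- function(reference, offset_px = 0L,
                          axial_pixel_depth_um = 4.37) {
  reference <- match.arg(reference, JUNCTIONS)
  stopifnot_scalar(offset_px, "offset_px", integer = TRUE)
  structure(list(reference = reference, offset_px = as.integer(offset_px),
                 offset_um = offset_px * axial_pixel_depth_um),
            class = "slab_boundary")
}

#' @export
format.slab_boundary <- function(x, ...) {
  if (x$offset_px == 0L) return(sprintf("%s + 0", x$reference))
  sprintf("%s %+d px (%.2f um %s)", x$reference, x$offset_px,
          abs(x$offset_um), if (x$offset_px < 0) "above" else "below")
}

same_boundary <- function(a, b)
  a$reference == b$reference && a$offset_px == b$offset_px

#' A named, contiguous slab scheme
#'
#' An ordered set of slabs, each bounded by two \code{\link{slab_boundary}}
#' objects.  Validation enforces the scheme contract: the lower boundary of
#' slab k is the upper boundary of slab k+1 (contiguity), the first upper
#' boundary is the ILM, and the last lower boundary is the OPL/ONL junction,
#' so the slabs partition the inner-retinal band.
#'
#' @param name scheme name.
#' @param slabs named list; each element a list with fields \code{upper} and
#'   \code{lower} (\code{slab_boundary} objects).
#' @param validate enforce the contiguity/outer-boundary contract.
#' @return list of class \code{slab_scheme}.
#' @export
slab_scheme <- function(name, slabs, validate = TRUE) {
  if (is.null(names(slabs)) || any(names(slabs) == ""))
    stop("slabs must be named", call. = FALSE)
  for (s in slabs)
    if (!inherits(s$upper, "slab_boundary") || !inherits(s$lower, "slab_boundary"))
      stop("each slab needs 'upper' and 'lower' slab_boundary fields", call. = FALSE)
  if (validate) {
    k <- length(slabs)
    if (!same_boundary(slabs[[1]]$upper, slab_boundary("ILM", 0L)))
      stop("upper boundary of the first slab must be ILM + 0", call. = FALSE)
    if (!same_boundary(slabs[[k]]$lower, slab_boundary("OPL_ONL", 0L)))
      stop("lower boundary of the last slab must be OPL_ONL + 0", call. = FALSE)
    if (k > 1L) for (i in seq_len(k - 1L))
      if (!same_boundary(slabs[[i]]$lower, slabs[[i + 1L]]$upper))
        stop(sprintf("slabs '%s' and '%s' are not contiguous",
                     names(slabs)[i], names(slabs)[i + 1L]), call. = FALSE)
  }
  structure(list(name = name, slabs = slabs), class = "slab_scheme")
}

#' @export
print.slab_scheme <- function(x, ...) {
  cat(sprintf("Slab scheme '%s' (%d slabs)\n", x$name, length(x$slabs)))
  for (nm in names(x$slabs)) {
    s <- x$slabs[[nm]]
    last <- nm == names(x$slabs)[length(x$slabs)]
    cat(sprintf("  %-4s [%s, %s%s\n", nm, format(s$upper), format(s$lower),
                if (last) "]" else ")"))
  }
  invisible(x)
}

#' Recommended three-layer scheme for term-equivalent eyes
#'
#' The recommended offsets for eyes with a formed three-layered perifoveal
#' vasculature (around 40 weeks postmenstrual age): SCP from the vitreous/ILM
#' junction down to 8.74 um (2 px) above the IPL/INL junction; ICP from there
#' down to 34.96 um (8 px) above the OPL/ONL junction; DCP from there to the
#' OPL/ONL junction.  Referencing the ICP/DCP boundary to the OPL/ONL junction
#' (rather than IPL/INL) keeps anomalous INL flow in cystoid macular edema
#' assigned to the ICP, to which it is more connected.
#'
#' @param axial_pixel_depth_um axial sampling in um/px.
#' @return A \code{\link{slab_scheme}} named \code{"term"}.
#' @export
make_term_scheme <- function(axial_pixel_depth_um = 4.37) {
  b <- function(ref, px) slab_boundary(ref, px, axial_pixel_depth_um)
  slab_scheme("term", list(
    SCP = list(upper = b("ILM", 0L), lower = b("IPL_INL", -2L)),
    ICP = list(upper = b("IPL_INL", -2L), lower = b("OPL_ONL", -8L)),
    DCP = list(upper = b("OPL_ONL", -8L), lower = b("OPL_ONL", 0L))
  ))
}

#' Recommended two-layer scheme for eyes without secondary vasculature
#'
#' Before the intermediate and deep plexuses form (around 35 weeks
#' postmenstrual age) the vasculature is grouped into a superficial vascular
#' complex (SVC) above the IPL/INL junction and a deep vascular complex (DVC)
#' from the IPL/INL junction to the OPL/ONL junction.
#'
#' @param axial_pixel_depth_um axial sampling in um/px.
#' @return A \code{\link{slab_scheme}} named \code{"early"}.
#' @export
make_early_scheme <- function(axial_pixel_depth_um = 4.37) {
  b <- function(ref, px) slab_boundary(ref, px, axial_pixel_depth_um)
  slab_scheme("early", list(
    SVC = list(upper = b("ILM", 0L), lower = b("IPL_INL", 0L)),
    DVC = list(upper = b("IPL_INL", 0L), lower = b("OPL_ONL", 0L))
  ))
}

#' Read a slab scheme from YAML
#'
#' Format: a mapping slab name -> \code{{upper: {ref, px}, lower: {ref, px}}},
#' in vitreous-to-choroid order.
#'
#' @param path YAML file.
#' @param axial_pixel_depth_um axial sampling for the derived um offsets.
#' @param validate enforce the contiguity contract (see \code{\link{slab_scheme}}).
#' @return A \code{\link{slab_scheme}}.
#' @export
read_scheme_yaml <- function(path, axial_pixel_depth_um = 4.37, validate = TRUE) {
  y <- yaml::read_yaml(path)
  slabs <- lapply(y, function(s) list(
    upper = slab_boundary(s$upper$ref, as.integer(s$upper$px), axial_pixel_depth_um),
    lower = slab_boundary(s$lower$ref, as.integer(s$lower$px), axial_pixel_depth_um)))
  slab_scheme(tools::file_path_sans_ext(basename(path)), slabs, validate = validate)
}

#' Resolve a scheme into per-slab depth surfaces
#'
#' Adds each boundary's pixel offset to its reference junction surface.
#' Wherever the resulting upper surface is at or below the lower one (thin
#' retina, e.g. toward the foveal pit), the slab is locally empty — never
#' inverted; the empty fraction per slab is reported in
#' \code{attr(, "empty_fraction")}.
#'
#' @param scheme a \code{\link{slab_scheme}}.
#' @param boundaries a \code{\link{boundary_set}} providing every referenced
#'   junction.
#' @return Named list (one element per slab) of lists with \code{upper} and
#'   \code{lower} (bscan x ascan) depth matrices; class \code{slab_surfaces}.
#' @export
resolve_surfaces <- function(scheme, boundaries) {
  stopifnot(inherits(scheme, "slab_scheme"), inherits(boundaries, "boundary_set"))
  g <- boundaries$geometry
  out <- list()
  empty_frac <- numeric(0)
  for (nm in names(scheme$slabs)) {
    s <- scheme$slabs[[nm]]
    for (side in c("upper", "lower"))
      if (is.null(boundaries$surfaces[[s[[side]]$reference]]))
        stop(sprintf("boundary set lacks junction '%s' needed by slab '%s'",
                     s[[side]]$reference, nm), call. = FALSE)
    up <- boundaries$surfaces[[s$upper$reference]] + s$upper$offset_px
    lo <- boundaries$surfaces[[s$lower$reference]] + s$lower$offset_px
    up <- pmin(pmax(up, 0), g$n_depth - 1)
    lo <- pmin(pmax(lo, 0), g$n_depth - 1)
    empty_frac[nm] <- mean(round_half_up(up) >= round_half_up(lo))
    out[[nm]] <- list(upper = up, lower = lo)
  }
  structure(out, class = "slab_surfaces", empty_fraction = empty_frac,
            scheme = scheme$name)
}

#' Project a depth slab to an en face image
#'
#' For every lateral position, reduces the flow values over the voxel depth
#' interval \code{[round(upper), round(lower))} (half-up rounding; the
#' deepest slab of a scheme closes its outer boundary with
#' \code{lower_inclusive = TRUE}).  Empty columns project to 0.  Maximum
#' projection is the default, the prevailing convention for rendering
#' capillaries in en face OCT-A; \code{mean} and \code{sum} are selectable,
#' and \code{sum} makes a zero-offset scheme an exact partition of the
#' ILM->OPL/ONL band.
#'
#' @param flow a \code{\link{flow_volume}} or 3-D (bscan, depth, ascan) array.
#' @param upper,lower (bscan x ascan) depth matrices (0-based, fractional ok).
#' @param projection \code{"max"}, \code{"mean"} or \code{"sum"}.
#' @param lower_inclusive include the voxel at the rounded lower boundary.
#' @return (bscan x ascan) matrix of projected values.
#' @export
project_slab <- function(flow, upper, lower, projection = c("max", "mean", "sum"),
                         lower_inclusive = FALSE) {
  projection <- match.arg(projection)
  v <- if (inherits(flow, "flow_volume")) flow$flow else flow
  stopifnot(length(dim(v)) == 3L)
  nb <- dim(v)[1]; nz <- dim(v)[2]; nx <- dim(v)[3]
  stopifnot(identical(dim(upper), c(nb, nx)), identical(dim(lower), c(nb, nx)))
  out <- matrix(0, nb, nx)
  zi <- 0:(nz - 1)
  for (b in seq_len(nb)) {
    zu <- round_half_up(upper[b, ])
    zl <- round_half_up(lower[b, ]) + if (lower_inclusive) 1L else 0L
    zu <- pmax(zu, 0); zl <- pmin(zl, nz)
    mask <- outer(zi, zu, ">=") & outer(zi, zl, "<")
    f <- v[b, , ]
    cnt <- colSums(mask)
    if (projection == "sum") {
      out[b, ] <- colSums(f * mask)
    } else if (projection == "mean") {
      out[b, ] <- colSums(f * mask) / pmax(cnt, 1L)
    } else {
      f[!mask] <- -Inf
      mx <- apply(f, 2, max)
      mx[cnt == 0L] <- 0
      out[b, ] <- mx
    }
  }
  out
}

#' Project every slab of a scheme
#'
#' Convenience wrapper: resolves the scheme surfaces and projects each slab,
#' closing the deepest slab's outer boundary inclusively so the scheme covers
#' the ILM->OPL/ONL band exactly.
#'
#' @param flow a \code{\link{flow_volume}}.
#' @param boundaries a \code{\link{boundary_set}}.
#' @param scheme a \code{\link{slab_scheme}}.
#' @param projection passed to \code{\link{project_slab}}.
#' @return Named list of en face matrices, one per slab.
#' @export
project_scheme <- function(flow, boundaries, scheme, projection = "max") {
  surf <- resolve_surfaces(scheme, boundaries)
  k <- length(surf)
  out <- vector("list", k)
  names(out) <- names(surf)
  for (i in seq_len(k)) {
    out[[i]] <- project_slab(flow, surf[[i]]$upper, surf[[i]]$lower,
                             projection, lower_inclusive = (i == k))
    attr(out[[i]], "slab") <- names(surf)[i]
    attr(out[[i]], "scheme") <- scheme$name
  }
  out
}

#' Default ICP/DCP boundary candidates for the offset sweep
#'
#' The tested ICP/DCP boundary placements: 1 to 5 px (4.37-21.85 um) below
#' the IPL/INL junction, and 5 to 10 px (21.85-43.7 um) above the OPL/ONL
#' junction.
#'
#' @param axial_pixel_depth_um axial sampling in um/px.
#' @return list of \code{\link{slab_boundary}} objects (11 candidates).
#' @export
default_icp_dcp_specs <- function(axial_pixel_depth_um = 4.37) {
  c(lapply(1:5, function(px) slab_boundary("IPL_INL", px, axial_pixel_depth_um)),
    lapply(-(5:10), function(px) slab_boundary("OPL_ONL", px, axial_pixel_depth_um)))
}

#' Sweep slab offsets into a collage grid
#'
#' Projects the target slab for every combination of SCP/ICP boundary offset
#' (relative to the IPL/INL junction) and ICP/DCP boundary candidate, the
#' side-by-side juxtaposition used to pick offsets by grader consensus.  The
#' default ranges are SCP/ICP 0-4 px above IPL/INL and the 11 ICP/DCP
#' candidates of \code{\link{default_icp_dcp_specs}}, i.e. a 5 x 11 grid.
#'
#' @param flow a \code{\link{flow_volume}}.
#' @param boundaries a \code{\link{boundary_set}}.
#' @param scip_offsets_px SCP/ICP boundary offsets in px relative to IPL/INL
#'   (negative = above).
#' @param icp_dcp_specs list of \code{\link{slab_boundary}} candidates for the
#'   ICP/DCP boundary.
#' @param slab which slab to render: \code{"SCP"}, \code{"ICP"} or \code{"DCP"}.
#' @param projection passed to \code{\link{project_slab}}.
#' @param enhance optional \code{\link{enhance_params}}; when given, each cell
#'   is run through \code{\link{enhance_slab}}.
#' @return An \code{offset_sweep}: list with \code{cells} (row-major list of
#'   \code{image}, \code{scip_px}, \code{icp_dcp}, \code{label}), \code{n_row},
#'   \code{n_col}, \code{slab}.
#' @export
sweep_offsets <- function(flow, boundaries,
                          scip_offsets_px = -(0:4),
                          icp_dcp_specs = default_icp_dcp_specs(),
                          slab = c("ICP", "SCP", "DCP"),
                          projection = "max",
                          enhance = NULL) {
  slab <- match.arg(slab)
  if (length(scip_offsets_px) == 0L || length(icp_dcp_specs) == 0L)
    stop("offset ranges must be nonempty", call. = FALSE)
  g <- boundaries$geometry
  pd <- g$axial_pixel_depth_um
  cells <- vector("list", length(scip_offsets_px) * length(icp_dcp_specs))
  k <- 0L
  for (scip in scip_offsets_px) {
    for (spec in icp_dcp_specs) {
      upper <- switch(slab,
        SCP = slab_boundary("ILM", 0L, pd),
        ICP = slab_boundary("IPL_INL", as.integer(scip), pd),
        DCP = spec)
      lower <- switch(slab,
        SCP = slab_boundary("IPL_INL", as.integer(scip), pd),
        ICP = spec,
        DCP = slab_boundary("OPL_ONL", 0L, pd))
      up <- boundaries$surfaces[[upper$reference]] + upper$offset_px
      lo <- boundaries$surfaces[[lower$reference]] + lower$offset_px
      img <- project_slab(flow, up, lo, projection,
                          lower_inclusive = (slab == "DCP"))
      if (!is.null(enhance)) img <- enhance_slab(img, enhance)
      k <- k + 1L
      cells[[k]] <- list(
        image = img, scip_px = as.integer(scip), icp_dcp = spec,
        label = sprintf("SCP/ICP %+d px | ICP/DCP %s", scip, format(spec)))
    }
  }
  structure(list(cells = cells, n_row = length(scip_offsets_px),
                 n_col = length(icp_dcp_specs), slab = slab,
                 projection = projection),
            class = "offset_sweep")
}

#' @export
print.offset_sweep <- function(x, ...) {
  cat(sprintf("Offset sweep of %s slab: %d x %d = %d cells (%s projection)\n",
              x$slab, x$n_row, x$n_col, length(x$cells), x$projection))
  invisible(x)
}

#' Write an offset-sweep collage
#'
#' Tiles the sweep cells into a labelled montage (rows = SCP/ICP offsets,
#' columns = ICP/DCP candidates) and writes it as PNG.
#'
#' @param sweep an \code{offset_sweep} from \code{\link{sweep_offsets}}.
#' @param path destination .png file.
#' @param cell_px approximate rendered cell width in pixels.
#' @return \code{path}, invisibly.
#' @export
write_montage <- function(sweep, path, cell_px = 160L) {
  stopifnot(inherits(sweep, "offset_sweep"))
  nr <- sweep$n_row; nc <- sweep$n_col
  grDevices::png(path, width = nc * cell_px, height = nr * (cell_px + 16L))
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(nr, nc), mar = c(0.2, 0.2, 1.1, 0.2))
  for (cell in sweep$cells) {
    img <- clamp01(cell$image / max(cell$image, 1e-12))
    graphics::plot(c(0, 1), c(0, 1), type = "n", axes = FALSE,
                   xlab = "", ylab = "", main = cell$label, cex.main = 0.7)
    graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1,
                          interpolate = FALSE)
  }
  invisible(path)
}
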