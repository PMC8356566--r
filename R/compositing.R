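# Blend-mode compositing of enhanced slabs into a colored overlay.
# All blend operations are element-wise, shape-, range- and
# determinism-preserving.

#' Default plexus colors
#'
#' Pure yellow, cyan and magenta for SCP, ICP and DCP; the two-layer scheme
#' reuses yellow (SVC) and magenta (DVC).
#' @export
PLEXUS_COLORS <- list(
  SCP = c(1, 1, 0), ICP = c(0, 1, 1), DCP = c(1, 0, 1),
  SVC = c(1, 1, 0), DVC = c(1, 0, 1))

check_gray <- function(img, arg) {
  if (!is.matrix(img) || any(img < 0) || any(img > 1) || anyNA(img))
    stop(sprintf("'%s' must be a matrix with values in [0, 1]", arg),
         call. = FALSE)
}

#' Subtract blend
#'
#' \code{clamp(base - layer, 0, 1)} element-wise — used to remove superficial
#' (SCP) shadow/projection artifacts from the ICP slab before coloring.
#'
#' @param base,layer matrices in [0, 1] with equal shape.
#' @return matrix in [0, 1].
#' @export
subtract_blend <- function(base, layer) {
  check_gray(base, "base"); check_gray(layer, "layer")
  if (!identical(dim(base), dim(layer)))
    stop("shape mismatch between base and layer", call. = FALSE)
  clamp01(base - layer)
}

#' Gradient map: grayscale to a black-to-color ramp
#'
#' Each output channel is \code{gray * color[channel]} — a linear ramp from
#' black to the endpoint color; display gamma is left to the viewer.
#'
#' @param gray matrix in [0, 1].
#' @param color length-3 RGB triple in [0, 1].
#' @return (rows x cols x 3) array in [0, 1].
#' @export
gradient_map <- function(gray, color) {
  check_gray(gray, "gray")
  if (length(color) != 3L || any(color < 0) || any(color > 1))
    stop("'color' must be an RGB triple in [0, 1]", call. = FALSE)
  out <- array(0, c(dim(gray), 3L))
  for (ch in 1:3) out[, , ch] <- gray * color[ch]
  out
}

#' Lighten blend
#'
#' Per-pixel, per-channel maximum across the input images (associative and
#' commutative), used to superimpose the colored slabs.
#'
#' @param images list of equally shaped RGB arrays (or a single array).
#' @return RGB array in [0, 1].
#' @export
lighten_blend <- function(images) {
  if (!is.list(images)) images <- list(images)
  if (length(images) == 0L) stop("empty image list", call. = FALSE)
  out <- images[[1]]
  for (img in images[-1]) {
    if (!identical(dim(img), dim(out)))
      stop("shape mismatch in lighten_blend", call. = FALSE)
    out <- pmax(out, img)
  }
  out
}

#' Three-color plexus overlay
#'
#' The display composite for the three-layer scheme: SCP shadows are removed
#' from the ICP slab with the subtract blend, the three slabs are gradient-
#' mapped to yellow (SCP), cyan (ICP) and magenta (DCP), and superimposed with
#' the lighten blend.  Shadow subtraction applies to the ICP only — DCP pixels
#' are never attenuated by the SCP.
#'
#' @param scp,icp,dcp enhanced en face slabs (matrices in [0, 1], same shape).
#' @param colors named list with SCP/ICP/DCP RGB triples.
#' @return (rows x cols x 3) RGB array of class \code{composite_image}, with
#'   the slab-to-color assignment in \code{attr(, "channels")}.
#' @export
compose_three_color <- function(scp, icp, dcp, colors = PLEXUS_COLORS) {
  icp_clean <- subtract_blend(icp, scp)
  out <- lighten_blend(list(gradient_map(scp, colors$SCP),
                            gradient_map(icp_clean, colors$ICP),
                            gradient_map(dcp, colors$DCP)))
  structure(out, class = "composite_image",
            channels = list(SCP = colors$SCP, ICP = colors$ICP,
                            DCP = colors$DCP))
}

#' Two-color complex overlay
#'
#' Composite for the two-layer (SVC/DVC) scheme used before the secondary
#' vasculature forms: gradient-mapped SVC and DVC superimposed with the
#' lighten blend.  No shadow subtraction is applied by default (the subtract
#' step is specific to the ICP); set \code{subtract_shadow = TRUE} to remove
#' SVC shadows from the DVC analogously.
#'
#' @param svc,dvc enhanced en face slabs (matrices in [0, 1], same shape).
#' @param colors named list with SVC/DVC RGB triples.
#' @param subtract_shadow remove SVC shadows from the DVC first.
#' @return RGB array of class \code{composite_image}.
#' @export
compose_two_color <- function(svc, dvc, colors = PLEXUS_COLORS,
                              subtract_shadow = FALSE) {
  if (subtract_shadow) dvc <- subtract_blend(dvc, svc)
  out <- lighten_blend(list(gradient_map(svc, colors$SVC),
                            gradient_map(dvc, colors$DVC)))
  structure(out, class = "composite_image",
            channels = list(SVC = colors$SVC, DVC = colors$DVC))
}

#' @export
print.composite_image <- function(x, ...) {
  ch <- attr(x, "channels")
  cat(sprintf("Composite overlay %d x %d; channels: %s\n",
              dim(x)[1], dim(x)[2],
              paste(sprintf("%s=(%s)", names(ch),
                            vapply(ch, function(c) paste(c, collapse = ","), "")),
                    collapse = " ")))
  invisible(x)
}
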