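# End-to-end orchestration: volume -> flow -> boundaries -> slabs ->
# enhancement -> composite (-> optional offset sweep), with provenance.

#' Default pipeline configuration
#'
#' Returns the full configuration list accepted by \code{\link{run_pipeline}},
#' with every field at its default.  Fields:
#' \describe{
#'   \item{input$volume}{\code{"phantom"} or a volume file path.}
#'   \item{input$layout}{axis order of a file volume (see \code{\link{load_volume}}).}
#'   \item{input$boundaries}{\code{"segment"} (run the baseline segmenter),
#'     \code{"truth"} (phantom ground truth) or a boundary file path.}
#'   \item{phantom}{\code{\link{phantom_config}} overrides (stage, seed, ...).}
#'   \item{processing}{\code{max_shift_px}, \code{mask_floor},
#'     \code{projection}, \code{smooth_window}.}
#'   \item{scheme}{\code{"term"}, \code{"early"}, or a scheme YAML path.}
#'   \item{enhance}{\code{\link{enhance_params}} overrides.}
#'   \item{sweep}{\code{enabled}, \code{slab} for the offset collage.}
#'   \item{output}{\code{save_volume} (write the raw acquisition),
#'     \code{bit_depth_raw} for raw slab TIFFs.}
#' }
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    input = list(volume = "phantom", layout = "rbza", boundaries = "segment",
                 corrections = NULL),
    phantom = list(stage = "term", seed = 1L),
    processing = list(max_shift_px = 3L, mask_floor = 0.05,
                      projection = "max", smooth_window = 5L),
    scheme = "term",
    enhance = list(),
    sweep = list(enabled = FALSE, slab = "ICP"),
    output = list(save_volume = FALSE, bit_depth_raw = 16L)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full slab-processing pipeline
#'
#' Executes, in order: volume acquisition (synthetic phantom or file), repeat
#' alignment, speckle-variance flow computation, low-signal masking, boundary
#' provision (baseline segmentation + median smoothing, phantom truth, or
#' file import, with optional corrections), slab scheme resolution, en face
#' projection, the enhancement chain, color compositing, and (optionally) the
#' offset-sweep collage.  Every artifact lands in \code{out_dir} together
#' with \code{provenance.json} recording the configuration, package version,
#' alignment shifts, per-slab empty fractions, raw-slab scales and the MD5 of
#' every written file.  All stages are deterministic given the configuration,
#' so a rerun reproduces byte-identical artifacts.
#'
#' @param config nested list (see \code{\link{default_pipeline_config}}) or a
#'   YAML file path; partial configs are merged over the defaults.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: \code{flow},
#'   \code{boundaries}, \code{slabs_raw}, \code{slabs_enhanced},
#'   \code{composite}, \code{truth} (phantom runs), \code{provenance}.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(package = "octaslabs",
               version = as.character(utils::packageVersion("octaslabs")),
               config = cfg)
  written <- character(0)
  fail <- function(stage, msg) stop(sprintf("[%s] %s", stage, msg), call. = FALSE)

  ## acquisition
  truth <- NULL
  if (identical(cfg$input$volume, "phantom")) {
    pcfg <- tryCatch(do.call(phantom_config, cfg$phantom),
                     error = function(e) fail("phantom", conditionMessage(e)))
    ph <- generate_phantom(pcfg)
    volume <- ph$volume; truth <- ph$truth
    if (isTRUE(cfg$output$save_volume)) {
      save_volume(volume, file.path(out_dir, "volume.h5"))
      written <- c(written, file.path(out_dir, "volume.h5"))
    }
  } else {
    volume <- tryCatch(load_volume(cfg$input$volume, cfg$input$layout),
                       error = function(e) fail("load", conditionMessage(e)))
    if (!is.null(cfg$phantom$seed)) set.seed(cfg$phantom$seed)
  }

  ## flow
  aligned <- align_repeats(volume, cfg$processing$max_shift_px)
  prov$alignment_shifts_range <- range(attr(aligned, "shifts"))
  flow <- speckle_variance(aligned)
  flow <- mask_low_signal(flow, aligned, cfg$processing$mask_floor)
  flow_path <- file.path(out_dir, "flow.h5")
  if (file.exists(flow_path)) unlink(flow_path)
  rhdf5::h5createFile(flow_path)
  rhdf5::h5createDataset(flow_path, "flow", dim(flow$flow),
                         storage.mode = "double", level = 0, chunk = NULL)
  rhdf5::h5write(flow$flow, flow_path, "flow")
  rhdf5::h5closeAll()
  written <- c(written, flow_path)

  ## boundaries
  bnd_src <- cfg$input$boundaries
  boundaries <- if (identical(bnd_src, "segment")) {
    b <- segment_boundaries(aligned)
    if (cfg$processing$smooth_window > 1L)
      b <- smooth_boundaries(b, cfg$processing$smooth_window)
    b
  } else if (identical(bnd_src, "truth")) {
    if (is.null(truth)) fail("boundaries", "'truth' boundaries need a phantom input")
    truth$boundaries
  } else {
    tryCatch(load_boundaries(bnd_src, volume$geometry),
             error = function(e) fail("boundaries", conditionMessage(e)))
  }
  if (!is.null(cfg$input$corrections)) {
    corr <- read_corrections_csv(cfg$input$corrections)
    boundaries <- apply_corrections(boundaries, corr)
    prov$correction_violations <- attr(boundaries, "violations")
  }
  bnd_path <- file.path(out_dir, "boundaries.csv")
  save_boundaries(boundaries, bnd_path)
  written <- c(written, bnd_path)

  ## scheme + slabs
  pd <- volume$geometry$axial_pixel_depth_um
  scheme <- switch(cfg$scheme,
                   term = make_term_scheme(pd),
                   early = make_early_scheme(pd),
                   tryCatch(read_scheme_yaml(cfg$scheme, pd),
                            error = function(e) fail("scheme", conditionMessage(e))))
  surf <- resolve_surfaces(scheme, boundaries)
  prov$empty_fraction <- as.list(attr(surf, "empty_fraction"))
  slabs_raw <- project_scheme(flow, boundaries, scheme, cfg$processing$projection)
  eparams <- do.call(enhance_params, cfg$enhance)
  slabs_enh <- lapply(slabs_raw, enhance_slab, params = eparams)
  prov$raw_slab_scale <- list()
  for (nm in names(slabs_raw)) {
    sc <- max(slabs_raw[[nm]], 1e-12)
    prov$raw_slab_scale[[nm]] <- sc
    p_raw <- file.path(out_dir, sprintf("slab_%s_raw.tif", nm))
    save_enface(slabs_raw[[nm]] / sc, p_raw,
                bit_depth = cfg$output$bit_depth_raw)
    p_enh <- file.path(out_dir, sprintf("slab_%s_enhanced.png", nm))
    save_enface(slabs_enh[[nm]], p_enh)
    written <- c(written, p_raw, p_enh)
  }

  ## composite
  nm <- names(slabs_enh)
  composite <- if (identical(nm, c("SCP", "ICP", "DCP"))) {
    compose_three_color(slabs_enh$SCP, slabs_enh$ICP, slabs_enh$DCP)
  } else if (identical(nm, c("SVC", "DVC"))) {
    compose_two_color(slabs_enh$SVC, slabs_enh$DVC)
  } else {
    warning("non-standard slab names; compositing first three slabs by lighten",
            call. = FALSE)
    lighten_blend(lapply(slabs_enh[seq_len(min(3, length(slabs_enh)))],
                         gradient_map, color = c(1, 1, 1)))
  }
  comp_path <- file.path(out_dir, "composite.png")
  save_enface(unclass(composite), comp_path)
  written <- c(written, comp_path)

  ## optional sweep collage
  if (isTRUE(cfg$sweep$enabled)) {
    sw <- sweep_offsets(flow, boundaries, slab = cfg$sweep$slab,
                        projection = cfg$processing$projection)
    collage_path <- file.path(out_dir, "sweep_collage.png")
    write_montage(sw, collage_path)
    written <- c(written, collage_path)
  }

  ## provenance
  if (!identical(cfg$input$volume, "phantom") && file.exists(cfg$input$volume))
    prov$input_md5 <- unname(tools::md5sum(cfg$input$volume))
  prov$outputs <- lapply(stats::setNames(written, basename(written)),
                         function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(flow = flow, boundaries = boundaries, scheme = scheme,
                 slabs_raw = slabs_raw, slabs_enhanced = slabs_enh,
                 composite = composite, truth = truth, provenance = prov))
}

#' Read boundary corrections from CSV
#'
#' Same table layout as \code{\link{load_boundaries}}
#' (\code{junction,bscan,ascan,depth_px}, 0-based indices); each junction's
#' rows must form a complete rectangular patch, which becomes one
#' \code{\link{boundary_correction}}.
#'
#' @param path CSV file.
#' @return list of \code{boundary_correction} objects.
#' @export
read_corrections_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(unique(tab$junction), function(j) {
    sub <- tab[tab$junction == j, ]
    bs <- sort(unique(sub$bscan)); as_ <- sort(unique(sub$ascan))
    if (nrow(sub) != length(bs) * length(as_))
      stop(sprintf("correction patch for '%s' is not a complete rectangle", j),
           call. = FALSE)
    m <- matrix(NA_real_, length(bs), length(as_))
    m[cbind(match(sub$bscan, bs), match(sub$ascan, as_))] <- sub$depth_px
    boundary_correction(j, bs + 1L, as_ + 1L, m)
  })
}
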