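test_that("micrometre offsets convert to the printed pixel counts", {
  expect_identical(offset_um_to_px(17.48, 4.37), 4L)
  expect_identical(offset_um_to_px(8.74, 4.37), 2L)
  expect_identical(offset_um_to_px(21.85, 4.37), 5L)
  expect_identical(offset_um_to_px(34.96, 4.37), 8L)
  expect_identical(offset_um_to_px(43.7, 4.37), 10L)
  expect_identical(offset_um_to_px(0, 4.37), 0L)
  expect_identical(offset_um_to_px(-17.48, 4.37), -4L)
  # a value that is not a whole pixel is a unit mix-up
  expect_error(offset_um_to_px(2, 4.37), "check units")
})

test_that("recommended schemes carry the published boundaries", {
  term <- make_term_scheme()
  expect_named(term$slabs, c("SCP", "ICP", "DCP"))
  expect_equal(term$slabs$SCP$lower$reference, "IPL_INL")
  expect_equal(term$slabs$SCP$lower$offset_px, -2L)
  expect_equal(term$slabs$SCP$lower$offset_um, -8.74)
  expect_equal(term$slabs$ICP$lower$reference, "OPL_ONL")
  expect_equal(term$slabs$ICP$lower$offset_px, -8L)
  expect_equal(term$slabs$ICP$lower$offset_um, -34.96)
  # contiguity: ICP.lower == DCP.upper etc.
  expect_equal(term$slabs$ICP$lower, term$slabs$DCP$upper)
  expect_equal(term$slabs$SCP$lower, term$slabs$ICP$upper)

  early <- make_early_scheme()
  expect_named(early$slabs, c("SVC", "DVC"))
  expect_equal(early$slabs$SVC$lower$reference, "IPL_INL")
  expect_equal(early$slabs$SVC$lower$offset_px, 0L)
  # union spans ILM -> OPL/ONL
  expect_equal(early$slabs$SVC$upper, slab_boundary("ILM", 0L))
  expect_equal(early$slabs$DVC$lower, slab_boundary("OPL_ONL", 0L))
  # the validator rejects non-contiguous schemes
  expect_error(slab_scheme("bad", list(
    A = list(upper = slab_boundary("ILM", 0L), lower = slab_boundary("IPL_INL", -2L)),
    B = list(upper = slab_boundary("IPL_INL", 0L), lower = slab_boundary("OPL_ONL", 0L))
  )), "not contiguous")
})

test_that("schemes round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "SCP: {upper: {ref: ILM, px: 0}, lower: {ref: IPL_INL, px: -2}}",
    "ICP: {upper: {ref: IPL_INL, px: -2}, lower: {ref: OPL_ONL, px: -8}}",
    "DCP: {upper: {ref: OPL_ONL, px: -8}, lower: {ref: OPL_ONL, px: 0}}"), f)
  sc <- read_scheme_yaml(f)
  expect_equal(sc$slabs, make_term_scheme()$slabs)
})

test_that("resolve_surfaces applies offsets and marks thin columns empty", {
  g <- acquisition_geometry(2, 4, 6, 100)
  b <- flat_boundaries(g, 10, 40, 60)
  surf0 <- resolve_surfaces(make_early_scheme(), b)
  expect_equal(surf0$SVC$upper, b$surfaces$ILM)     # zero offsets: = junctions
  expect_equal(surf0$SVC$lower, b$surfaces$IPL_INL)
  expect_true(all(attr(surf0, "empty_fraction") == 0))

  # an IPL_INL -> OPL_ONL gap of 6 px makes the term-scheme ICP locally empty
  b2 <- flat_boundaries(g, 10, 40, 60)
  b2$surfaces$IPL_INL[, 3] <- 54  # gap of 6 px < 2 + 8 px of offsets
  surf <- resolve_surfaces(make_term_scheme(), b2)
  expect_true(all(surf$ICP$upper[, 3] >= surf$ICP$lower[, 3]))
  expect_equal(unname(attr(surf, "empty_fraction")["ICP"]), 4 / 24)
  # flat junctions give constant-depth surfaces
  expect_equal(diff(range(surf$DCP$lower)), 0)
})

test_that("projection matches trivial cases and the brute-force oracle", {
  g <- acquisition_geometry(2, 3, 8, 20)
  b <- flat_boundaries(g, 2, 10, 16)
  cflow <- flow_volume(array(0.7, c(3, 20, 8)), g)
  img <- project_slab(cflow, b$surfaces$ILM, b$surfaces$OPL_ONL, "max")
  expect_true(all(img == 0.7))
  # single bright voxel -> lateral delta
  fl <- array(0, c(3, 20, 8)); fl[2, 12, 5] <- 3
  img <- project_slab(flow_volume(fl, g), b$surfaces$IPL_INL, b$surfaces$OPL_ONL, "max")
  expect_equal(img[2, 5], 3)
  expect_equal(sum(img != 0), 1L)

  # brute-force agreement across projections, offsets and inclusivity
  for (seed in 1:8) {
    set.seed(seed)
    fl <- array(runif(3 * 20 * 8), c(3, 20, 8))
    up <- matrix(runif(24, 0, 9), 3, 8)
    lo <- up + matrix(runif(24, -2, 8), 3, 8)  # includes empty columns
    lo <- pmin(lo, 19)
    for (proj in c("max", "mean", "sum")) for (incl in c(FALSE, TRUE)) {
      expect_equal(project_slab(fl, up, lo, proj, incl),
                   brute_project(fl, up, lo, proj, incl), tolerance = 1e-10)
    }
  }
})

test_that("zero-offset sum projection partitions the inner-retinal band", {
  for (seed in 1:20) {
    set.seed(seed)
    g <- acquisition_geometry(2, 4, 6, 30)
    b <- flat_boundaries(g,
                         ilm = runif(1, 1, 6),
                         ipl = runif(1, 10, 16),
                         opl = runif(1, 20, 27))
    b$surfaces$IPL_INL <- b$surfaces$IPL_INL +
      matrix(runif(24, -2, 2), 4, 6)  # wobble one junction
    b <- boundary_set(b$surfaces, g, enforce_order = TRUE)
    fl <- flow_volume(array(runif(4 * 30 * 6), c(4, 30, 6)), g)
    slabs <- project_scheme(fl, b, make_early_scheme(), projection = "sum")
    whole <- project_slab(fl, b$surfaces$ILM, b$surfaces$OPL_ONL, "sum",
                          lower_inclusive = TRUE)
    expect_equal(Reduce(`+`, slabs), whole, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("raising the SCP/ICP boundary never thins the ICP", {
  ph <- term_phantom()
  b <- ph$truth$boundaries
  thickness <- function(scip_px) {
    up <- b$surfaces$IPL_INL + scip_px
    lo <- b$surfaces$OPL_ONL - 8
    pmax(floor(lo + 0.5) - floor(up + 0.5), 0)
  }
  t0 <- thickness(0); t2 <- thickness(-2); t4 <- thickness(-4)
  expect_true(all(t2 >= t0))
  expect_true(all(t4 >= t2))
})

test_that("offset sweep produces the documented grid", {
  ph <- term_phantom()
  fl <- speckle_variance(ph$volume)
  b <- ph$truth$boundaries
  sw <- sweep_offsets(fl, b)
  # 5 SCP/ICP offsets x (5 IPL/INL + 6 OPL/ONL candidates) = 55 cells
  expect_equal(length(sw$cells), 55L)
  expect_equal(sw$n_row, 5L); expect_equal(sw$n_col, 11L)

  # single-element ranges reduce to one project_slab call
  one <- sweep_offsets(fl, b, scip_offsets_px = -2,
                       icp_dcp_specs = list(slab_boundary("OPL_ONL", -8L)))
  expect_equal(length(one$cells), 1L)
  direct <- project_slab(fl, b$surfaces$IPL_INL - 2, b$surfaces$OPL_ONL - 8, "max")
  expect_equal(one$cells[[1]]$image, direct)

  # swapping the scip range order permutes grid rows only
  sw2 <- sweep_offsets(fl, b, scip_offsets_px = c(-1, 0),
                       icp_dcp_specs = list(slab_boundary("OPL_ONL", -8L),
                                            slab_boundary("IPL_INL", 2L)))
  sw3 <- sweep_offsets(fl, b, scip_offsets_px = c(0, -1),
                       icp_dcp_specs = list(slab_boundary("OPL_ONL", -8L),
                                            slab_boundary("IPL_INL", 2L)))
  expect_equal(sw2$cells[[1]]$image, sw3$cells[[3]]$image)
  expect_equal(sw2$cells[[2]]$image, sw3$cells[[4]]$image)
  expect_error(sweep_offsets(fl, b, scip_offsets_px = integer(0)), "nonempty")
})
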