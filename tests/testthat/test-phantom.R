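test_that("phantom generation is fully reproducible from its seed", {
  cfg <- phantom_config(seed = 21, n_bscans = 16L, n_ascans = 48L, depth_px = 120L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(a$truth$vessel_labels, b$truth$vessel_labels)
  expect_identical(a$truth$boundaries$surfaces, b$truth$boundaries$surfaces)
})

test_that("phantom truth respects its anatomical invariants", {
  ph <- term_phantom()
  lbl <- ph$truth$vessel_labels
  tb <- ph$truth$boundaries$surfaces
  idx <- which(lbl > 0L, arr.ind = TRUE)
  z0 <- idx[, 2] - 1
  flat <- cbind(idx[, 1], idx[, 3])
  plex <- lbl[idx]
  # SCP voxels lie in [ILM, IPL_INL)
  expect_true(all(z0[plex == 1L] >= tb$ILM[flat[plex == 1L, ]] - 0.5))
  expect_true(all(z0[plex == 1L] < tb$IPL_INL[flat[plex == 1L, ]]))
  # ICP voxels hug the inner INL stratum just below the IPL/INL junction
  d_icp <- z0[plex == 2L] - tb$IPL_INL[flat[plex == 2L, ]]
  expect_true(all(abs(d_icp - 2) <= 2.5))
  # DCP voxels sit in the band above the OPL/ONL junction
  d_dcp <- z0[plex == 3L] - tb$OPL_ONL[flat[plex == 3L, ]]
  expect_true(all(d_dcp >= -8.5 & d_dcp <= 0.5))
})

test_that("early-stage phantom has no secondary plexuses", {
  ph <- early_phantom()
  expect_false(any(ph$truth$vessel_labels %in% c(2L, 3L)))
  expect_gt(sum(ph$truth$vessel_labels == 1L), 0)
  # configuration invariant: early forces the tube counts to zero
  cfg <- phantom_config(stage = "early", n_icp = 9L, n_dcp = 9L)
  expect_equal(cfg$n_icp, 0L); expect_equal(cfg$n_dcp, 0L)
})

test_that("vessel flow dominates background variance when flow is on, not when off", {
  ph <- term_phantom()
  fl <- speckle_variance(ph$volume)$flow
  m <- colMeans(ph$volume$intensities, dims = 1)
  nv <- fl / pmax(m^2, 1e-6)  # normalized: multiplicative speckle is intensity-scaled
  vessel <- ph$truth$vessel_labels > 0L
  retina <- m > 0.3  # compare against signal-bearing background
  bg <- retina & !vessel
  expect_gt(sum(vessel), 1e4)
  # stochastic dominance at flow_amplitude > 0
  expect_gt(median(nv[vessel]), 10 * median(nv[bg]))
  w <- wilcox.test(sample(nv[vessel], 4000), sample(nv[bg], 4000),
                   alternative = "greater")
  expect_lt(w$p.value, 1e-10)

  # with flow amplitude 0, vessel and background normalized variance match
  ph0 <- generate_phantom(phantom_config(seed = 11, flow_amplitude = 0))
  fl0 <- speckle_variance(ph0$volume)$flow
  m0 <- colMeans(ph0$volume$intensities, dims = 1)
  nv0 <- fl0 / pmax(m0^2, 1e-6)
  v0 <- ph0$truth$vessel_labels > 0L
  bg0 <- (m0 > 0.3) & !v0
  set.seed(99)
  ks <- suppressWarnings(ks.test(sample(nv0[v0], 2000), sample(nv0[bg0], 2000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("slab assignment scoring matches constructed ground truth", {
  g <- acquisition_geometry(2, 4, 8, 100)
  b <- flat_boundaries(g, 10, 40, 60)
  surf <- resolve_surfaces(make_term_scheme(), b)
  mk_truth <- function(coords_by_plexus) {
    lbl <- array(0L, c(4, 100, 8))
    for (p in seq_along(coords_by_plexus))
      for (co in coords_by_plexus[[p]]) lbl[co[1], co[2] + 1L, co[3]] <- p
    attr(lbl, "plexus") <- c("SCP", "ICP", "DCP")
    structure(list(boundaries = b, vessel_labels = lbl,
                   cyst_mask = array(FALSE, c(4, 100, 8))),
              class = "phantom_truth")
  }
  # voxels placed exactly inside each term-scheme interval: 100% recall
  truth <- mk_truth(list(list(c(1, 20, 3), c(2, 12, 5)),   # SCP in [10, 38)
                         list(c(1, 45, 2)),                 # ICP in [38, 52)
                         list(c(3, 55, 7), c(4, 60, 1))))   # DCP in [52, 60]
  ev <- evaluate_slab_assignment(truth, surf)
  expect_equal(unname(ev$recall), c(1, 1, 1))
  expect_equal(ev$n, 5L)

  # DCP 4 px deeper than the scheme expects: recall drops, voxels land outside
  truth2 <- mk_truth(list(list(), list(), list(c(3, 62, 7), c(4, 63, 1))))
  ev2 <- evaluate_slab_assignment(truth2, surf)
  expect_equal(unname(ev2$recall["DCP"]), 0)
  expect_equal(unname(ev2$table["DCP", "outside"]), 2)

  # empty truth: empty table
  ev3 <- evaluate_slab_assignment(mk_truth(list(list(), list(), list())), surf)
  expect_equal(ev3$n, 0L)
  expect_equal(nrow(ev3$table), 0L)
})

test_that("edema mode carves dark cysts inside the INL", {
  cfg <- phantom_config(seed = 13, edema = TRUE)
  ph <- generate_phantom(cfg)
  expect_gt(sum(ph$truth$cyst_mask), 100)
  idx <- which(ph$truth$cyst_mask, arr.ind = TRUE)
  z0 <- idx[, 2] - 1
  flat <- cbind(idx[, 1], idx[, 3])
  tb <- ph$truth$boundaries$surfaces
  # cysts confined to the INL band (between IPL/INL and OPL/ONL)
  expect_true(all(z0 >= tb$IPL_INL[flat] - 1))
  expect_true(all(z0 <= tb$OPL_ONL[flat] + 1))
  # cyst cores are darker than the surrounding INL
  m <- colMeans(ph$volume$intensities, dims = 1)
  ph_clean <- generate_phantom(phantom_config(seed = 13, edema = FALSE))
  m_clean <- colMeans(ph_clean$volume$intensities, dims = 1)
  expect_lt(mean(m[ph$truth$cyst_mask]), 0.6 * mean(m_clean[ph$truth$cyst_mask]))
})

test_that("end-to-end: flow + segmentation + term scheme recover the plexuses", {
  ph <- term_phantom()
  b <- smooth_boundaries(segment_boundaries(ph$volume), 5)
  surf <- resolve_surfaces(make_term_scheme(), b)
  ev <- evaluate_slab_assignment(ph$truth, surf)
  expect_true(all(ev$recall >= 0.9))
})
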