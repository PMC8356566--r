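rms <- function(a, b) sqrt(mean((a - b)^2))

test_that("segmentation recovers phantom boundaries within tolerance", {
  # noise-free: within 1 px RMS
  ph0 <- generate_phantom(phantom_config(seed = 5, speckle_sigma = 0,
                                         flow_amplitude = 0))
  b0 <- segment_boundaries(ph0$volume)
  for (j in names(b0$surfaces))
    expect_lt(rms(b0$surfaces[[j]], ph0$truth$boundaries$surfaces[[j]]), 1)
  # speckle at ~10% of layer contrast: within 2 px RMS
  ph1 <- generate_phantom(phantom_config(seed = 5, speckle_sigma = 0.10))
  b1 <- segment_boundaries(ph1$volume)
  for (j in names(b1$surfaces))
    expect_lt(rms(b1$surfaces[[j]], ph1$truth$boundaries$surfaces[[j]]), 2)
})

test_that("segmentation is deterministic and error shrinks with noise", {
  ph <- generate_phantom(phantom_config(seed = 8, n_bscans = 16L,
                                        n_ascans = 48L, depth_px = 120L))
  b1 <- segment_boundaries(ph$volume)
  b2 <- segment_boundaries(ph$volume)
  expect_identical(b1$surfaces, b2$surfaces)
  # boundary RMS error is monotone non-increasing as speckle noise decreases
  errs <- vapply(c(0.12, 0.05, 0), function(sig) {
    p <- generate_phantom(phantom_config(seed = 8, n_bscans = 16L,
                                         n_ascans = 48L, depth_px = 120L,
                                         speckle_sigma = sig))
    b <- segment_boundaries(p$volume)
    rms(b$surfaces$IPL_INL, p$truth$boundaries$surfaces$IPL_INL)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0.02))  # non-increasing up to sub-pixel jitter
})

test_that("uniform volume yields flat surfaces with a warning", {
  g <- acquisition_geometry(2, 4, 10, 60)
  vol <- acquisition_volume(array(0.5, c(2, 4, 60, 10)), g)
  expect_warning(b <- segment_boundaries(vol), "degenerate")
  for (s in b$surfaces) expect_equal(diff(range(s)), 0)
  # order invariant holds even in the degenerate case
  expect_true(all(b$surfaces$ILM <= b$surfaces$IPL_INL))
  expect_true(all(b$surfaces$IPL_INL <= b$surfaces$OPL_ONL))
})

test_that("corrections splice in, clip to neighbours, and log violations", {
  g <- acquisition_geometry(2, 6, 10, 100)
  b <- flat_boundaries(g, 10, 40, 60)
  expect_identical(apply_corrections(b, list()), b)

  # a correction pushing IPL_INL below OPL_ONL in 3 columns is clipped there
  corr <- boundary_correction("IPL_INL", bscans = 2, ascans = 4:6, depth_px = 75)
  expect_message(b2 <- apply_corrections(b, list(corr), margin = 0),
                 "clipped 3 position")
  expect_equal(attr(b2, "violations"), 3L)
  expect_true(all(b2$surfaces$IPL_INL[2, 4:6] == 60))  # clipped to OPL_ONL
  expect_true(all(b2$surfaces$IPL_INL[-2, ] == 40))    # rest untouched

  # full-surface replacement equals the replacement (after clipping)
  repl <- matrix(45, g$n_bscans, g$n_ascans)
  corr_full <- boundary_correction("IPL_INL", 1:g$n_bscans, 1:g$n_ascans, 45)
  b3 <- apply_corrections(b, list(corr_full), margin = 2)
  expect_equal(b3$surfaces$IPL_INL, repl)
})

test_that("correction cross-fade blends linearly over the margin", {
  g <- acquisition_geometry(2, 4, 20, 100)
  b <- flat_boundaries(g, 10, 40, 60)
  corr <- boundary_correction("IPL_INL", bscans = 1:4, ascans = 6:15, depth_px = 50)
  b2 <- apply_corrections(b, list(corr), margin = 2)
  s <- b2$surfaces$IPL_INL[1, ]
  expect_equal(s[5], 40)                     # outside the patch
  expect_equal(s[8:13], rep(50, 6))          # patch interior fully replaced
  expect_true(s[6] > 40 && s[6] < s[7] && s[7] < 50)  # linear ramp inward
})

test_that("median smoothing removes spikes and preserves smooth planes", {
  g <- acquisition_geometry(2, 8, 12, 100)
  b <- flat_boundaries(g, 10, 40, 60)
  expect_equal(smooth_boundaries(b, 1)$surfaces, b$surfaces)
  # single-column spike of +20 px is removed by a 5x5 median
  spiked <- b
  spiked$surfaces$IPL_INL[4, 6] <- 60
  sm <- smooth_boundaries(spiked, 5)
  expect_equal(sm$surfaces$IPL_INL, b$surfaces$IPL_INL)
  # an already-smooth tilted plane is unchanged away from edges
  plane <- outer(seq(20, 27, length.out = 8), rep(1, 12))
  bp <- boundary_set(list(ILM = plane), g)
  smp <- smooth_boundaries(bp, 3)
  expect_equal(smp$surfaces$ILM[2:7, ], plane[2:7, ])
  expect_error(smooth_boundaries(b, 4), "odd")
})

test_that("every boundary operation preserves the non-crossing order", {
  ph <- generate_phantom(phantom_config(seed = 10, n_bscans = 12L,
                                        n_ascans = 32L, depth_px = 120L))
  b <- segment_boundaries(ph$volume)
  check_order <- function(bs) {
    expect_true(all(bs$surfaces$ILM <= bs$surfaces$IPL_INL + 1e-9))
    expect_true(all(bs$surfaces$IPL_INL <= bs$surfaces$OPL_ONL + 1e-9))
  }
  check_order(b)
  check_order(smooth_boundaries(b, 5))
  corr <- boundary_correction("OPL_ONL", 1:3, 1:5, depth_px = 1)  # above ILM
  suppressMessages(check_order(apply_corrections(b, list(corr), margin = 0)))
})
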