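test_that("HDF5 volume round-trip is bit-identical and layouts canonicalize", {
  vol <- random_volume(1, nr = 4L, nb = 8L, nz = 32L, nx = 16L)
  f <- withr::local_tempfile(fileext = ".h5")
  save_volume(vol, f)
  back <- load_volume(f)
  expect_identical(back$intensities, vol$intensities)
  expect_equal(back$geometry, vol$geometry)

  # same voxels stored depth-last ("rbaz") load to the identical canonical array
  f2 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f2)
  rhdf5::h5write(aperm(vol$intensities, c(1, 2, 4, 3)), f2, "volume")
  rhdf5::h5closeAll()
  back2 <- load_volume(f2, layout = "rbaz")
  expect_identical(back2$intensities, vol$intensities)
  # canonicalization is a pure permutation: voxel multiset unchanged
  expect_equal(sort(as.vector(back2$intensities)), sort(as.vector(vol$intensities)))
})

test_that("multi-page TIFF volume round-trips within 16-bit quantization", {
  vol <- random_volume(2, nr = 3L, nb = 4L, nz = 16L, nx = 8L)
  f <- withr::local_tempfile(fileext = ".tif")
  save_volume(vol, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- load_volume(f)
  expect_equal(back$intensities, vol$intensities,
               tolerance = 1 / 65535 * max(vol$intensities) * 2)
  expect_error(load_volume(withr::local_tempfile(fileext = ".tif")), "not found")
})

test_that("boundary tables round-trip losslessly, fractional depths included", {
  g <- acquisition_geometry(2, 3, 4, 40)
  b <- flat_boundaries(g, 5.25, 12.5, 20.125)
  b$surfaces$ILM[2, 3] <- 6.7071067811865  # irrational-ish fractional value
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    save_boundaries(b, f)
    back <- load_boundaries(f, g)
    expect_equal(back$surfaces, b$surfaces, tolerance = 1e-12)
  }
  # single-junction file
  b1 <- boundary_set(list(ILM = matrix(12.5, 3, 4)), g)
  f <- withr::local_tempfile(fileext = ".csv")
  save_boundaries(b1, f)
  back <- load_boundaries(f, g)
  expect_named(back$surfaces, "ILM")
  expect_true(all(back$surfaces$ILM == 12.5))
})

test_that("boundary loading rejects unknown junctions and bad indices", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("junction,bscan,ascan,depth_px", "FOO,0,0,3.5"), f)
  expect_error(load_boundaries(f), "unknown junction")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("junction,bscan,ascan,depth_px", "ILM,5,0,3.5"), f2)
  g <- acquisition_geometry(2, 2, 2, 10)
  expect_error(load_boundaries(f2, g), "out of range")
})

test_that("en face images quantize round-to-nearest at both bit depths", {
  # endpoints
  z <- matrix(0, 4, 5)
  f <- withr::local_tempfile(fileext = ".png")
  save_enface(z, f)
  expect_true(all(load_enface(f, as_integer = TRUE) == 0))
  save_enface(matrix(1, 4, 5), f)
  expect_true(all(load_enface(f, as_integer = TRUE) == 255))
  # mid-gray at 16 bit: round(0.5 * 65535) with half-up rule = 32768
  f16 <- withr::local_tempfile(fileext = ".tif")
  save_enface(matrix(0.5, 2, 2), f16, bit_depth = 16L)
  expect_true(all(load_enface(f16, as_integer = TRUE) == 32768))
  # random image: stored integers equal the round-half-up quantization oracle
  set.seed(42)
  img <- matrix(runif(60), 6, 10)
  save_enface(img, f16, bit_depth = 16L)
  expect_identical(as.vector(load_enface(f16, as_integer = TRUE)),
                   as.integer(floor(img * 65535 + 0.5)))
  # out-of-range pixels rejected
  expect_error(save_enface(matrix(1.2, 2, 2), f), "\\[0, 1\\]")
  expect_error(save_enface(matrix(-0.1, 2, 2), f), "\\[0, 1\\]")
})

test_that("acquisition containers validate shape, finiteness and geometry", {
  g <- acquisition_geometry(4, 2, 3, 5)
  expect_error(acquisition_geometry(1, 2, 3, 5), "n_repeats")
  a <- array(1, c(4, 2, 5, 3))
  expect_silent(acquisition_volume(a, g))
  expect_error(acquisition_volume(array(1, c(4, 2, 5, 4)), g), "shape")
  a[1] <- -1
  expect_error(acquisition_volume(a, g), "nonnegative")
  a[1] <- NaN
  expect_error(acquisition_volume(a, g), "non-finite")
})
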