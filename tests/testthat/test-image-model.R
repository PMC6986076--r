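test_that("per-slice normalization maps the observed range to [0, 255]", {
  s <- ImageStack(array(c(10, 60, 110, 35), c(2, 2, 1)))
  out <- voxels(normalizeSlicewise(s))[, , 1]
  expect_equal(out[1, 1], 0)       # min -> 0
  expect_equal(out[1, 2], 255)     # max -> 255
  expect_equal(out[2, 1], 128)     # midpoint 60 -> round(127.5) half-up
})

test_that("a constant slice normalizes to empty background", {
  s <- ImageStack(array(7, c(4, 4, 2)))
  expect_true(all(voxels(normalizeSlicewise(s)) == 0))
})

test_that("normalization cancels per-slice multiplicative drift", {
  withr::with_seed(1, {
    v <- array(sample(50:4000, 16 * 16 * 5, TRUE), c(16, 16, 5))
  })
  drift <- v
  m <- c(1, 0.9, 0.5, 1.7, 0.03)
  for (z in 1:5) drift[, , z] <- v[, , z] * m[z]
  n1 <- normalizeSlicewise(ImageStack(v))
  n2 <- normalizeSlicewise(ImageStack(drift))
  expect_identical(voxels(n1), voxels(n2))
  # halved second slice (photobleaching) normalizes identically
  v2 <- v[, , 1:2]
  v2[, , 2] <- v[, , 1] / 2
  nn <- voxels(normalizeSlicewise(ImageStack(v2)))
  expect_identical(nn[, , 1], nn[, , 2])
})

test_that("normalization is idempotent", {
  withr::with_seed(2, v <- array(sample(0:65535, 12 * 10 * 4, TRUE),
                                 c(12, 10, 4)))
  n1 <- normalizeSlicewise(ImageStack(v))
  n2 <- normalizeSlicewise(n1)
  expect_identical(voxels(n1), voxels(n2))
})

test_that("TIFF write/read round trip is voxel-exact at 8 and 16 bit", {
  cal <- Calibration(dx = 0.2, dy = 0.2, dz = 0.5, nucleusDiameter = 12,
                     fociDiameter = 1)
  for (depth in c(8, 16)) {
    withr::with_seed(depth, {
      v <- array(sample(0:(2^depth - 1), 9 * 7 * 3, TRUE), c(9, 7, 3))
    })
    st <- ImageStack(v, calibration = cal, bitDepth = depth)
    path <- tempfile(fileext = ".tif")
    writeStack(st, path, bitDepth = depth)
    back <- readStack(path)
    expect_identical(voxels(back), v + 0)
    expect_equal(calibration(back)@dx, 0.2)  # embedded calibration survives
    expect_equal(calibration(back)@dz, 0.5)
    unlink(path)
  }
})

test_that("a rendered scene survives a write/read round trip", {
  sp <- sceneSpec(dims = c(48L, 40L, 6L),
                  nuclei = data.frame(cx = 2, cy = 2.4, cz = 0.75,
                                      ax = 1.5, ay = 1.5, az = 1.2,
                                      intensity = 3000),
                  seed = 9L)
  sc <- renderScene(sp)
  path <- tempfile(fileext = ".tif")
  writeStack(sc$stack, path)
  expect_identical(voxels(readStack(path)), voxels(sc$stack))
  unlink(path)
})

test_that("single-page TIFF yields a one-slice stack with identical pixels", {
  withr::with_seed(3, img <- matrix(sample(0:255, 30, TRUE), 6, 5))
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(img / 255, path, bits.per.sample = 8)
  st <- readStack(path)
  expect_equal(dim(voxels(st)), c(6L, 5L, 1L))
  expect_identical(voxels(st)[, , 1], img + 0)
  unlink(path)
})

test_that("channel extraction from pages with samples picks one channel", {
  withr::with_seed(4, {
    pages <- lapply(1:4, function(i) array(sample(0:255, 5 * 5 * 3, TRUE),
                                           c(5, 5, 3)))
  })
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(pages, function(p) p / 255), path,
                  bits.per.sample = 8)
  st <- readStack(path, channel = 2)
  expect_equal(dim(voxels(st)), c(5L, 5L, 4L))
  expect_equal(st@channelCount, 3L)
  for (z in 1:4) expect_identical(voxels(st)[, , z], pages[[z]][, , 2] + 0)
  expect_error(readStack(path, channel = 5), "out of range")
  unlink(path)
})

test_that("page-interleaved multi-channel layouts need an explicit flag", {
  # pages encode (channel, slice) as value channel*10 + slice
  mk <- function(ch, z) matrix((ch * 10 + z) / 255, 4, 4)
  pathI <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(mk(1, 1), mk(2, 1), mk(1, 2), mk(2, 2)), pathI,
                  bits.per.sample = 8)
  stI <- readStack(pathI, channel = 2, layout = "interleaved", nChannels = 2)
  expect_equal(unique(as.vector(voxels(stI)[, , 1])), 21)
  expect_equal(unique(as.vector(voxels(stI)[, , 2])), 22)
  pathC <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(mk(1, 1), mk(1, 2), mk(2, 1), mk(2, 2)), pathC,
                  bits.per.sample = 8)
  stC <- readStack(pathC, channel = 2, layout = "channel-major",
                   nChannels = 2)
  expect_equal(unique(as.vector(voxels(stC)[, , 1])), 21)
  expect_error(readStack(pathI, channel = 2), "out of range|ambiguous")
  unlink(c(pathI, pathC))
})

test_that("PNG slice directories read in lexicographic order", {
  dir <- tempfile()
  dir.create(dir)
  withr::with_seed(5, v <- array(sample(0:255, 4 * 4 * 3, TRUE), c(4, 4, 3)))
  for (z in 1:3)
    png::writePNG(v[, , z] / 255, file.path(dir, sprintf("s%02d.png", z)))
  st <- readStack(dir)
  expect_identical(voxels(st), v + 0)
  unlink(dir, recursive = TRUE)
})

test_that("user calibration overrides file calibration with a warning", {
  st <- ImageStack(array(0:23, c(4, 3, 2)),
                   calibration = Calibration(dx = 0.1))
  path <- tempfile(fileext = ".tif")
  writeStack(st, path, bitDepth = 8)
  expect_warning(back <- readStack(path, calibration = Calibration(dx = 0.3,
                                                                   dy = 0.3)),
                 "overrides")
  expect_equal(calibration(back)@dx, 0.3)
  unlink(path)
})

test_that("unreadable input and invalid construction raise errors", {
  expect_error(readStack(tempfile(fileext = ".tif")), "cannot read")
  expect_error(ImageStack(array(-1, c(2, 2, 1))), "non-negative")
  expect_error(Calibration(dx = 0), "positive")
  expect_error(Calibration(nucleusDiameter = 1, fociDiameter = 2),
               "exceed")
})
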