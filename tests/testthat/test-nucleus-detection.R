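test_that("signal separation of an empty field is all zero after blur", {
  v <- array(5, c(32, 32, 3))  # constant slices: ALT yields no objects
  st <- normalizeSlicewise(ImageStack(v))
  p <- nucleusParams(Calibration(nucleusDiameter = 2, fociDiameter = 0.5))
  sep <- separateSignal(st, p)
  expect_true(all(voxels(sep) == 0))
})

test_that("Gaussian blur of a single object pixel conserves mass", {
  m <- matrix(0, 41, 41)
  m[21, 21] <- 255
  b <- EBImage::gblur(m, sigma = 2)
  expect_equal(sum(b), 255, tolerance = 1e-6)
})

test_that("z-projection honours the basal cutoff", {
  mask <- array(FALSE, c(10, 10, 8))
  mask[3:5, 3:5, 1:5] <- TRUE        # artifact confined to basal slices 1-5
  mask[7:9, 7:9, 6:8] <- TRUE        # real object above the cutoff
  fp <- projectNuclei(mask, basalCutoff = 5L)
  expect_false(any(fp[3:5, 3:5]))
  expect_true(all(fp[7:9, 7:9]))
  # cutoff 0 is the plain OR-projection
  fp0 <- projectNuclei(mask, 0L)
  expect_identical(fp0, apply(mask, c(1, 2), any))
  # an object spanning all slices projects to the union of its footprints
  sl <- array(FALSE, c(6, 6, 3))
  sl[1:2, 1:2, 1] <- TRUE; sl[2:3, 2:3, 2] <- TRUE; sl[3:4, 3:4, 3] <- TRUE
  expect_identical(projectNuclei(sl, 0L), apply(sl, c(1, 2), any))
  expect_error(projectNuclei(sl, 3L), "smaller than")
})

test_that("the tolerance watershed separates overlapping discs", {
  m <- discMask(40, 60, 20, 22, 10) | discMask(40, 60, 20, 38, 10)
  lab1 <- nucleiWatershed(m, tolerance = 1)
  expect_equal(max(lab1), 2L)
  expect_true(lab1[20, 22] != lab1[20, 38])
  expect_true(all(lab1[20, 22] > 0, lab1[20, 38] > 0))
  # union of labels is the input foreground; labels are disjoint by design
  expect_identical(lab1 > 0L, m)
  # tolerance above the disc radius merges the maxima
  expect_equal(max(nucleiWatershed(m, tolerance = 11)), 1L)
  # a single disc stays one label with its footprint intact
  d <- discMask(30, 30, 15, 15, 9)
  labd <- nucleiWatershed(d, tolerance = 2)
  expect_equal(max(labd), 1L)
  expect_identical(labd > 0L, d)
  # empty mask -> empty label map, no error
  expect_equal(max(nucleiWatershed(matrix(FALSE, 5, 5), 1)), 0L)
})

test_that("watershed label count is non-increasing in tolerance", {
  withr::with_seed(21, {
    m <- matrix(FALSE, 64, 64)
    for (i in 1:6) {
      cy <- sample(10:54, 1); cx <- sample(10:54, 1)
      m <- m | discMask(64, 64, cy, cx, sample(5:9, 1))
    }
  })
  counts <- vapply(c(0.5, 1, 2, 4, 8, 16),
                   function(tol) max(nucleiWatershed(m, tol)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("particle filtering enforces size, roundness and edge rules", {
  cal <- Calibration(nucleusDiameter = 4, fociDiameter = 0.5)
  # disc of radius 20 px: retained, circularity within the estimator band
  lab <- matrix(0L, 60, 60)
  lab[discMask(60, 60, 30, 30, 20)] <- 1L
  ns <- filterNuclei(lab, cal, nucleusParams(cal, areaMin = 1, areaMax = 50,
                                             roundnessMin = 0.3))
  expect_equal(nrow(nucleusROIs(ns)), 1L)
  circ <- nucleusROIs(ns)$circularity
  expect_gt(circ, 0.85)
  expect_lt(circ, 1.1)
  # border-touching region is discarded
  lab2 <- matrix(0L, 40, 40)
  lab2[discMask(40, 40, 3, 20, 8)] <- 1L   # crosses the top border
  lab2[discMask(40, 40, 25, 20, 8)] <- 2L
  ns2 <- filterNuclei(lab2, cal, nucleusParams(cal, areaMin = 0.5,
                                               areaMax = 50))
  expect_equal(nrow(nucleusROIs(ns2)), 1L)
  expect_equal(sum(ns2@labels > 0), sum(lab2 == 2L))
  # a 2-px speck falls below the area minimum
  lab3 <- matrix(0L, 20, 20)
  lab3[10, 10:11] <- 1L
  ns3 <- filterNuclei(lab3, cal, nucleusParams(cal))
  expect_equal(nrow(nucleusROIs(ns3)), 0L)
})

test_that("a single synthetic nucleus is recovered with an accurate footprint", {
  sc <- renderScene(fociFieldScene(0, seed = 314))
  st <- sc$stack
  norm <- normalizeSlicewise(st)
  p <- nucleusParams(calibration(st))
  sep <- separateSignal(norm, p)
  # separated stack: brighter inside the true footprint than outside
  fp <- truthFootprint(sc$truth)
  mid <- sc$truth@midsection
  sl <- voxels(sep)[, , mid]
  expect_gt(mean(sl[fp]), mean(sl[!fp]))
  # candidate-mask midsection overlaps the true cross-section well
  mask <- nucleusMask(sep, p)
  truthMid <- truthNucleusMask(sc$truth)[, , mid]
  jacc <- sum(mask[, , mid] & truthMid) / sum(mask[, , mid] | truthMid)
  expect_gte(jacc, 0.7)
  # full detection: exactly one ROI, centroid within 3 px of truth
  nuc <- filterNuclei(nucleiWatershed(projectNuclei(mask, p@basalCutoff),
                                      p@watershedTolerance),
                      calibration(st), p)
  rois <- nucleusROIs(nuc)
  expect_equal(nrow(rois), 1L)
  expect_lt(abs(rois$xUm - 11.2), 0.3)
  expect_lt(abs(rois$yUm - 11.2), 0.3)
})

test_that("two overlapping nuclei are separated into two ROIs", {
  sc <- renderScene(standardScenes(7)$twoOverlappingNuclei)
  # the projected true footprints overlap by construction
  expect_true(any(truthFootprint(sc$truth, 1) & truthFootprint(sc$truth, 2)))
  nuc <- detectNuclei(sc$stack)
  rois <- nucleusROIs(nuc)
  expect_equal(nrow(rois), 2L)
  expect_equal(sort(round(rois$xUm)), c(11, 24))
})
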