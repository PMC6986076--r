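smallCal <- Calibration(nucleusDiameter = 3, fociDiameter = 0.6)

test_that("a constant stack yields an empty foci mask", {
  st <- normalizeSlicewise(ImageStack(array(80, c(24, 24, 4)), smallCal))
  p <- fociParams(smallCal)
  expect_false(any(fociMask(st, p)))
})

test_that("one rendered focus becomes one 26-connected component", {
  sc <- renderScene(fociFieldScene(1, seed = 5))
  tr <- sc$truth@foci
  norm <- normalizeSlicewise(sc$stack)
  p <- fociParams(calibration(sc$stack))
  m <- fociMask(norm, p)
  lab <- labelFoci3D(m)
  sizes <- tabulate(lab[lab > 0])
  inRange <- which(sizes >= p@minFocusVoxels & sizes <= p@maxFocusVoxels)
  expect_length(inRange, 1L)
  # the component contains the voxel at the true focus centre
  ctr <- c(round(tr$y / 0.1), round(tr$x / 0.1), round(tr$z / 0.25))
  expect_equal(lab[ctr[1], ctr[2], ctr[3]], inRange)
  # a mild pre-blur does not change the component count on a clean focus
  p2 <- fociParams(calibration(sc$stack), preBlurSigma = 1)
  lab2 <- labelFoci3D(fociMask(norm, p2))
  sizes2 <- tabulate(lab2[lab2 > 0])
  expect_length(which(sizes2 >= p@minFocusVoxels &
                        sizes2 <= p@maxFocusVoxels), 1L)
})

test_that("3D maxima finder resolves separated peaks and respects tolerance", {
  # constant stack: no seeds at any tolerance
  expect_equal(nrow(findMaxima3D(array(30, c(10, 10, 5)), 0)), 0L)
  # two Gaussian peaks 3 sigma apart -> exactly two seeds near the centres
  dims <- c(40, 40, 16)
  g <- array(10, dims)
  centers <- list(c(14, 20, 8), c(26, 20, 8))   # 12 px apart, sigma 4 px
  for (cc in centers) {
    for (z in 1:16) {
      d2 <- outer((seq_len(40) - cc[1])^2, (seq_len(40) - cc[2])^2, "+") +
        ((z - cc[3]) * 2.5)^2
      g[, , z] <- g[, , z] + 200 * exp(-d2 / (2 * 16))
    }
  }
  g <- round(g)
  seeds <- findMaxima3D(g, tolerance = 10)
  expect_equal(nrow(seeds), 2L)
  for (cc in centers) {
    d <- sqrt((seeds[, 1] - cc[1])^2 + (seeds[, 2] - cc[2])^2 +
                (seeds[, 3] - cc[3])^2)
    expect_lte(min(d), sqrt(3))  # within one voxel
  }
  # tolerance above the peak height suppresses everything
  expect_equal(nrow(findMaxima3D(g, tolerance = 500)), 0L)
  # an intensity plateau yields a single centroid seed
  pl <- array(0, c(9, 9, 3))
  pl[4:6, 4:6, 2] <- 50
  s <- findMaxima3D(pl, tolerance = 5)
  expect_equal(nrow(s), 1L)
  expect_equal(unname(s[1, ]), c(5L, 5L, 2L))
})

test_that("the seeded 3D watershed partitions fused spheres", {
  cal <- Calibration()
  dims <- c(24L, 24L, 24L)
  m <- sphereMask(dims, c(12, 8, 12), 5) | sphereMask(dims, c(12, 16, 12), 5)
  expect_equal(max(labelFoci3D(m)), 1L)  # fused into one component
  seeds <- rbind(c(12, 8, 12), c(12, 16, 12))
  lab <- fociWatershed3D(m, seeds, cal)
  expect_equal(max(lab), 2L)
  expect_true(lab[12, 8, 12] != lab[12, 16, 12])
  # partition property: labels cover exactly the foreground, disjointly
  expect_identical(lab > 0L, m)
  # one component, one interior seed: label map equals the component
  s <- sphereMask(dims, c(12, 12, 12), 5)
  lab1 <- fociWatershed3D(s, matrix(c(12, 12, 12), 1), cal)
  expect_identical(lab1 == 1L, s)
  # zero seeds: the component is kept whole as one label
  lab0 <- fociWatershed3D(s, matrix(numeric(), 0, 3), cal)
  expect_identical(lab0 == 1L, s)
  # off-foreground seeds are dropped with a warning
  expect_warning(fociWatershed3D(s, rbind(c(1, 1, 1), c(12, 12, 12)), cal),
                 "dropped")
})

test_that("watershed seed containment holds on random blob masks", {
  cal <- Calibration()
  withr::with_seed(31, {
    for (rep in 1:3) {
      dims <- c(20L, 20L, 14L)
      m <- array(FALSE, dims)
      cent <- matrix(0, 3, 3)
      for (i in 1:3) {
        cent[i, ] <- c(sample(5:15, 1), sample(5:15, 1), sample(4:10, 1))
        m <- m | sphereMask(dims, cent[i, ], sample(3:5, 1))
      }
      lab <- fociWatershed3D(m, cent, cal)
      expect_identical(lab > 0L, m)
      lbl <- lab[cent]
      expect_true(all(lbl > 0))
      expect_equal(length(unique(lbl)), 3L)
    }
  })
})

test_that("focus measurements are calibrated (volume, surface, centroid)", {
  cal <- Calibration()  # 0.1 x 0.1 x 0.25 um voxels
  dims <- c(20L, 20L, 10L)
  mask <- array(FALSE, dims)
  mask[9:12, 9:12, 4:5] <- TRUE  # 4 x 4 x 2 voxel block
  lab2d <- matrix(1L, 20, 20)
  nuc <- new("NucleusSet", labels = lab2d,
             rois = data.frame(label = 1L, areaUm2 = 4, xUm = 1, yUm = 1,
                               circularity = 1, touchesEdge = FALSE),
             calibration = cal)
  norm <- ImageStack(array(100, dims), cal, bitDepth = 8)
  p <- fociParams(cal, minFocusVoxels = 2L)
  res <- countFoci(mask, nuc, norm, p)
  f <- fociTable(res)
  expect_equal(nrow(f), 1L)
  expect_equal(f$voxelCount, 32L)
  expect_equal(f$volumeUm3, 32 * 0.1 * 0.1 * 0.25)   # 0.08 um^3
  # exposed faces: 16 y-faces, 16 x-faces, 32 z-faces
  expect_equal(f$surfaceUm2, 16 * 0.1 * 0.25 + 16 * 0.1 * 0.25 + 32 * 0.01)
  expect_equal(f$xUm, (mean(9:12) - 0.5) * 0.1)
  expect_equal(f$zUm, (mean(4:5) - 0.5) * 0.25)
  # centroid lies inside the bounding box of the focus
  expect_true(f$xUm >= 8 * 0.1 && f$xUm <= 12 * 0.1)
  # a focus whose centroid lies outside every footprint is not reported
  lab0 <- matrix(0L, 20, 20)
  lab0[1:3, 1:3] <- 1L
  nuc0 <- new("NucleusSet", labels = lab0, rois = nucleusROIs(nuc),
              calibration = cal)
  res0 <- countFoci(mask, nuc0, norm, p)
  expect_equal(nrow(fociTable(res0)), 0L)
  expect_equal(fociCounts(res0)$fn3d, 0L)
})

test_that("the default midsection slice sits ~3 um above the glass", {
  expect_equal(midsectionSlice(0.25), 13L)   # 0-based index 12
  expect_equal(midsectionSlice(0.25) - 1L, as.integer(round(3 / 0.25)))
  expect_equal(midsectionSlice(0.5), 7L)
})

test_that("2D midsection counting finds exactly the in-plane foci", {
  mid <- midsectionSlice(0.25)
  zMid <- (mid - 0.5) * 0.25
  nuc <- data.frame(cx = 11.2, cy = 11.2, cz = 7.5, ax = 8, ay = 8,
                    az = 9.5, intensity = 3000)
  ang <- seq(0, 2 * pi, length.out = 6)[1:5]
  foci <- data.frame(x = 11.2 + 4 * cos(ang), y = 11.2 + 4 * sin(ang),
                     z = zMid, sigma = 0.2, peak = 13000, nucleus = 1L)
  sc <- renderScene(sceneSpec(nuclei = nuc, foci = foci, seed = 77L))
  norm <- normalizeSlicewise(sc$stack)
  nset <- truthNucleusSet(sc$truth)
  f2 <- countFoci2D(norm, nset)
  expect_equal(f2$fn2d, 5L)
  # an empty slice yields zero for every nucleus
  f2e <- countFoci2D(norm, nset, midsection = 1L)
  expect_equal(f2e$fn2d, 0L)
  # 3D count of the same scene sees all five as well: fn3d >= fn2d
  res <- countFoci(fociMask(norm), nset, norm)
  expect_equal(fociCounts(res)$fn3d, 5L)
  expect_gte(fociCounts(res)$fn3d, f2$fn2d)
})
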