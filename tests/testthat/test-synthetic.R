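tinyNucleus <- data.frame(cx = 2.4, cy = 2.4, cz = 1.5, ax = 1.8, ay = 1.8,
                          az = 1.6, intensity = 3000)

test_that("rendering is deterministic per seed", {
  sp <- sceneSpec(dims = c(48L, 48L, 12L), nuclei = tinyNucleus,
                  noiseSd = 3, seed = 11L)
  a <- renderScene(sp)$stack
  b <- renderScene(sp)$stack
  expect_identical(voxels(a), voxels(b))
  sp2 <- sp; sp2@seed <- 12L
  expect_false(identical(voxels(a), voxels(renderScene(sp2)$stack)))
})

test_that("ground truth mirrors the scene construction", {
  sp <- fociFieldScene(25, seed = 8)
  sc <- renderScene(sp)
  expect_equal(sc$truth@nuclei$fociCount, 25L)
  expect_equal(nrow(sc$truth@foci), 25L)
  expect_equal(sc$truth@midsection, 13L)
  # sampled centres respect the spacing constraint
  D <- as.matrix(dist(sp@foci[, c("x", "y", "z")]))
  diag(D) <- Inf
  expect_gte(min(D), 2)
})

test_that("rendering is additive and order-independent", {
  foci <- data.frame(x = c(2.0, 2.8, 2.4), y = c(2.2, 2.4, 2.8),
                     z = c(1.2, 1.8, 1.5), sigma = 0.2, peak = 13000,
                     nucleus = 1L)
  sp1 <- sceneSpec(dims = c(48L, 48L, 12L), nuclei = tinyNucleus,
                   foci = foci, seed = 3L)
  sp2 <- sceneSpec(dims = c(48L, 48L, 12L), nuclei = tinyNucleus,
                   foci = foci[c(3, 1, 2), ], seed = 3L)
  expect_identical(voxels(renderScene(sp1)$stack),
                   voxels(renderScene(sp2)$stack))
})

test_that("noiseless unbleached voxels equal the closed-form scene", {
  foci <- data.frame(x = 2.8, y = 2.0, z = 1.6, sigma = 0.2, peak = 13000,
                     nucleus = 1L)
  sp <- sceneSpec(dims = c(48L, 48L, 12L), nuclei = tinyNucleus,
                  foci = foci, seed = 4L)
  v <- voxels(renderScene(sp)$stack)
  withr::with_seed(5, {
    for (i in 1:60) {
      y <- sample(48, 1); x <- sample(48, 1); z <- sample(12, 1)
      expect_equal(v[y, x, z],
                   min(floor(sceneValueAt(sp, y, x, z) + 0.5), 65535))
    }
  })
})

test_that("the per-slice decay factor scales slices geometrically", {
  sp <- sceneSpec(dims = c(32L, 32L, 10L), nuclei = tinyNucleus[0, ],
                  background = 600, bleachRate = 0.98, seed = 6L)
  v <- voxels(renderScene(sp)$stack)
  for (z in 1:10)
    expect_equal(unique(as.vector(v[, , z])), round(600 * 0.98^(z - 1)))
})

test_that("scene validation rejects inconsistent specifications", {
  expect_error(renderScene(sceneSpec(
    dims = c(32L, 32L, 8L),
    nuclei = data.frame(cx = 1.6, cy = 1.6, cz = 1, ax = 1, ay = 1, az = 1,
                        intensity = 500))),  # dimmer than background
    "exceed")
  expect_error(sceneSpec(
    dims = c(32L, 32L, 8L), nuclei = tinyNucleus,
    foci = data.frame(x = 90, y = 1, z = 1, sigma = 0.2, peak = 1000,
                      nucleus = 0L)), "inside the imaged volume")
  expect_error(sceneSpec(
    dims = c(48L, 48L, 12L), nuclei = tinyNucleus,
    foci = data.frame(x = 4.7, y = 4.7, z = 2.9, sigma = 0.2, peak = 1000,
                      nucleus = 1L)), "outside its nucleus")
})

test_that("standard presets cover the documented regimes", {
  sc <- standardScenes(2)
  expect_named(sc, c("empty", "singleNucleus", "twoOverlappingNuclei",
                     "edgeClippedNucleus", "sparseFoci", "denseFoci",
                     "fusedPairs", "basalArtifact", "photobleached"))
  expect_equal(nrow(sc$empty@nuclei), 0L)
  expect_equal(nrow(sc$empty@foci), 0L)
  # dense regime: 150-250 foci in one nucleus
  expect_gte(nrow(sc$denseFoci@foci), 150L)
  expect_lte(nrow(sc$denseFoci@foci), 250L)
  # sparse regime: unirradiated background level
  expect_lte(nrow(sc$sparseFoci@foci), 15L)
  expect_equal(sc$photobleached@bleachRate, 0.98)
  expect_gte(sc$basalArtifact@basalArtifactSlices, 1L)
  # overlapping preset: projected footprints intersect
  tr <- renderScene(sc$twoOverlappingNuclei)$truth
  expect_true(any(truthFootprint(tr, 1) & truthFootprint(tr, 2)))
})
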