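#' Construct a synthetic-scene specification
#'
#' Builds a \code{\linkS4class{SceneSpec}} describing a ground-truthed
#' confocal scene: dimly autofluorescent ellipsoidal nuclei containing
#' bright 3D-Gaussian foci (isotropic in um, hence anisotropic in voxels)
#' over a flat background, with per-slice multiplicative signal decay,
#' Gaussian read noise, and an optional bright basal glass-surface artifact.
#'
#' Default intensities (arbitrary 16-bit units: background 600, nucleus
#' interior 3000, focus amplitude ~13000) emulate a high-signal-to-noise
#' confocal acquisition; the default rendering is noiseless, which after
#' per-slice 8-bit normalization makes every flat region quantize to a
#' single grey level — the regime in which the strict-inequality local
#' thresholding is exactly clean. The methods vignette explains why any
#' sub-quantization read noise interacts with the per-slice rescaling to
#' produce sporadic false positives, and what that implies for real data.
#'
#' @param dims integer \code{(ny, nx, nz)} voxel dimensions.
#' @param calibration a \code{\linkS4class{Calibration}}.
#' @param nuclei data.frame with um-valued \code{cx, cy, cz, ax, ay, az}
#'   and \code{intensity} (a.u.).
#' @param foci data.frame with um-valued \code{x, y, z}, \code{sigma},
#'   \code{peak} and parent \code{nucleus} index (0 = unparented).
#' @param background flat background intensity (a.u.).
#' @param noiseSd Gaussian read-noise sd (a.u.).
#' @param bleachRate per-slice multiplicative decay factor in (0, 1].
#' @param basalArtifactSlices basal slices carrying the artifact.
#' @param basalArtifactIntensity artifact peak intensity (a.u.).
#' @param textureAmp smooth interior-texture amplitude as a fraction of the
#'   interior excess (default 0; see the methods vignette for why).
#' @param seed RNG seed making the rendering deterministic.
#' @return a \code{SceneSpec}.
#' @export
sceneSpec <- function(dims = c(224L, 224L, 60L), calibration = Calibration(),
                      nuclei = .defaultNucleus(), foci = .emptySceneFoci(),
                      background = 600, noiseSd = 0, bleachRate = 1,
                      basalArtifactSlices = 0L, basalArtifactIntensity = 12000,
                      textureAmp = 0, seed = 1L) {
  new("SceneSpec", dims = as.integer(dims), calibration = calibration,
      nuclei = nuclei, foci = foci, background = background,
      noiseSd = noiseSd, bleachRate = bleachRate,
      basalArtifactSlices = as.integer(basalArtifactSlices),
      basalArtifactIntensity = basalArtifactIntensity,
      textureAmp = textureAmp, seed = as.integer(seed))
}

.defaultNucleus <- function(cx = 11.2, cy = 11.2, cz = 7.5,
                            ax = 8, ay = 8, az = 9.5, intensity = 3000) {
  data.frame(cx = cx, cy = cy, cz = cz, ax = ax, ay = ay, az = az,
             intensity = intensity)
}

.emptySceneFoci <- function() {
  data.frame(x = numeric(), y = numeric(), z = numeric(), sigma = numeric(),
             peak = numeric(), nucleus = integer())
}

#' Render a synthetic scene
#'
#' Renders the scene additively (permuting the foci list leaves the stack
#' unchanged), applies the per-slice decay factor to the fully formed slice,
#' adds the basal artifact and read noise, and quantizes to 16 bit. The
#' basal artifact is a set of fixed smooth bright bumps on the first
#' \code{basalArtifactSlices} slices, emulating imperfections on the glass
#' surface.
#'
#' @param spec a \code{\linkS4class{SceneSpec}}.
#' @return list with \code{stack} (16-bit \code{\linkS4class{ImageStack}})
#'   and \code{truth} (\code{\linkS4class{GroundTruth}}).
#' @examples
#' sc <- renderScene(sceneSpec(dims = c(64L, 64L, 8L),
#'   nuclei = data.frame(cx = 3.2, cy = 3.2, cz = 1, ax = 2.5, ay = 2.5,
#'                       az = 1.2, intensity = 3000)))
#' sc$stack
#' @export
renderScene <- function(spec) {
  validObject(spec)
  cal <- calibration(spec)
  d <- spec@dims
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  xs <- (seq_len(nx) - 0.5) * cal@dx
  ys <- (seq_len(ny) - 0.5) * cal@dy
  zs <- (seq_len(nz) - 0.5) * cal@dz
  img <- array(spec@background, c(ny, nx, nz))
  withr::with_seed(spec@seed, {
    for (i in seq_len(nrow(spec@nuclei))) {
      nn <- spec@nuclei[i, ]
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      excess <- nn$intensity - spec@background
      L <- max(nn$ax, nn$ay, nn$az)
      dx2 <- outer(((ys - nn$cy) / nn$ay)^2, ((xs - nn$cx) / nn$ax)^2, "+")
      for (z in seq_len(nz)) {
        rz <- 1 - ((zs[z] - nn$cz) / nn$az)^2
        if (rz <= 0) next
        inside <- dx2 <= rz
        if (!any(inside)) next
        add <- matrix(0, ny, nx)
        add[inside] <- excess
        if (spec@textureAmp > 0) {
          lin <- outer((ys - nn$cy) * u[1], (xs - nn$cx) * u[2], "+") +
            (zs[z] - nn$cz) * u[3]
          add[inside] <- add[inside] +
            spec@textureAmp * excess * (lin[inside] / L)
        }
        img[, , z] <- img[, , z] + add
      }
    }
    for (i in seq_len(nrow(spec@foci))) {
      fc <- spec@foci[i, ]
      img <- .addFocus(img, fc, xs, ys, zs)
    }
    if (spec@basalArtifactSlices > 0L) {
      pat <- .basalPattern(ny, nx, cal)
      for (z in seq_len(min(spec@basalArtifactSlices, nz)))
        img[, , z] <- img[, , z] + spec@basalArtifactIntensity * pat
    }
    if (spec@noiseSd > 0)
      img <- img + array(stats::rnorm(length(img), sd = spec@noiseSd), dim(img))
  })
  if (spec@bleachRate < 1) {
    for (z in seq_len(nz)) img[, , z] <- img[, , z] * spec@bleachRate^(z - 1)
  }
  img <- pmin(pmax(floor(img + 0.5), 0), 65535)
  stack <- ImageStack(img, calibration = cal, bitDepth = 16)
  counts <- if (nrow(spec@nuclei) > 0) {
    vapply(seq_len(nrow(spec@nuclei)),
           function(i) sum(spec@foci$nucleus == i), 0L)
  } else integer()
  nucTruth <- spec@nuclei
  if (nrow(nucTruth) > 0) nucTruth$fociCount <- counts
  truth <- new("GroundTruth", nuclei = nucTruth, foci = spec@foci,
               midsection = midsectionSlice(cal@dz), dims = d,
               calibration = cal)
  list(stack = stack, truth = truth)
}

# truncated (4 sigma) isotropic-in-um 3D Gaussian added in place
.addFocus <- function(img, fc, xs, ys, zs) {
  r <- 4 * fc$sigma
  yi <- which(abs(ys - fc$y) <= r)
  xi <- which(abs(xs - fc$x) <= r)
  zi <- which(abs(zs - fc$z) <= r)
  if (!length(yi) || !length(xi) || !length(zi)) return(img)
  dy2 <- (ys[yi] - fc$y)^2
  dx2 <- (xs[xi] - fc$x)^2
  lat <- outer(dy2, dx2, "+")
  for (z in zi) {
    d2 <- lat + (zs[z] - fc$z)^2
    g <- fc$peak * exp(-d2 / (2 * fc$sigma^2))
    g[d2 > r^2] <- 0
    img[yi, xi, z] <- img[yi, xi, z] + g
  }
  img
}

# three fixed smooth bumps (deterministic glass-surface imperfections)
.basalPattern <- function(ny, nx, cal) {
  xs <- seq_len(nx) / nx
  ys <- seq_len(ny) / ny
  centers <- rbind(c(0.80, 0.30), c(0.75, 0.72), c(0.90, 0.55))  # (x, y)
  sig <- 0.09
  pat <- matrix(0, ny, nx)
  for (k in seq_len(nrow(centers))) {
    pat <- pat + outer(exp(-(ys - centers[k, 2])^2 / (2 * sig^2)),
                       exp(-(xs - centers[k, 1])^2 / (2 * sig^2)))
  }
  pmin(pat, 1)
}

#' Ground-truth 3D mask and 2D footprint of one nucleus
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param i nucleus index.
#' @return \code{truthNucleusMask}: 3D logical array;
#'   \code{truthFootprint}: 2D logical matrix of the projected ellipse.
#' @export
truthNucleusMask <- function(truth, i = 1L) {
  cal <- calibration(truth)
  d <- truth@dims
  nn <- truth@nuclei[i, ]
  xs <- (seq_len(d[2]) - 0.5) * cal@dx
  ys <- (seq_len(d[1]) - 0.5) * cal@dy
  zs <- (seq_len(d[3]) - 0.5) * cal@dz
  lat <- outer(((ys - nn$cy) / nn$ay)^2, ((xs - nn$cx) / nn$ax)^2, "+")
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    rz <- 1 - ((zs[z] - nn$cz) / nn$az)^2
    if (rz > 0) out[, , z] <- lat <= rz
  }
  out
}

#' @rdname truthNucleusMask
#' @export
truthFootprint <- function(truth, i = 1L) {
  cal <- calibration(truth)
  d <- truth@dims
  nn <- truth@nuclei[i, ]
  xs <- (seq_len(d[2]) - 0.5) * cal@dx
  ys <- (seq_len(d[1]) - 0.5) * cal@dy
  outer(((ys - nn$cy) / nn$ay)^2, ((xs - nn$cx) / nn$ax)^2, "+") <= 1
}

#' NucleusSet from ground truth
#'
#' Builds a \code{\linkS4class{NucleusSet}} directly from the true nucleus
#' footprints of a scene, bypassing detection. Useful to isolate the
#' performance of the foci-detection stage from nucleus recognition.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @return a \code{NucleusSet} with one label per true nucleus.
#' @export
truthNucleusSet <- function(truth) {
  cal <- calibration(truth)
  d <- truth@dims
  lab <- matrix(0L, d[1], d[2])
  n <- nrow(truth@nuclei)
  rois <- .emptyRois()
  for (i in seq_len(n)) lab[truthFootprint(truth, i)] <- i
  if (n > 0) {
    nn <- truth@nuclei
    rois <- data.frame(label = seq_len(n),
                       areaUm2 = pi * nn$ax * nn$ay,
                       xUm = nn$cx, yUm = nn$cy,
                       circularity = 1, touchesEdge = FALSE)
  }
  new("NucleusSet", labels = lab, rois = rois, calibration = cal)
}

# dart-throwing sampler: n points inside the (shrunken) nucleus ellipsoid,
# restricted to the axial slab zRange, with a minimum pairwise distance (um)
.sampleFociCenters <- function(nn, n, minDist, margin = 1.5,
                               zRange = c(1.2, 13.8),
                               maxAttempts = 60000L) {
  ax <- nn$ax - margin; ay <- nn$ay - margin; az <- nn$az - margin
  if (min(ax, ay, az) <= 0) stop("nucleus too small for the focus margin")
  pts <- matrix(NA_real_, n, 3)
  k <- 0L
  att <- 0L
  while (k < n && att < maxAttempts) {
    att <- att + 1L
    p <- stats::runif(3, -1, 1)
    if (sum(p^2) > 1) next
    cand <- c(nn$cx + p[1] * ax, nn$cy + p[2] * ay, nn$cz + p[3] * az)
    if (cand[3] < zRange[1] || cand[3] > zRange[2]) next
    if (k > 0L) {
      d2 <- (pts[seq_len(k), 1] - cand[1])^2 +
        (pts[seq_len(k), 2] - cand[2])^2 + (pts[seq_len(k), 3] - cand[3])^2
      if (min(d2) < minDist^2) next
    }
    k <- k + 1L
    pts[k, ] <- cand
  }
  if (k < n) stop("could not place ", n, " foci at spacing ", minDist, " um")
  pts
}

#' Scene with n well-separated foci in one nucleus
#'
#' The count-recovery scenario: a single centred nucleus containing
#' \code{nFoci} foci whose pairwise centre distances exceed 2 um (more
#' than three times the rendered 0.47 um focus FWHM), so that every focus is
#' resolvable and the detected 3D count can be compared to truth exactly.
#'
#' @param nFoci number of foci (0 allowed).
#' @param seed scene seed.
#' @param minDist minimum pairwise centre distance (um).
#' @param sigma rendered focus sigma (um).
#' @param peak focus peak amplitude (a.u.).
#' @return a \code{\linkS4class{SceneSpec}}.
#' @export
fociFieldScene <- function(nFoci, seed = 1L, minDist = 2, sigma = 0.2,
                           peak = 13000) {
  nuc <- .defaultNucleus()
  foci <- .emptySceneFoci()
  if (nFoci > 0) {
    pts <- withr::with_seed(seed, .sampleFociCenters(nuc, nFoci, minDist))
    foci <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                       sigma = sigma, peak = peak, nucleus = 1L)
  }
  sceneSpec(nuclei = nuc, foci = foci, seed = seed)
}

#' Scene of fused focus pairs
#'
#' Pairs of foci whose centres are only 1.2 focus-FWHMs apart (about
#' 0.57 um), randomly oriented in 3D: the binary mask of each pair is a
#' single fused blob, the regime the seeded 3D watershed exists for. The
#' first \code{2 * nPairs} rows of the focus table are the pair members
#' (rows \code{i} and \code{i + nPairs} form pair \code{i}).
#'
#' The scene additionally contains \code{nSingles} well-separated companion
#' foci laddered across the axial range, emulating the dense-nucleus regime
#' in which overlapping foci actually occur: every slice then carries bright
#' focal signal, so the per-slice normalization does not flatten focus
#' summits against dim-slice interiors and the prominence-based seed finder
#' can resolve the pair summits (see the methods vignette).
#'
#' @param nPairs number of fused pairs.
#' @param seed scene seed.
#' @param pairDist intra-pair centre distance (um).
#' @param sigma rendered focus sigma (um).
#' @param nSingles number of companion singleton foci.
#' @return a \code{\linkS4class{SceneSpec}}.
#' @export
fusedPairsScene <- function(nPairs = 8L, seed = 1L, pairDist = 0.57,
                            sigma = 0.2, nSingles = 48L) {
  nuc <- .defaultNucleus()
  pts <- withr::with_seed(seed, {
    centers <- .sampleFociCenters(nuc, nPairs, minDist = 4, margin = 2,
                                  zRange = c(2.5, 12.5))
    dirs <- matrix(stats::rnorm(3 * nPairs), nPairs, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    members <- rbind(centers + dirs * pairDist / 2,
                     centers - dirs * pairDist / 2)
    rbind(members, .zLadderSingles(nuc, nSingles, members, minDist = 2.2))
  })
  foci <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                     sigma = sigma, peak = 13000, nucleus = 1L)
  sceneSpec(nuclei = nuc, foci = foci, seed = seed)
}

# companion singles at fixed z strata (one per stratum), placed inside the
# shrunken nucleus at >= minDist from all existing points
.zLadderSingles <- function(nn, n, existing, minDist, margin = 2,
                            maxAttempts = 20000L) {
  if (n == 0L) return(matrix(numeric(), 0, 3))
  zg <- seq(1.2, 13.8, length.out = n)
  out <- matrix(NA_real_, n, 3)
  pts <- existing
  for (k in seq_len(n)) {
    att <- 0L
    repeat {
      att <- att + 1L
      if (att > maxAttempts) stop("could not place companion foci")
      p <- stats::runif(2, -1, 1)
      if (sum(p^2) > 1) next
      rz <- 1 - ((zg[k] - nn$cz) / (nn$az - margin))^2
      if (rz <= 0) rz <- 0.02
      cand <- c(nn$cx + p[1] * (nn$ax - margin) * sqrt(rz),
                nn$cy + p[2] * (nn$ay - margin) * sqrt(rz), zg[k])
      d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 +
        (pts[, 3] - cand[3])^2
      if (min(d2) >= minDist^2) break
    }
    out[k, ] <- cand
    pts <- rbind(pts, cand)
  }
  out
}

#' Standard scene presets
#'
#' Named \code{\linkS4class{SceneSpec}} presets covering the regimes the
#' detection chain must handle: an empty field, one isolated nucleus, two
#' overlapping nuclei, an edge-clipped nucleus, sparse foci (unirradiated
#' background level), dense foci (irradiated, up to ~200 per nucleus),
#' fused focus pairs, a basal glass-artifact scene and a photobleached
#' scene. Default geometry uses 0.1 x 0.1 x 0.25 um voxels and 60 slices
#' per stack.
#'
#' @param seed base seed; each preset derives its own from it.
#' @return named list of \code{SceneSpec} objects.
#' @export
standardScenes <- function(seed = 1L) {
  seed <- as.integer(seed)
  nuc <- .defaultNucleus()
  wide <- c(224L, 352L, 60L)
  twoNuc <- rbind(.defaultNucleus(cx = 11.2, cy = 11.2),
                  .defaultNucleus(cx = 24, cy = 11.2))
  edgeNuc <- rbind(.defaultNucleus(cx = 6.4, cy = 11.2),
                   .defaultNucleus(cx = 24, cy = 11.2))
  dense <- withr::with_seed(seed + 5L, {
    p <- .sampleFociCenters(nuc, 200L, minDist = 0, margin = 1.5)
    data.frame(x = p[, 1], y = p[, 2], z = p[, 3], sigma = 0.2,
               peak = 13000, nucleus = 1L)
  })
  list(
    empty = sceneSpec(nuclei = .defaultNucleus()[0, ], seed = seed),
    singleNucleus = sceneSpec(nuclei = nuc, seed = seed + 1L),
    twoOverlappingNuclei = sceneSpec(dims = wide, nuclei = twoNuc,
                                     seed = seed + 2L),
    edgeClippedNucleus = sceneSpec(dims = wide, nuclei = edgeNuc,
                                   seed = seed + 3L),
    sparseFoci = fociFieldScene(12L, seed = seed + 4L),
    denseFoci = sceneSpec(nuclei = nuc, foci = dense, seed = seed + 5L),
    fusedPairs = fusedPairsScene(8L, seed = seed + 6L),
    basalArtifact = sceneSpec(dims = wide, nuclei = nuc,
                              basalArtifactSlices = 8L, seed = seed + 7L),
    photobleached = {
      s <- fociFieldScene(12L, seed = seed + 8L)
      s@bleachRate <- 0.98
      s
    })
}
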