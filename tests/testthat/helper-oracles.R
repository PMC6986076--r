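# Independent brute-force reference for the auto-local-threshold operators:
# explicit window gathering per pixel, statistics computed with base R.
naiveALT <- function(img, method, r, c = 0) {
  ny <- nrow(img)
  nx <- ncol(img)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  out <- matrix(FALSE, ny, nx)
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      yy <- y + offs$dy
      xx <- x + offs$dx
      k <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
      w <- img[cbind(yy[k], xx[k])]
      S <- switch(method,
                  mean = sum(w) / length(w),
                  midgray = (max(w) + min(w)) / 2,
                  median = sort(w)[ceiling(length(w) / 2)])
      out[y, x] <- img[y, x] > S - c
    }
  }
  out
}

# small random 8-bit test image
randomImage <- function(ny, nx, seed) {
  withr::with_seed(seed, matrix(sample(0:255, ny * nx, TRUE), ny, nx))
}

# digital disc mask
discMask <- function(ny, nx, cy, cx, r) {
  outer(seq_len(ny), seq_len(nx),
        function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

# binary sphere mask in a 3D array (voxel units)
sphereMask <- function(dims, center, r) {
  a <- array(FALSE, dims)
  for (z in seq_len(dims[3])) {
    d2 <- outer((seq_len(dims[1]) - center[1])^2,
                (seq_len(dims[2]) - center[2])^2, "+") + (z - center[3])^2
    a[, , z] <- d2 <= r^2
  }
  a
}

# closed-form scene value at one voxel (independent of renderScene internals)
sceneValueAt <- function(spec, y, x, z) {
  cal <- calibration(spec)
  px <- (x - 0.5) * cal@dx
  py <- (y - 0.5) * cal@dy
  pz <- (z - 0.5) * cal@dz
  v <- spec@background
  for (i in seq_len(nrow(spec@nuclei))) {
    nn <- spec@nuclei[i, ]
    if (((px - nn$cx) / nn$ax)^2 + ((py - nn$cy) / nn$ay)^2 +
        ((pz - nn$cz) / nn$az)^2 <= 1)
      v <- v + nn$intensity - spec@background
  }
  for (i in seq_len(nrow(spec@foci))) {
    fc <- spec@foci[i, ]
    d2 <- (px - fc$x)^2 + (py - fc$y)^2 + (pz - fc$z)^2
    if (d2 <= (4 * fc$sigma)^2)
      v <- v + fc$peak * exp(-d2 / (2 * fc$sigma^2))
  }
  v
}
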