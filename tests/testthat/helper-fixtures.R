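# Shared fixtures, built in code.  Expensive objects are memoised for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# smooth off-centre Gaussian blob phantom for interpolation tests
gaussian_blob_volume <- function(n = 24, center = NULL, sigma = 2.5,
                                 voxel_size = 1) {
  if (is.null(center)) center <- (n - 1) / 2 + c(0, 0, 0)
  z <- seq_len(n) - 1
  g <- array(0, c(n, n, n))
  for (ix in seq_len(n)) {
    dx2 <- (ix - 1 - center[3])^2
    g[, , ix] <- outer((z - center[1])^2, (z - center[2])^2, `+`) + dx2
  }
  density_volume(exp(-g / (2 * sigma^2)), voxel_size)
}

centroid_xyz <- function(vol) {
  d <- dim(vol$grid)
  w <- vol$grid
  iz <- slice.index(w, 1) - 1
  iy <- slice.index(w, 2) - 1
  ix <- slice.index(w, 3) - 1
  s <- sum(w)
  c(sum(w * ix), sum(w * iy), sum(w * iz)) / s
}

# small crystal configuration for fast end-to-end tests
mini_crystal <- function(jitter = 0, seed = 1) {
  crystal_spec(n_cells = c(2, 2), jitter_sigma_xy = jitter,
               jitter_sigma_angle = jitter, seed = seed)
}

mini_sim <- function(jitter = 0, seed = 1) {
  memo(sprintf("mini_sim_%g_%d", jitter, seed),
       build_crystal_volume(mini_crystal(jitter, seed), phantom_spec(),
                            box = c(80, 96, 96), voxel_size = 6.66,
                            phantom_box = 40))
}

# synthetic two-cosine crystal image with a given cell (A, deg) sampled at
# pixel_size; optionally rotated in-plane by `rot` degrees (built
# analytically so no resampling is involved)
cosine_crystal_image <- function(a, b, gamma, n = 160, pixel_size = 6.66,
                                 rot = 0, phases = c(0, 0),
                                 weights = c(1, 0.8), harmonics = TRUE) {
  g <- gamma * pi / 180
  A <- cbind(c(0, a), c(b * sin(g), b * cos(g))) / pixel_size
  R <- matrix(c(cos(rot * pi / 180), -sin(rot * pi / 180),
                sin(rot * pi / 180), cos(rot * pi / 180)), 2, 2, byrow = TRUE)
  A <- R %*% A
  G <- t(solve(A))
  X <- matrix(0:(n - 1), n, n)
  Y <- matrix(rep(0:(n - 1), each = n), n, n)
  img <- weights[1] * cos(2 * pi * (G[1, 1] * X + G[2, 1] * Y) + phases[1]) +
         weights[2] * cos(2 * pi * (G[1, 2] * X + G[2, 2] * Y) + phases[2])
  if (harmonics)   # higher orders so more than one order is present
    img <- img + 0.4 * cos(4 * pi * (G[1, 1] * X + G[2, 1] * Y)) +
                 0.3 * cos(4 * pi * (G[1, 2] * X + G[2, 2] * Y)) +
                 0.25 * cos(2 * pi * ((G[1, 1] + G[1, 2]) * X +
                                      (G[2, 1] + G[2, 2]) * Y))
  projection_image(img, pixel_size)
}

# quantise a numeric vector through float32 (independent base-R oracle)
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4), "numeric",
          n = length(x), size = 4)
}


# crystal image of Gaussian blobs on the lattice nodes (motif-style
# fixture with sharp correlation peaks)
blob_crystal_image <- function(a, b, gamma, n = 160, pixel_size = 6.66,
                               sigma_px = 6) {
  g <- gamma * pi / 180
  A <- cbind(c(0, a), c(b * sin(g), b * cos(g))) / pixel_size
  Ainv <- solve(A)
  X <- matrix(0:(n - 1), n, n)
  Y <- matrix(rep(0:(n - 1), each = n), n, n)
  U <- Ainv[1, 1] * X + Ainv[1, 2] * Y
  V <- Ainv[2, 1] * X + Ainv[2, 2] * Y
  du <- U - round(U); dv <- V - round(V)
  dx <- A[1, 1] * du + A[1, 2] * dv
  dy <- A[2, 1] * du + A[2, 2] * dv
  projection_image(exp(-(dx^2 + dy^2) / (2 * sigma_px^2)), pixel_size)
}
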