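#' 3D density volume
#'
#' The common container of the whole workflow: a 3D scalar grid with a
#' physical (isotropic) voxel size.  The grid is stored in `(z, y, x)` axis
#' order, i.e. `grid[iz, iy, ix]`, with 0-based voxel centres at integer
#' coordinates; the physical position of voxel `(0,0,0)` is `origin`
#' (Angstrom, `(z, y, x)` components).
#'
#' @param grid numeric 3D array in `(z, y, x)` order, all values finite,
#'   at least 2 voxels along every axis.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @param origin physical offset (Angstrom) of voxel `(0,0,0)`, length-3
#'   `(z, y, x)`; defaults to zero.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array")
  if (any(dim(grid) < 2L))
    stop("grid dimensions must be >= 2 in every axis")
  if (!all(is.finite(grid)))
    stop("grid values must be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_volume> %d x %d x %d voxels (z,y,x) @ %.3f A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$grid), max(x$grid), mean(x$grid)))
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$grid)

as_volume_like <- function(grid, template) {
  density_volume(grid, template$voxel_size, template$origin)
}

is_cubic <- function(vol) {
  d <- dim(vol$grid)
  d[1] == d[2] && d[2] == d[3]
}

#' Rotate (and shift) a volume about its centre
#'
#' Applies a rigid transform to the density: the object is rotated by the
#' transform's rotation about the volume centre and translated by its shift,
#' using trilinear interpolation; voxels sampled outside the source are zero.
#' Used, e.g., to flip particles from the opposite membrane face by 180°
#' about the x axis before alignment.
#'
#' @param vol a [density_volume()]; must be cubic so the rotation stays
#'   in place.
#' @param transform a [rigid_transform()]; the shift is in voxels `(z, y, x)`.
#' @return The transformed [density_volume()].
#' @export
rotate_volume <- function(vol, transform) {
  if (!is_cubic(vol))
    stop("rotate_volume() requires a cubic volume")
  d <- dim(vol$grid)
  R <- transform_matrix(transform)        # xyz convention, reference -> particle
  ctr <- (rev(d) - 1) / 2                 # (x, y, z) centre
  s_xyz <- rev(transform$shift)           # shift given (z,y,x) -> (x,y,z)
  A <- t(R)                               # R^{-1}
  b <- ctr - A %*% (ctr + s_xyz)
  out <- cpp_affine_sample(vol$grid, dim(vol$grid), d, A, as.numeric(b))
  as_volume_like(out, vol)
}

#' Bin a volume by block averaging
#'
#' @param vol a [density_volume()]; every dimension must be divisible by
#'   `factor`.
#' @param factor integer binning factor (1 returns the input).
#' @return Binned [density_volume()] with voxel size scaled by `factor`.
#' @export
bin_volume <- function(vol, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  d <- dim(vol$grid)
  if (any(d %% factor != 0L))
    stop("volume dimensions must be divisible by the binning factor")
  g <- vol$grid
  dn <- d %/% factor
  # collapse each axis in turn
  g <- array(g, c(factor, dn[1], d[2], d[3]))
  g <- colMeans(g)
  g <- aperm(array(g, c(dn[1], factor, dn[2], d[3])), c(2, 1, 3, 4))
  g <- colMeans(g)
  g <- aperm(array(g, c(dn[1], dn[2], factor, dn[3])), c(3, 1, 2, 4))
  g <- colMeans(g)
  density_volume(array(g, dn), vol$voxel_size * factor, vol$origin)
}

# --- Fourier helpers ---------------------------------------------------------

# Signed integer frequency index along an axis of length n (FFT layout).
freq_index <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n)
}

# List of three arrays (kz, ky, kx) of spatial frequency in cycles/voxel.
freq_grids <- function(d) {
  kz <- freq_index(d[1]) / d[1]
  ky <- freq_index(d[2]) / d[2]
  kx <- freq_index(d[3]) / d[3]
  list(kz = array(rep(kz, times = d[2] * d[3]), d),
       ky = array(rep(rep(ky, each = d[1]), times = d[3]), d),
       kx = array(rep(kx, each = d[1] * d[2]), d))
}

# |k| in cycles/voxel on the FFT grid (cached per dimension).
.freq_cache <- new.env(parent = emptyenv())
freq_radius <- function(d) {
  key <- paste(d, collapse = "x")
  if (!is.null(.freq_cache[[key]])) return(.freq_cache[[key]])
  k <- freq_grids(d)
  r <- sqrt(k$kz^2 + k$ky^2 + k$kx^2)
  .freq_cache[[key]] <- r
  r
}

#' Low-pass filter a volume by a hard spherical cutoff
#'
#' @param vol a [density_volume()].
#' @param resolution cutoff in Angstrom; frequencies beyond `1/resolution`
#'   are zeroed.  `Inf` (or anything coarser than the box) returns the input.
#' @return Filtered [density_volume()].
#' @export
lowpass_volume <- function(vol, resolution) {
  if (!is.finite(resolution)) return(vol)
  kc <- vol$voxel_size / resolution   # cycles/voxel
  if (kc >= 0.5 * sqrt(3)) return(vol)
  r <- freq_radius(dim(vol$grid))
  ft <- fft(vol$grid)
  ft[r > kc] <- 0
  as_volume_like(Re(fft(ft, inverse = TRUE)) / length(ft), vol)
}

#' Gaussian-smooth a volume
#'
#' Fourier-domain Gaussian filter `exp(-2 pi^2 sigma^2 k^2)`; compact,
#' ring-free smoothing (unlike a sharp cutoff).
#'
#' @param vol a [density_volume()].
#' @param sigma real-space standard deviation in Angstrom (0 returns the
#'   input).
#' @return Smoothed [density_volume()].
#' @export
gaussian_smooth_volume <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  s <- sigma / vol$voxel_size
  r <- freq_radius(dim(vol$grid))
  F <- fft(vol$grid) * exp(-2 * pi^2 * s^2 * r^2)
  as_volume_like(Re(fft(F, inverse = TRUE)) / length(F), vol)
}

# Soft-edged cylindrical mask along z (cosine edge), radius in Angstrom.
# For lattice specimens this keeps a particle's own missing-wedge ghosts
# (which smear along z) while excluding the neighbouring unit cells.
soft_cylinder_mask <- function(d, voxel_size, radius, edge_width = 3) {
  ctr <- (d - 1) / 2
  y <- ((seq_len(d[2]) - 1) - ctr[2]) * voxel_size
  x <- ((seq_len(d[3]) - 1) - ctr[3]) * voxel_size
  rr <- sqrt(outer(y^2, x^2, `+`))
  w <- edge_width * voxel_size
  m2 <- (rr <= radius) +
    (rr > radius & rr < radius + w) * 0.5 * (1 + cos(pi * (rr - radius) / w))
  array(rep(as.numeric(m2), each = d[1]), d)
}

alignment_mask <- function(shape, d, voxel_size, radius) {
  if (is.null(radius)) return(NULL)
  switch(shape,
         sphere = soft_sphere_mask(d, voxel_size, radius),
         cylinder = soft_cylinder_mask(d, voxel_size, radius),
         stop("unknown mask shape: ", shape))
}

# Soft-edged spherical mask (cosine edge), radius in Angstrom.
soft_sphere_mask <- function(d, voxel_size, radius, edge_width = 3) {
  ctr <- (d - 1) / 2
  z <- (seq_len(d[1]) - 1 - ctr[1])
  y <- (seq_len(d[2]) - 1 - ctr[2])
  x <- (seq_len(d[3]) - 1 - ctr[3])
  rr <- sqrt(outer(outer(z^2, y^2, `+`), x^2, `+`)) * voxel_size
  r0 <- radius
  w <- edge_width * voxel_size
  m <- (rr <= r0) + (rr > r0 & rr < r0 + w) * 0.5 * (1 + cos(pi * (rr - r0) / w))
  array(m, d)
}
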