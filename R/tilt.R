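#' Simulate a single-axis tilt series
#'
#' Projects the volume along the beam for each tilt angle about the y axis
#' (real-space rotation + summation along z) and adds white Gaussian noise.
#' The default angular range is the acquisition scheme of the study
#' conditions: -60 to +60 degrees in 1.5-degree steps (81 images).
#'
#' @param vol a [density_volume()].
#' @param angles tilt angles in degrees, strictly increasing, within
#'   (-90, 90).
#' @param noise_sigma standard deviation of the additive white noise, in
#'   the same units as the projected densities.  Alternatively supply
#'   `snr` to derive it from the signal.
#' @param snr if not `NULL`, `noise_sigma` is set to `sd(noiseless
#'   projections) / snr`.
#' @param seed RNG seed for the noise.
#' @return A list of class `tilt_series`: `images` (array nx x ny x
#'   n_angles), `angles`, `pixel_size` (A), `noise_sigma`, `seed`.
#' @export
simulate_tilt_series <- function(vol, angles = seq(-60, 60, by = 1.5),
                                 noise_sigma = 0, snr = NULL, seed = 1) {
  stopifnot(all(diff(angles) > 0), all(angles > -90 & angles < 90))
  imgs <- cpp_project_tilt(vol$grid, dim(vol$grid), angles)
  if (!is.null(snr)) {
    s <- sd(as.numeric(imgs))
    noise_sigma <- if (snr > 0) s / snr else 0
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    imgs <- imgs + array(rnorm(length(imgs), 0, noise_sigma), dim(imgs))
  }
  structure(list(images = imgs, angles = angles,
                 pixel_size = vol$voxel_size, noise_sigma = noise_sigma,
                 seed = seed),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  cat(sprintf("<tilt_series> %d images %d x %d @ %.3f A/px, %+.1f..%+.1f deg, noise sd %.3g\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              x$pixel_size, min(x$angles), max(x$angles), x$noise_sigma))
  invisible(x)
}

# Ramp (R-weighting) filter along the detector x axis, per image.
ramp_filter_images <- function(imgs) {
  d <- dim(imgs)
  kx <- abs(freq_index(d[1])) / d[1]
  kx[1] <- 1 / (4 * d[1])                 # keep a little DC so means survive
  w <- kx * (0.5 + 0.5 * cos(pi * kx / 0.5))   # raised-cosine rolloff to Nyquist
  out <- imgs
  for (ia in seq_len(d[3])) {
    F <- mvfft(imgs[, , ia])
    out[, , ia] <- Re(mvfft(F * w, inverse = TRUE)) / d[1]
  }
  out
}

#' Weighted back-projection reconstruction
#'
#' Ramp-weighted (R-weighted) back-projection of a single-axis tilt series
#' about the y axis.  The output voxel size equals the pixel size; the
#' z extent is configurable.
#'
#' @param series a [tilt_series()] (angles are taken as exact, i.e. a
#'   simulated, pre-aligned series).
#' @param nz output thickness in voxels (default: the detector width nx).
#' @return A [density_volume()] of dimensions `(nz, ny, nx)`.
#' @export
reconstruct_wbp <- function(series, nz = NULL) {
  d <- dim(series$images)
  if (is.null(nz)) nz <- d[1]
  filt <- ramp_filter_images(series$images)
  vol <- cpp_backproject_tilt(filt, dim(filt), series$angles,
                              as.integer(c(nz, d[2], d[1])))
  vol <- vol * (pi / (2 * length(series$angles)))
  density_volume(vol, series$pixel_size)
}

#' Fourier-domain missing-wedge mask
#'
#' Binary mask of the Fourier region sampled by a single-axis tilt series
#' about y with maximal tilt `theta_max`: a voxel is included iff
#' `|k_z| <= tan(theta_max) * |k_x|`.  The mask is Hermitian (Friedel)
#' symmetric by construction and is returned in FFT index order.
#'
#' @param shape integer `(nz, ny, nx)`.
#' @param theta_max maximal tilt in degrees, in (0, 90].
#' @return Logical array of dimension `shape`.
#' @export
wedge_mask <- function(shape, theta_max = 60) {
  stopifnot(theta_max > 0, theta_max <= 90)
  if (theta_max == 90) return(array(TRUE, shape))
  k <- freq_grids(shape)
  abs(k$kz) <= tan(theta_max * pi / 180) * abs(k$kx)
}

# Wedge mask rotated by rotation matrix Q (mask of a particle whose object
# was rotated by Q relative to the acquisition frame), evaluated analytically.
rotated_wedge_mask <- function(shape, Q, theta_max = 60) {
  if (theta_max == 90) return(array(TRUE, shape))
  k <- freq_grids(shape)
  # components of Q^{-1} k  (k in xyz order)
  Qi <- t(Q)
  ux <- Qi[1, 1] * k$kx + Qi[1, 2] * k$ky + Qi[1, 3] * k$kz
  uz <- Qi[3, 1] * k$kx + Qi[3, 2] * k$ky + Qi[3, 3] * k$kz
  abs(uz) <= tan(theta_max * pi / 180) * abs(ux)
}
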