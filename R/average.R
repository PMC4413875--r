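#' Alignment search constraints
#'
#' The angular search leaves the rotation about the particle z axis free
#' and restricts the off-axis (x/y) rotation; translations are bounded
#' per axis.  Defaults follow the study conditions: +/-45 degrees off-axis,
#' 12 voxels of shift.
#'
#' @param max_xy_rot maximal off-axis rotation (ZYZ tilt) in degrees,
#'   in (0, 90].
#' @param max_shift maximal translation per axis, voxels (>= 0), applied
#'   at full sampling and scaled down for binned stages.
#' @param resolution_limit optional low-pass limit (A) applied during
#'   scoring; usually supplied per refinement stage instead.
#' @return List of class `alignment_constraints`.
#' @export
alignment_constraints <- function(max_xy_rot = 45, max_shift = 12,
                                  resolution_limit = Inf) {
  stopifnot(max_xy_rot > 0, max_xy_rot <= 90, max_shift >= 0)
  structure(list(max_xy_rot = max_xy_rot, max_shift = max_shift,
                 resolution_limit = resolution_limit),
            class = "alignment_constraints")
}

#' Coarse-to-fine refinement schedule
#'
#' An ordered list of stages, each a list with `binning` (1, 2 or 4),
#' `resolution` (low-pass limit in A), `step` (angular grid step in
#' degrees) and `iterations`.  Binning and resolution limits must be
#' non-increasing: the default mirrors a 60 A start on binned data
#' gradually lowered to 30 A unbinned.
#'
#' @param stages list of stage lists.
#' @return List of class `refinement_schedule`.
#' @export
refinement_schedule <- function(stages = list(
    list(binning = 2, resolution = 60, step = 15, iterations = 2),
    list(binning = 2, resolution = 40, step = 7.5, iterations = 1),
    list(binning = 1, resolution = 30, step = 4, iterations = 2))) {
  b <- vapply(stages, `[[`, 0, "binning")
  r <- vapply(stages, `[[`, 0, "resolution")
  if (any(diff(b) > 0)) stop("schedule binning must be non-increasing")
  if (any(diff(r) > 0)) stop("schedule resolution limits must be non-increasing")
  if (!all(b %in% c(1, 2, 4))) stop("binning must be 1, 2 or 4")
  structure(list(stages = stages), class = "refinement_schedule")
}

#' Extract subvolumes at particle positions
#'
#' Cuts one cubic box per table record, centred (with trilinear sub-voxel
#' accuracy) on the recorded position.  Boxes reaching outside the
#' tomogram are zero-padded or skipped.  Down-face records are flagged
#' for the 180-degree x-flip applied before alignment.
#'
#' @param tomogram a [density_volume()].
#' @param table a [particle_table()].
#' @param box cube edge, voxels.
#' @param out_of_bounds `"pad"` (zero-fill, default) or `"skip"` (drop the
#'   record with a warning).
#' @return List of class `subvolume_stack`: `data` (array box^3 x n),
#'   `table`, `flip` (logical), `voxel_size`, `box`.
#' @export
extract_subvolumes <- function(tomogram, table, box = 40,
                               out_of_bounds = c("pad", "skip")) {
  out_of_bounds <- match.arg(out_of_bounds)
  d <- dim(tomogram$grid)
  n <- nrow(table)
  cb <- (box - 1) / 2
  inside <- table$x - cb >= 0 & table$x + cb <= d[3] - 1 &
            table$y - cb >= 0 & table$y + cb <= d[2] - 1 &
            table$z - cb >= 0 & table$z + cb <= d[1] - 1
  if (out_of_bounds == "skip" && any(!inside)) {
    warning(sprintf("skipping %d particle(s) with boxes outside the tomogram",
                    sum(!inside)))
    table <- table[inside, ]
    n <- nrow(table)
  }
  data <- array(0, c(box, box, box, n))
  A <- diag(3)
  for (i in seq_len(n)) {
    b <- c(table$x[i], table$y[i], table$z[i]) - cb
    data[, , , i] <- cpp_affine_sample(tomogram$grid, d,
                                       rep(as.integer(box), 3), A, b)
  }
  structure(list(data = data, table = particle_table(as.data.frame(table)),
                 flip = table$face == "down",
                 voxel_size = tomogram$voxel_size, box = box),
            class = "subvolume_stack")
}

stack_volume <- function(stack, i) {
  density_volume(array(stack$data[, , , i], rep(stack$box, 3)),
                 stack$voxel_size)
}

x_flip_transform <- function() rigid_transform(tilt = 180, psi = 180)

# Work copy of the stack with down-face members flipped 180 deg about x.
flipped_stack_data <- function(stack) {
  data <- stack$data
  fl <- x_flip_transform()
  for (i in which(stack$flip))
    data[, , , i] <- rotate_volume(stack_volume(stack, i), fl)$grid
  data
}

#' Initial reference from unaligned subvolumes
#'
#' Plain average of the (unaligned) up-face boxes; down-face boxes
#' contribute after the 180-degree x-rotation.
#'
#' @param stack a `subvolume_stack` from [extract_subvolumes()].
#' @param members optional index subset.
#' @return A [density_volume()].
#' @export
make_initial_reference <- function(stack, members = NULL) {
  if (is.null(members)) members <- seq_len(nrow(stack$table))
  if (!length(members)) stop("cannot build a reference from an empty selection")
  acc <- array(0, rep(stack$box, 3))
  fl <- x_flip_transform()
  for (i in members) {
    v <- stack_volume(stack, i)
    if (stack$flip[i]) v <- rotate_volume(v, fl)
    acc <- acc + v$grid
  }
  density_volume(acc / length(members), stack$voxel_size)
}

# --- angular grids -----------------------------------------------------------

# Global ZYZ grid: psi (in-plane/z spin) free, tilt limited; degenerate
# rot/psi at tilt 0 pruned.  Returns list of rotation matrices sorted by
# total rotation angle (tie-break: smaller rotations tried first).
global_orientation_grid <- function(step, max_tilt) {
  tilts <- seq(0, max_tilt, by = step)
  azi <- seq(0, 360 - step, by = step)
  Rs <- list()
  for (tl in tilts) {
    rots <- if (tl == 0) 0 else azi
    for (ro in rots) for (ps in azi)
      Rs[[length(Rs) + 1]] <- transform_matrix(c(ro, tl, ps))
  }
  Rs[order(vapply(Rs, rotation_angle, 0))]
}

# Local grid: perturbations of R0 by small rotations about the lab axes,
# +/- n_steps * step per axis; candidates violating the tilt constraint
# are dropped.  Sorted by distance from R0.
local_orientation_grid <- function(R0, step, max_tilt, n_steps = 2) {
  offs <- seq(-n_steps, n_steps) * step
  Rs <- list(R0); dist <- 0   # the current orientation is always a candidate
  for (ax in offs) for (ay in offs) for (az in offs) {
    if (ax == 0 && ay == 0 && az == 0) next
    R <- rot_x(ax) %*% rot_y(ay) %*% rot_z(az) %*% R0
    e <- matrix_to_euler(R)
    if (e[2] > max_tilt + 1e-6) next
    Rs[[length(Rs) + 1]] <- R
    dist[length(Rs)] <- sqrt(ax^2 + ay^2 + az^2)
  }
  Rs[order(dist)]
}

# --- scoring -----------------------------------------------------------------

# Fourier mask for scoring: band limit, optional high-pass (suppresses the
# broad membrane-slab correlation), optional wedge, no DC.
score_mask <- function(shape, voxel_size, resolution, wedge,
                       highpass = Inf) {
  r <- freq_radius(shape)
  m <- r > 0
  if (is.finite(resolution)) m <- m & (r <= voxel_size / resolution)
  if (is.finite(highpass)) m <- m & (r > voxel_size / highpass)
  if (!is.null(wedge)) m <- m & wedge
  m
}

# allowed shift index sets and signed shifts for a box of size n
shift_index <- function(n, max_shift) {
  m <- min(max_shift, floor((n - 1) / 2))
  idx <- c(1:(m + 1), if (m > 0) (n - m + 1):n)
  shifts <- c(0:m, if (m > 0) -(m:1))
  list(idx = idx, shifts = shifts)
}

parabolic_offset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (!is.finite(den) || den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (fm - fp) / den))
}

# Correlate one particle FT against a rotated-reference FT over masked
# Fourier voxels; returns best (shift, score) within the per-axis bound.
best_shift <- function(Fp, Fr, np, nr, si) {
  cc <- Re(fft(Fp * Conj(Fr), inverse = TRUE))
  sub <- cc[si$idx, si$idx, si$idx]
  mx <- max(sub)
  w <- which(sub == mx)
  if (length(w) > 1) {
    co <- arrayInd(w, dim(sub))
    nrm <- rowSums(matrix(si$shifts[co], ncol = 3)^2)
    w <- w[which.min(nrm)]
  }
  co <- arrayInd(w[1], dim(sub))[1, ]
  sh <- si$shifts[co]                       # (z, y, x) signed integer shift
  n <- dim(cc)[1]
  wrap <- function(i) ((i - 1) %% n) + 1
  off <- numeric(3)
  for (ax in 1:3) {
    i0 <- wrap(sh[ax] + 1); im <- wrap(sh[ax]); ip <- wrap(sh[ax] + 2)
    pick <- function(iz, iy, ix) cc[iz, iy, ix]
    ctr <- wrap(sh + 1)
    args <- list(ctr[1], ctr[2], ctr[3])
    fm <- do.call(pick, `[<-`(args, ax, im))
    fp <- do.call(pick, `[<-`(args, ax, ip))
    off[ax] <- parabolic_offset(fm, mx, fp)
  }
  list(shift = sh + off, score = mx / (np * nr))
}

#' Align one subvolume to a reference
#'
#' Exhaustive constrained search: rotations on a grid with free z spin and
#' off-axis tilt limited to `constraints$max_xy_rot`, translations by
#' FFT cross-correlation restricted to `constraints$max_shift` voxels per
#' axis.  The score is the normalised correlation computed only over
#' Fourier voxels inside the scoring mask: band limit intersected with the
#' particle's missing-wedge mask and the reference coverage rotated to the
#' candidate orientation.  Ties are broken by the smaller rotation angle,
#' then the smaller shift norm.
#'
#' @param subvol particle [density_volume()].
#' @param reference reference [density_volume()] (same box).
#' @param constraints an [alignment_constraints()].
#' @param wedge logical Fourier mask of the particle's sampled region
#'   (e.g. [wedge_mask()]), or `NULL` for no wedge weighting.
#' @param resolution low-pass limit (A) for scoring.
#' @param highpass optional high-pass limit (A) for scoring (`Inf` for
#'   none).
#' @param step angular grid step in degrees.
#' @param ref_coverage logical Fourier mask of the reference's sampled
#'   region, or `NULL` if the reference is fully sampled.
#' @param around optional [rigid_transform()]: search only a local
#'   neighbourhood (+/- 2 steps per axis) of this orientation.
#' @return List with `transform` (a [rigid_transform()]) and `score`.
#' @export
align_subvolume <- function(subvol, reference, constraints = alignment_constraints(),
                            wedge = NULL, resolution = Inf, step = 10,
                            highpass = Inf, ref_coverage = NULL,
                            around = NULL) {
  stopifnot(identical(dim(subvol$grid), dim(reference$grid)))
  d <- dim(subvol$grid)
  M <- score_mask(d, subvol$voxel_size, resolution, wedge, highpass)
  if (!any(M)) stop("empty wedge/band intersection: pathological geometry")
  Fp <- fft(subvol$grid); Fp[!M] <- 0
  np <- sqrt(sum(Mod(Fp)^2))
  orientations <- if (is.null(around))
    global_orientation_grid(step, constraints$max_xy_rot)
  else
    local_orientation_grid(transform_matrix(around), step,
                           constraints$max_xy_rot)
  si <- shift_index(d[1], constraints$max_shift)
  best <- list(score = -Inf, transform = rigid_transform())
  for (R in orientations) {
    refr <- cpp_affine_sample(reference$grid, d, d, t(R),
                              as.numeric((rev(d) - 1) / 2 -
                                           t(R) %*% ((rev(d) - 1) / 2)))
    Fr <- fft(refr)
    Mo <- M
    if (!is.null(ref_coverage)) {
      cov <- rotated_coverage(ref_coverage, R)
      Mo <- M & cov
      if (!any(Mo)) stop("empty wedge intersection for an orientation")
      Fp_o <- fft(subvol$grid); Fp_o[!Mo] <- 0
    }
    Fr[!Mo] <- 0
    nr <- sqrt(sum(Mod(Fr)^2))
    if (nr == 0) next
    use_Fp <- if (is.null(ref_coverage)) Fp else Fp_o
    use_np <- if (is.null(ref_coverage)) np else sqrt(sum(Mod(use_Fp)^2))
    bs <- best_shift(use_Fp, Fr, use_np, nr, si)
    if (bs$score > best$score + 1e-12) {
      best$score <- bs$score
      best$transform <- transform_from_matrix(R, bs$shift)
    }
  }
  best
}

# Rotate a logical Fourier coverage mask by R (nearest-neighbour on the
# fftshifted grid).
rotated_coverage <- function(mask, R) {
  d <- dim(mask)
  sh <- fft_shift(mask * 1)
  ctr <- (rev(d) - 1) / 2
  A <- t(R)
  out <- cpp_affine_sample(array(as.numeric(sh), d), d, d, A,
                           as.numeric(ctr - A %*% ctr))
  fft_unshift(out) >= 0.5
}

fft_shift <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2)))
  do.call(`[`, c(list(a), idx))
}
fft_unshift <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) c((n - floor(n / 2) + 1):n, 1:(n - floor(n / 2))))
  do.call(`[`, c(list(a), idx))
}

#' Merge two half-maps
#'
#' @param mapA,mapB [density_volume()] objects of identical shape.
#' @return Voxel-wise mean as a [density_volume()].
#' @export
merge_halfmaps <- function(mapA, mapB) {
  if (!identical(dim(mapA$grid), dim(mapB$grid)))
    stop("half-map shapes differ")
  as_volume_like((mapA$grid + mapB$grid) / 2, mapA)
}
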