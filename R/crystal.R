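#' 2D unit cell
#'
#' @param a,b cell edges in Angstrom (> 0).
#' @param gamma included angle in degrees, in (0, 180).
#' @return Object of class `unit_cell_2d` with derived real-space lattice
#'   vectors: by package convention `va = (0, a)` runs along the y (tilt)
#'   axis and `vb = (b sin(gamma), b cos(gamma))` so the zigzag modulation
#'   of the membrane runs along x.
#' @export
unit_cell_2d <- function(a, b, gamma) {
  stopifnot(a > 0, b > 0, gamma > 0, gamma < 180)
  g <- gamma * pi / 180
  structure(list(a = a, b = b, gamma = gamma,
                 va = c(x = 0, y = a),
                 vb = c(x = b * sin(g), y = b * cos(g))),
            class = "unit_cell_2d")
}

#' Crystal specification
#'
#' Geometry of the synthetic 2D crystal: the unit cell, per-cell motif, the
#' out-of-plane inclination of the particle long axes, the azimuth
#' separation of the two same-face monomers of a pair, the in-plane
#' rotation between opposite-face partners, the zigzag membrane kink, and
#' disorder parameters.
#'
#' The default motif places one same-face pair per cell (fractional
#' positions 1/4,1/4 and 3/4,3/4) with an opposite-face partner under each
#' monomer, c-rings apposed across the membrane midplane and offset
#' `interface_offset`/2 either side of the membrane fold line.
#'
#' @param cell a [unit_cell_2d()] (default: the packaged crystal cell,
#'   a = 179.1 A, b = 171.4 A, gamma = 94.9 deg).
#' @param inclination_theta long-axis tilt from the crystal-plane normal,
#'   degrees in `[0, 45)`.
#' @param pair_azimuth_delta azimuth separation (degrees) of the two
#'   same-face monomers' tilt directions; the default 98.1 deg makes a
#'   16 deg inclination produce a 24 deg pair angle via
#'   `cos(pair) = cos^2(theta) + sin^2(theta) cos(delta)`.
#' @param interface_rotation in-plane rotation (degrees) between
#'   opposite-face partners after the 180-degree x-flip.
#' @param kink_kappa membrane direction change (degrees) at each particle
#'   row, in `[0, 90)`.
#' @param interface_offset in-plane separation (A) of the two apposed
#'   c-rings across a fold line.
#' @param jitter_sigma_xy,jitter_sigma_angle positional (A) and angular
#'   (degrees) disorder, applied per particle.
#' @param n_cells integer vector `(na, nb)`: number of cells along each
#'   lattice vector.
#' @param seed RNG seed for the disorder draws.
#' @return A list of class `crystal_spec`.
#' @export
crystal_spec <- function(cell = unit_cell_2d(179.1, 171.4, 94.9),
                         inclination_theta = 16,
                         pair_azimuth_delta = 98.1,
                         interface_rotation = 90,
                         kink_kappa = 43,
                         interface_offset = 45,
                         jitter_sigma_xy = 2,
                         jitter_sigma_angle = 1.5,
                         n_cells = c(3, 3),
                         seed = 1) {
  stopifnot(inherits(cell, "unit_cell_2d"),
            inclination_theta >= 0, inclination_theta < 45,
            kink_kappa >= 0, kink_kappa < 90)
  structure(list(cell = cell, inclination_theta = inclination_theta,
                 pair_azimuth_delta = pair_azimuth_delta,
                 interface_rotation = interface_rotation,
                 kink_kappa = kink_kappa, interface_offset = interface_offset,
                 jitter_sigma_xy = jitter_sigma_xy,
                 jitter_sigma_angle = jitter_sigma_angle,
                 n_cells = as.integer(n_cells), seed = seed),
            class = "crystal_spec")
}

# Membrane fold geometry implied by a crystal spec: fold rows parallel to y
# at x = phase + m * period, membrane height a triangle wave along x.
membrane_model <- function(crystal) {
  period <- crystal$cell$vb["x"] / 2
  slope <- tan(crystal$kink_kappa / 2 * pi / 180)
  list(period = unname(period), phase = unname(period / 2),
       amplitude = unname(period * slope / 2), slope = slope)
}

# Triangle-wave membrane height (A) at physical x (A).  Vertices sit at
# x = phase + m * period (peaks at even m, troughs at odd m), so the wave's
# full spatial period is 2 * period.
membrane_height <- function(mm, x) {
  u <- (x - mm$phase) / (2 * mm$period)
  tri <- 2 * abs(u - floor(u) - 0.5) - 0.5   # in [-1/2, 1/2], peak at u = 0
  2 * mm$amplitude * tri
}

# small random rotation with per-axis angles ~ N(0, sigma_deg)
jitter_rotation <- function(sigma_deg) {
  a <- rnorm(3, 0, sigma_deg)
  rot_x(a[1]) %*% rot_y(a[2]) %*% rot_z(a[3])
}

#' Build the ground-truth crystal volume and particle table
#'
#' Renders the phantom at every motif position of the crystal over
#' `n_cells` unit cells, centred in a tomogram-sized box, together with a
#' zigzag lipid slab (piecewise-planar segments tilted +/- kappa/2 from
#' the crystal plane, fold vertices at the particle rows).  Per cell the
#' motif holds two up-face monomers (a pair with azimuths separated by
#' `pair_azimuth_delta`) and two down-face monomers obtained by a 180-degree
#' rotation about x followed by `interface_rotation` about z, with c-rings
#' apposed across the membrane.  Every placement is recorded in the
#' returned ground-truth table.
#'
#' @param crystal a [crystal_spec()].
#' @param phantom a [phantom_spec()].
#' @param box integer `(nz, ny, nx)` tomogram dimensions in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param phantom_box phantom cube edge in voxels.
#' @return A list with elements `volume` (a [density_volume()]), `table`
#'   (the ground-truth [particle_table()]), `membrane` (fold-model list:
#'   period, phase, amplitude in A, in tomogram physical coordinates) and
#'   `z_mid` (voxel z of the mean membrane midplane).
#' @export
build_crystal_volume <- function(crystal, phantom = phantom_spec(),
                                 box = c(96, 128, 128), voxel_size = 6.66,
                                 phantom_box = 40) {
  if (any(crystal$n_cells < 1)) stop("need at least one unit cell")
  set.seed(crystal$seed)
  ph <- build_phantom(phantom, voxel_size, phantom_box)
  cell <- crystal$cell
  mm <- membrane_model(crystal)
  # motif: fractional (u, v), azimuth of tilt direction, face
  d2 <- crystal$pair_azimuth_delta / 2
  # u values 0.3/0.7 (not 0.25/0.75) so intra-cell pair distances are
  # strictly shorter than the cross-cell alternative (no mutual-NN ties)
  motif <- data.frame(u = c(0.3, 0.7, 0.3, 0.7),
                      v = c(0.25, 0.75, 0.25, 0.75),
                      azimuth = c(-d2, d2, -d2, d2),
                      face = c("up", "up", "down", "down"),
                      stringsAsFactors = FALSE)
  na <- crystal$n_cells[1]; nb <- crystal$n_cells[2]
  # centre the lattice block in the box (physical xy, A)
  ext_mid <- (na / 2) * cell$va + (nb / 2) * cell$vb
  box_ctr_xy <- c((box[3] - 1) / 2, (box[2] - 1) / 2) * voxel_size
  off_xy <- box_ctr_xy - ext_mid        # (x, y)
  z_mid <- (box[1] - 1) / 2             # membrane midplane mean, voxel z
  mm$phase <- mm$phase + off_xy[1]      # fold phase in tomogram coordinates
  recs <- list(); k <- 0
  Rflip <- rot_x(180)
  for (i in seq_len(na) - 1) for (j in seq_len(nb) - 1) {
    for (m in seq_len(nrow(motif))) {
      k <- k + 1
      fr <- c(i + motif$u[m], j + motif$v[m])
      xy <- fr[1] * cell$va + fr[2] * cell$vb + off_xy
      up <- motif$face[m] == "up"
      # apposed c-rings sit on the fold line, separated along the row (y)
      xy[2] <- xy[2] + (if (up) -1 else 1) * crystal$interface_offset / 2
      xy <- xy + rnorm(2, 0, crystal$jitter_sigma_xy)
      R <- rot_z(motif$azimuth[m]) %*% rot_y(crystal$inclination_theta)
      if (!up) R <- rot_z(crystal$interface_rotation) %*% Rflip %*% R
      if (crystal$jitter_sigma_angle > 0)
        R <- jitter_rotation(crystal$jitter_sigma_angle) %*% R
      zc <- membrane_height(mm, xy[1])                     # c-ring midplane, A
      centre_off <- R %*% c(0, 0, phantom$box_center_height)  # xyz, A
      pos <- c(xy[1] + centre_off[1], xy[2] + centre_off[2],
               z_mid * voxel_size + zc + centre_off[3]) / voxel_size
      recs[[k]] <- data.frame(id = k, x = pos[1], y = pos[2], z = pos[3],
                              rot = NA, tilt = NA, psi = NA,
                              face = motif$face[m], halfset = NA_character_,
                              score = NA_real_, stringsAsFactors = FALSE)
      e <- matrix_to_euler(R)
      recs[[k]]$rot <- e[1]; recs[[k]]$tilt <- e[2]; recs[[k]]$psi <- e[3]
    }
  }
  table <- particle_table(do.call(rbind, recs))
  # overlap check: placements closer than half a c-ring diameter
  pos <- particle_positions(table) * voxel_size
  dmat <- as.matrix(stats::dist(pos))
  n_overlap <- sum(dmat[upper.tri(dmat)] < phantom$cring_radius)
  if (n_overlap > 0)
    warning(sprintf("crystal packing: %d placement pair(s) overlap", n_overlap))
  # render: protein paste + lipid slab, protein displaces lipid (pmax)
  vol <- array(0, box)
  for (r in seq_len(nrow(table))) {
    R <- transform_matrix(c(table$rot[r], table$tilt[r], table$psi[r]))
    paste_rotated(vol, ph$grid, R, c(table$x[r], table$y[r], table$z[r]))
  }
  slab <- lipid_slab(box, voxel_size, mm, z_mid, phantom)
  vol <- pmax(vol, slab)
  list(volume = density_volume(array(vol, box), voxel_size),
       table = table, membrane = mm, z_mid = z_mid)
}

# In-place additive paste of `block_grid` rotated by R (reference->particle)
# at fractional voxel position pos = (x, y, z) in `target` (a plain array,
# modified by reference via the C++ kernel).
paste_rotated <- function(target, block_grid, R, pos) {
  d <- dim(block_grid)
  cb <- (d[1] - 1) / 2                    # cubic block
  q0 <- floor(cb)
  off <- floor(pos)                       # (x, y, z) integer
  frac <- pos - off
  A <- t(R)
  b <- rep(cb, 3) - A %*% (q0 + frac)
  block <- cpp_affine_sample(block_grid, d, d, A, as.numeric(b))
  cpp_paste_add(target, dim(target), block, d,
                as.integer(c(off[3] - q0, off[2] - q0, off[1] - q0)))
  invisible(target)
}

# Zigzag lipid slab density over the whole box.
lipid_slab <- function(box, voxel_size, mm, z_mid, phantom) {
  nx <- box[3]; ny <- box[2]; nz <- box[1]
  xs <- (seq_len(nx) - 1) * voxel_size
  hs <- membrane_height(mm, xs)           # A, per x column
  zs <- ((seq_len(nz) - 1) - z_mid) * voxel_size
  half <- phantom$membrane_thickness / 2
  edge <- phantom$edge_width * voxel_size
  # profile matrix (nz, nx)
  dzx <- outer(zs, hs, `-`)
  P <- soft_in(abs(dzx) - half, edge) * phantom$lipid_density
  aperm(array(P, c(nz, nx, ny)), c(1, 3, 2))
}
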