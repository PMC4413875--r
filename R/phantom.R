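#' Phantom specification for an ATP-synthase-like membrane complex
#'
#' Geometric solid primitives standing in for the complex seen in
#' tomograms of the 2D crystals: a spherical catalytic head held above the
#' membrane by a thin central stalk, an off-axis peripheral stalk, and a
#' membrane-embedded rotor ring (c-ring).  All lengths in Angstrom; the
#' long axis is +z and the c-ring is centred on the membrane midplane
#' z = 0.
#'
#' @param head_diameter diameter of the catalytic head (default 100 A,
#'   i.e. 10 nm).
#' @param head_height height of the head centre above the membrane
#'   midplane (default 150 A, i.e. 15 nm).
#' @param central_stalk_radius,central_stalk_length thin stalk connecting
#'   the c-ring to the head; the stalk spans from the top of the c-ring
#'   upward.
#' @param peripheral_stalk_radius,peripheral_stalk_offset off-axis stator
#'   stalk: a vertical cylinder at `x = offset` running from the membrane
#'   surface to the head centre height.  This is the feature that breaks
#'   azimuthal symmetry and makes the spin angle alignable.
#' @param cring_radius,cring_height membrane-embedded rotor ring, modelled
#'   as a solid cylinder centred on z = 0.
#' @param membrane_thickness lipid slab thickness (default 40 A).
#' @param protein_density,lipid_density unitless contrast levels.
#' @param box_center_height physical height (A) above the membrane
#'   midplane that maps to the phantom box centre; particle positions in
#'   tables refer to this point.
#' @param edge_width soft-edge width of all primitives, in voxels.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(head_diameter = 100, head_height = 150,
                         central_stalk_radius = 10,
                         central_stalk_length = NULL,
                         peripheral_stalk_radius = 14,
                         peripheral_stalk_offset = 52,
                         cring_radius = 22, cring_height = 40,
                         membrane_thickness = 40,
                         protein_density = 1, lipid_density = 0.5,
                         box_center_height = 80, edge_width = 1) {
  if (head_height <= head_diameter / 2)
    stop("head_height must exceed head_diameter/2 (head must clear the membrane)")
  if (is.null(central_stalk_length))
    central_stalk_length <- head_height - head_diameter / 2 - cring_height / 2
  spec <- list(head_diameter = head_diameter, head_height = head_height,
               central_stalk_radius = central_stalk_radius,
               central_stalk_length = central_stalk_length,
               peripheral_stalk_radius = peripheral_stalk_radius,
               peripheral_stalk_offset = peripheral_stalk_offset,
               cring_radius = cring_radius, cring_height = cring_height,
               membrane_thickness = membrane_thickness,
               protein_density = protein_density,
               lipid_density = lipid_density,
               box_center_height = box_center_height,
               edge_width = edge_width)
  lens <- unlist(spec[c("head_diameter", "head_height", "central_stalk_radius",
                        "central_stalk_length", "peripheral_stalk_radius",
                        "cring_radius", "cring_height", "membrane_thickness")])
  if (any(lens <= 0)) stop("all phantom lengths must be > 0")
  if (head_height <= head_diameter / 2)
    stop("head_height must exceed head_diameter/2 (head must clear the membrane)")
  structure(spec, class = "phantom_spec")
}

# soft solid indicator: 1 inside, cosine-free linear ramp of `edge` Angstrom
soft_in <- function(signed_dist, edge) {
  pmin(1, pmax(0, 0.5 - signed_dist / edge))
}

# Maximal reach (A) of phantom density from the box centre point.
phantom_reach <- function(spec) {
  zc <- spec$box_center_height
  reach <- c(
    sqrt(0^2) + abs(spec$head_height - zc) + spec$head_diameter / 2,
    sqrt((spec$cring_radius)^2 + (zc + spec$cring_height / 2)^2),
    sqrt((spec$peripheral_stalk_offset + spec$peripheral_stalk_radius)^2 +
           max(abs(spec$head_height + spec$head_diameter / 4 - zc),
               abs(zc - spec$membrane_thickness / 2))^2))
  max(reach)
}

#' Build the phantom density volume
#'
#' Renders the solid primitives of a [phantom_spec()] additively on a cubic
#' grid.  The long axis runs along +z; the membrane midplane z = 0 sits
#' `box_center_height` Angstrom below the box centre.  The membrane slab
#' itself is not rendered here (it belongs to the crystal builder); the
#' phantom is the protein reference used for alignment and re-insertion.
#'
#' @param spec a [phantom_spec()].
#' @param voxel_size Angstrom per voxel.
#' @param box cube edge in voxels (default 40).
#' @return A [density_volume()].
#' @export
build_phantom <- function(spec, voxel_size = 6.66, box = 40) {
  need <- 2 * (phantom_reach(spec) + spec$edge_width * voxel_size)
  if (need > box * voxel_size)
    stop(sprintf("phantom exceeds box: need >= %.0f A (%d voxels at %.2f A)",
                 need, ceiling(need / voxel_size), voxel_size))
  ctr <- (box - 1) / 2
  z <- ((seq_len(box) - 1) - ctr) * voxel_size + spec$box_center_height
  y <- ((seq_len(box) - 1) - ctr) * voxel_size
  x <- y
  edge <- spec$edge_width * voxel_size
  Z <- array(rep(z, times = box * box), c(box, box, box))
  Y <- array(rep(rep(y, each = box), times = box), c(box, box, box))
  X <- array(rep(x, each = box * box), c(box, box, box))
  g <- array(0, c(box, box, box))
  # catalytic head: sphere
  r_head <- sqrt(X^2 + Y^2 + (Z - spec$head_height)^2)
  g <- g + soft_in(r_head - spec$head_diameter / 2, edge)
  # central stalk: vertical cylinder from c-ring top upward
  z0 <- spec$cring_height / 2
  z1 <- z0 + spec$central_stalk_length
  r_cyl <- sqrt(X^2 + Y^2)
  d_cs <- pmax(r_cyl - spec$central_stalk_radius,
               pmax(z0 - Z, Z - z1))
  g <- g + soft_in(d_cs, edge)
  # peripheral stalk: vertical cylinder at x = offset, running from the
  # membrane surface past the head equator to the head top (the stator
  # stalk and OSCP region hug the full height of the complex)
  ps_top <- spec$head_height + spec$head_diameter / 4
  r_ps <- sqrt((X - spec$peripheral_stalk_offset)^2 + Y^2)
  d_ps <- pmax(r_ps - spec$peripheral_stalk_radius,
               pmax(spec$membrane_thickness / 2 - Z, Z - ps_top))
  g <- g + soft_in(d_ps, edge)
  # c-ring: solid cylinder straddling the membrane midplane
  d_cr <- pmax(r_cyl - spec$cring_radius, abs(Z) - spec$cring_height / 2)
  g <- g + soft_in(d_cr, edge)
  density_volume(g * spec$protein_density, voxel_size)
}
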