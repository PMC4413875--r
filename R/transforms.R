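#' Rigid transform (intrinsic ZYZ Euler angles + shift)
#'
#' Rotations are parameterised by intrinsic ZYZ Euler angles
#' `(rot, tilt, psi)` in degrees, with rotation matrix
#' `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)` acting on `(x, y, z)` column
#' vectors and mapping the reference frame into the particle frame.  The
#' shift is in voxels, `(z, y, x)` order, applied after rotation.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @param shift length-3 numeric, voxels in `(z, y, x)` order.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rot = 0, tilt = 0, psi = 0, shift = c(0, 0, 0)) {
  stopifnot(length(shift) == 3L, all(is.finite(c(rot, tilt, psi, shift))))
  structure(list(euler = c(rot = as.numeric(rot), tilt = as.numeric(tilt),
                           psi = as.numeric(psi)),
                 shift = as.numeric(shift)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot=%.3f tilt=%.3f psi=%.3f  shift(z,y,x)=(%.3f, %.3f, %.3f)\n",
    x$euler[1], x$euler[2], x$euler[3], x$shift[1], x$shift[2], x$shift[3]))
  invisible(x)
}

rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}
rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

#' Rotation matrix of a transform
#'
#' @param t a [rigid_transform()], or a length-3 numeric of Euler angles
#'   `(rot, tilt, psi)` in degrees.
#' @return 3x3 rotation matrix acting on `(x, y, z)` column vectors.
#' @export
transform_matrix <- function(t) {
  e <- if (inherits(t, "rigid_transform")) t$euler else t
  rot_z(e[1]) %*% rot_y(e[2]) %*% rot_z(e[3])
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [transform_matrix()]: decomposes an orthonormal matrix into
#' intrinsic ZYZ angles in degrees, with `tilt` in `[0, 180]`.  At the
#' `tilt = 0` degeneracy `psi` is set to 0 and the full z-rotation goes
#' into `rot`.
#'
#' @param R 3x3 rotation matrix.
#' @return Named numeric `(rot, tilt, psi)`.
#' @export
matrix_to_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct)
  if (sin(tilt) > 1e-9) {
    rot <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else if (ct > 0) {
    rot <- atan2(R[2, 1], R[1, 1])
    psi <- 0
  } else {
    rot <- atan2(-R[2, 1], -R[1, 1]) # Rz(rot) Ry(180) Rz(0) convention
    psi <- 0
  }
  c(rot = rot, tilt = tilt, psi = psi) * 180 / pi
}

transform_from_matrix <- function(R, shift = c(0, 0, 0)) {
  e <- matrix_to_euler(R)
  rigid_transform(e[1], e[2], e[3], shift)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t1, t2)` applies `t2` first: the result maps
#' `x -> R1 (R2 x + s2) + s1`.  Shifts are carried in `(z, y, x)` voxel
#' order; rotation acts on the `(x, y, z)` components.
#'
#' @param t1,t2 [rigid_transform()] objects.
#' @return The composed [rigid_transform()].
#' @export
compose_transforms <- function(t1, t2) {
  R1 <- transform_matrix(t1)
  R2 <- transform_matrix(t2)
  s_xyz <- R1 %*% rev(t2$shift) + rev(t1$shift)
  transform_from_matrix(R1 %*% R2, rev(as.numeric(s_xyz)))
}

#' Invert a rigid transform
#'
#' `compose_transforms(invert_transform(t), t)` is the identity to
#' numerical precision.
#'
#' @param t a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  R <- transform_matrix(t)
  s_xyz <- -t(R) %*% rev(t$shift)
  transform_from_matrix(t(R), rev(as.numeric(s_xyz)))
}

# Total rotation angle (degrees) of a rotation matrix; used for tie-breaking.
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
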