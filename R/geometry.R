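# Crystal-packing geometry: re-insertion and angle measurements.

#' Re-insert an average into the tomogram frame
#'
#' Pastes the average at every particle position with the particle's
#' rotation (the inverse of the alignment parameters maps the reference
#' back into each particle's frame); overlaps are summed.  The result is
#' the visual packing model of the crystal.
#'
#' @param shape integer `(nz, ny, nx)` of the output volume.
#' @param table refined (or ground-truth) [particle_table()].
#' @param average cubic [density_volume()] (box must fit in `shape`).
#' @return A [density_volume()].
#' @export
reposition_average <- function(shape, table, average) {
  if (any(dim(average$grid) > shape))
    stop("average box larger than the tomogram")
  vol <- array(0, shape)
  d <- dim(average$grid)
  cb <- (d[1] - 1) / 2
  clipped <- 0
  for (i in seq_len(nrow(table))) {
    R <- transform_matrix(c(table$rot[i], table$tilt[i], table$psi[i]))
    pos <- c(table$x[i], table$y[i], table$z[i])
    if (any(pos < cb) || any(pos > rev(shape) - 1 - cb)) clipped <- clipped + 1
    paste_rotated(vol, average$grid, R, pos)
  }
  if (clipped > 0)
    warning(sprintf("%d particle paste(s) clipped at the volume edge", clipped))
  density_volume(array(vol, shape), average$voxel_size)
}

#' Pair and interface assignment
#'
#' Same-face mutual nearest neighbours within `same_face_cutoff` become
#' pairs; opposite-face mutual nearest neighbours within
#' `cross_face_cutoff` become cross-membrane interfaces.  Each particle
#' joins at most one pair and one interface; isolated particles stay
#' unassigned.
#'
#' @param table a [particle_table()].
#' @param voxel_size A/voxel, to convert table positions to Angstrom.
#' @param same_face_cutoff,cross_face_cutoff distance cutoffs in Angstrom.
#' @param axis_offset height (A) of the recorded particle position above
#'   the mid-membrane point along the particle axis; distances are
#'   measured between mid-membrane (c-ring level) points, where the
#'   cross-face contacts live.
#' @return List with data frames `pairs` (`i`, `j`, `distance`; both
#'   same-face) and `interfaces` (`up`, `down`, `distance`), holding row
#'   indices into `table`.
#' @export
find_pairs <- function(table, voxel_size = 1, same_face_cutoff = 130,
                       cross_face_cutoff = 80, axis_offset = 0) {
  pos <- particle_positions(table) * voxel_size
  if (axis_offset != 0)
    pos <- pos - particle_axes(table) * axis_offset
  n <- nrow(table)
  if (n < 2)
    return(list(pairs = data.frame(i = integer(), j = integer(),
                                   distance = numeric()),
                interfaces = data.frame(up = integer(), down = integer(),
                                        distance = numeric())))
  D <- as.matrix(stats::dist(pos))
  diag(D) <- Inf
  same <- outer(table$face, table$face, `==`)
  mutual_nn <- function(mask, cutoff) {
    Dm <- D
    Dm[!mask] <- Inf
    nn <- apply(Dm, 1, which.min)
    dd <- Dm[cbind(seq_len(n), nn)]
    keep <- which(dd <= cutoff & nn[nn] == seq_len(n) & seq_len(n) < nn)
    data.frame(i = keep, j = nn[keep], distance = dd[keep])
  }
  pr <- mutual_nn(same, same_face_cutoff)
  cr <- mutual_nn(!same, cross_face_cutoff)
  up_first <- table$face[cr$i] == "up"
  interfaces <- data.frame(up = ifelse(up_first, cr$i, cr$j),
                           down = ifelse(up_first, cr$j, cr$i),
                           distance = cr$distance)
  list(pairs = pr, interfaces = interfaces)
}

# Least-squares crystal plane through the particle mid-membrane points.
# Returns list(normal, center, basis) with basis = cbind(e1, e2, normal),
# e1 the in-plane projection of global +x.
fit_crystal_plane <- function(table, axis_offset_voxels = 0) {
  pos <- particle_positions(table)          # (x, y, z) voxels
  if (axis_offset_voxels != 0) {
    ax <- t(vapply(particle_matrices(table), function(R) as.numeric(R %*% c(0, 0, 1)),
                   numeric(3)))
    pos <- pos - ax * axis_offset_voxels
  }
  ctr <- colMeans(pos)
  X <- sweep(pos, 2, ctr)
  sv <- svd(X)
  if (nrow(pos) < 3 || sv$d[2] < 1e-6 * max(sv$d[1], 1))
    stop("degenerate plane fit: particle positions are collinear")
  nrm <- sv$v[, 3]
  if (nrm[3] < 0) nrm <- -nrm
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * nrm) * nrm
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  list(normal = nrm, center = ctr, basis = cbind(e1, e2, nrm))
}

particle_axes <- function(table) {
  t(vapply(particle_matrices(table),
           function(R) as.numeric(R %*% c(0, 0, 1)), numeric(3)))
}

#' Long-axis inclination relative to the crystal plane normal
#'
#' The particle long axis is the reference +z axis mapped through each
#' particle's rotation; down-face axes are folded to the common (up)
#' hemisphere.  Inclination is the angle between the folded axis and the
#' crystal-plane normal (least-squares plane through the particles'
#' mid-membrane points, or a supplied normal).
#'
#' @param table a [particle_table()].
#' @param plane_normal optional unit 3-vector `(x, y, z)`; fitted if `NULL`.
#' @param axis_offset height (voxels) of the recorded particle position
#'   above the mid-membrane point along the particle axis, used by the
#'   plane fit.
#' @return List: `per_particle` (degrees), `mean`, `sd`, `normal`.
#' @export
measure_inclination <- function(table, plane_normal = NULL, axis_offset = 0) {
  nrm <- plane_normal %||% fit_crystal_plane(table, axis_offset)$normal
  nrm <- nrm / sqrt(sum(nrm^2))
  ax <- particle_axes(table)
  dt <- as.numeric(ax %*% nrm)
  ang <- acos(pmin(1, abs(dt))) * 180 / pi
  list(per_particle = ang, mean = mean(ang), sd = sd(ang), normal = nrm)
}

#' Angle between the long axes of paired monomers
#'
#' @param pairs `pairs` data frame from [find_pairs()].
#' @param table a [particle_table()].
#' @return List: `per_pair` (degrees, folded to 0..90), `mean`, `sd`.
#' @export
measure_pair_angle <- function(pairs, table) {
  ax <- particle_axes(table)
  ang <- vapply(seq_len(nrow(pairs)), function(r) {
    d <- sum(ax[pairs$i[r], ] * ax[pairs$j[r], ])
    acos(pmin(1, abs(d))) * 180 / pi
  }, 0)
  list(per_pair = ang, mean = mean(ang), sd = sd(ang))
}

#' In-plane rotation between opposite-face partners
#'
#' Maps each interface's down particle through the 180-degree flip about
#' the in-plane reference axis (`basis[,1]`) and reports the residual
#' rotation about the plane normal between the partners, folded to
#' `[0, 180)`.
#'
#' @param interfaces `interfaces` data frame from [find_pairs()].
#' @param table a [particle_table()].
#' @param basis 3x3 plane basis `cbind(e1, e2, normal)` (from the plane
#'   fit if `NULL`); the flip axis is `e1`.
#' @param axis_offset passed to the plane fit (voxels).
#' @return List: `per_interface` (degrees), `mean`, `sd`, plus
#'   `dominant` (mean of the largest cluster of values within 30 degrees
#'   of the median) and `dominant_fraction`.  The spin angle of a
#'   refined particle can occasionally lock into a wrong discrete
#'   attractor, making the distribution bimodal; the dominant-mode mean
#'   is then the meaningful location estimate (it equals the plain mean
#'   for a clean refinement).
#' @export
measure_interface_rotation <- function(interfaces, table, basis = NULL,
                                       axis_offset = 0) {
  B <- basis %||% fit_crystal_plane(table, axis_offset)$basis
  Rmats <- particle_matrices(table)
  flip <- rot_x(180)
  ang <- vapply(seq_len(nrow(interfaces)), function(r) {
    Ru <- Rmats[[interfaces$up[r]]]
    Rd <- Rmats[[interfaces$down[r]]]
    M <- t(B) %*% Rd %*% t(Ru) %*% B %*% flip
    a <- atan2(M[2, 1] - M[1, 2], M[1, 1] + M[2, 2]) * 180 / pi
    a <- a %% 360
    min(a, 360 - a)
  }, 0)
  keep <- abs(ang - stats::median(ang)) <= 30
  list(per_interface = ang, mean = mean(ang), sd = sd(ang),
       dominant = if (any(keep)) mean(ang[keep]) else mean(ang),
       dominant_fraction = mean(keep))
}

#' Trace the membrane zigzag and measure its kink
#'
#' Averages the tomogram over the row (y) direction, ridge-traces the
#' membrane-band density per x column inside a z band, and fits the
#' piecewise-linear membrane profile with breakpoints at the known fold
#' vertices (`phase + m * period` along x): each vertex height is
#' estimated from the ridge columns within `vertex_window` of the vertex
#' (where the rotor-ring rows put density on the membrane midplane — the
#' only membrane feature that survives the missing wedge in a
#' reconstruction), segment directions run between adjacent vertex
#' heights, and the kink is the angle between adjacent segment
#' directions.
#'
#' @param tomogram a [density_volume()].
#' @param period fold-vertex spacing along x, Angstrom.
#' @param phase x position (A) of a fold vertex.
#' @param z_mid mean membrane midplane, voxel z.
#' @param band half-width (A) of the z search band around `z_mid`.
#' @param vertex_window half-width (A) of the x window used to estimate
#'   each vertex height from the ridge.
#' @param smooth_sigma Gaussian smoothing sd (A) applied before tracing;
#'   0 for none.
#' @param xy_margin fraction of the field trimmed at each x/y edge.
#' @return List: `per_vertex` kink angles (degrees), `mean` (from the
#'   alternation fit over all vertex heights), `sd` (over per-vertex
#'   kinks), `segment_angles` (degrees, signed), `vertices` (data frame
#'   x/z in A), `ridge` (data frame x/z in A).
#' @export
trace_membrane_kink <- function(tomogram, period, phase, z_mid,
                                band = 55, vertex_window = 12,
                                smooth_sigma = 8, xy_margin = 0.15) {
  vs <- tomogram$voxel_size
  vol <- gaussian_smooth_volume(tomogram, smooth_sigma)
  d <- dim(vol$grid)
  ys <- seq(max(1, round(d[2] * xy_margin)), min(d[2], round(d[2] * (1 - xy_margin))))
  xs <- seq(max(1, round(d[3] * xy_margin)), min(d[3], round(d[3] * (1 - xy_margin))))
  prof <- apply(vol$grid[, ys, xs, drop = FALSE], c(1, 3), mean)  # (z, x)
  zb <- which(abs((seq_len(d[1]) - 1) - z_mid) <= band / vs)
  ridge <- rep(NA_real_, length(xs))
  lost <- integer()
  for (j in seq_along(xs)) {
    col <- prof[zb, j]
    if (!any(is.finite(col)) || max(col) <= 1e-9) { lost <- c(lost, xs[j]); next }
    k <- which.max(col)
    off <- if (k > 1 && k < length(col))
      parabolic_offset(col[k - 1], col[k], col[k + 1]) else 0
    ridge[j] <- (zb[k] - 1 + off) * vs
  }
  if (length(lost))
    stop("membrane ridge lost (no density in band) at x columns: ",
         paste(head(lost, 10), collapse = ", "))
  xA <- (xs - 1) * vs
  m_first <- ceiling((min(xA) + vertex_window - phase) / period)
  m_last <- floor((max(xA) - vertex_window - phase) / period)
  if (m_last - m_first < 2) stop("field of view spans too few fold vertices")
  ms <- m_first:m_last
  verts <- phase + ms * period
  zv <- vapply(verts, function(xv) {
    sel <- abs(xA - xv) <= vertex_window & is.finite(ridge)
    if (sum(sel) < 1) return(NA_real_)
    mean(ridge[sel])
  }, 0)
  ok <- is.finite(zv)
  if (sum(ok) < 3) stop("too few vertex heights recovered from the ridge")
  # global alternation fit: vertex heights follow z0 +/- s * period / 2
  tv <- (-1)^ms * period / 2
  fit <- lm(zv[ok] ~ tv[ok])
  kink_global <- 2 * atan(abs(coef(fit)[2])) * 180 / pi
  # per-vertex kinks from adjacent segment directions
  ang <- atan(diff(zv) / period) * 180 / pi
  kinks <- abs(diff(ang))
  kinks <- kinks[is.finite(kinks)]
  list(per_vertex = kinks, mean = unname(kink_global),
       sd = if (length(kinks) > 1) sd(kinks) else NA_real_,
       segment_angles = ang[is.finite(ang)],
       vertices = data.frame(x = verts, z = zv),
       ridge = data.frame(x = xA, z = ridge))
}

#' Membrane kink from particle row heights
#'
#' Estimates the zigzag kink of the membrane from the rotor-ring (mid-
#' membrane) heights of the particles in a refined (or ground-truth)
#' table: each particle's c-ring point is the recorded position minus
#' `axis_offset` along its long axis; particles are assigned to fold rows
#' by their x position, row heights are averaged, and the piecewise-
#' linear (alternating-slope) membrane profile is fitted through the row
#' heights.  In a single-axis reconstruction the lipid slab itself lies
#' almost entirely inside the missing wedge (its local normals stay
#' within 30 degrees of the beam), so the membrane-embedded protein rows
#' are the reliable anchor for the membrane geometry.
#'
#' @param table a [particle_table()].
#' @param period fold-row spacing along x, Angstrom.
#' @param phase x position (A) of a fold row.
#' @param voxel_size A/voxel.
#' @param axis_offset height (A) of the recorded position above the
#'   mid-membrane point along the particle axis.
#' @return List: `per_vertex` kinks (degrees, from adjacent segment
#'   directions), `mean` (alternation fit), `sd`, `rows` (data frame
#'   m/x/z/n).
#' @export
measure_kink_from_rows <- function(table, period, phase, voxel_size,
                                   axis_offset = 80) {
  pos <- particle_positions(table) * voxel_size
  pos <- pos - particle_axes(table) * axis_offset
  m <- round((pos[, 1] - phase) / period)
  rows <- split(seq_len(nrow(table)), m)
  if (length(rows) < 3) stop("too few particle rows to measure a kink")
  ms <- as.integer(names(rows))
  zv <- vapply(rows, function(i) mean(pos[i, 3]), 0)
  nv <- lengths(rows)
  tv <- (-1)^ms * period / 2
  fit <- lm(zv ~ tv, weights = nv)
  kink <- 2 * atan(abs(coef(fit)[2])) * 180 / pi
  ord <- order(ms)
  ang <- atan(diff(zv[ord]) / (period * diff(ms[ord]))) * 180 / pi
  kinks <- abs(diff(ang))
  list(per_vertex = kinks, mean = unname(kink),
       sd = if (length(kinks) > 1) sd(kinks) else NA_real_,
       rows = data.frame(m = ms[ord], x = phase + ms[ord] * period,
                         z = zv[ord], n = nv[ord]))
}

#' Predicted dimer angle from the membrane kink
#'
#' Two monomers joining at a shared fold each contribute one kink, so the
#' predicted angle between their long axes is twice the per-monomer kink.
#'
#' @param kink_kappa per-monomer membrane kink in degrees, in `[0, 90)`.
#' @return Predicted dimer angle in degrees.
#' @export
predict_dimer_angle <- function(kink_kappa) {
  stopifnot(kink_kappa >= 0, kink_kappa < 90)
  2 * kink_kappa
}

#' Height of the catalytic-head band above the membrane midplane
#'
#' Segments the up-face head band (z between `band[1]` and `band[2]`
#' Angstrom above `z_mid`), keeps density above the given quantile, and
#' returns the density-weighted centroid height in Angstrom.
#'
#' @param tomogram a [density_volume()].
#' @param z_mid membrane midplane, voxel z.
#' @param band numeric(2), z band above the midplane in Angstrom.
#' @param threshold_quantile density quantile (within the band) below
#'   which voxels are ignored.
#' @param smooth_resolution low-pass (A) applied first.
#' @param xy_margin fraction trimmed at the x/y edges.
#' @return Centroid height in Angstrom.
#' @export
measure_head_height <- function(tomogram, z_mid, band = c(100, 220),
                                threshold_quantile = 0.9,
                                smooth_resolution = 40, xy_margin = 0.15) {
  vs <- tomogram$voxel_size
  vol <- lowpass_volume(tomogram, smooth_resolution)
  d <- dim(vol$grid)
  ys <- seq(max(1, round(d[2] * xy_margin)), min(d[2], round(d[2] * (1 - xy_margin))))
  xs <- seq(max(1, round(d[3] * xy_margin)), min(d[3], round(d[3] * (1 - xy_margin))))
  hz <- ((seq_len(d[1]) - 1) - z_mid) * vs
  zb <- which(hz >= band[1] & hz <= band[2])
  sub <- vol$grid[zb, ys, xs, drop = FALSE]
  thr <- stats::quantile(sub, threshold_quantile)
  w <- pmax(sub - thr, 0)
  if (sum(w) <= 0) stop("no density above threshold in the head band")
  zw <- apply(w, 1, sum)
  sum(zw * hz[zb]) / sum(zw)
}

#' Assemble a geometry report
#'
#' Convenience wrapper running the plane fit, pairing and all angle
#' measurements on a refined (or ground-truth) particle table.
#'
#' @param table a [particle_table()].
#' @param voxel_size A/voxel.
#' @param axis_offset height (A) of the recorded position above the
#'   mid-membrane point along the particle axis.
#' @param same_face_cutoff,cross_face_cutoff pairing cutoffs, Angstrom.
#' @return List of class `geometry_report`.
#' @export
geometry_report <- function(table, voxel_size, axis_offset = 80,
                            same_face_cutoff = 130, cross_face_cutoff = 80) {
  off_vox <- axis_offset / voxel_size
  plane <- fit_crystal_plane(table, off_vox)
  assign <- find_pairs(table, voxel_size, same_face_cutoff, cross_face_cutoff,
                       axis_offset = axis_offset)
  inc <- measure_inclination(table, plane$normal)
  pa <- measure_pair_angle(assign$pairs, table)
  ir <- measure_interface_rotation(assign$interfaces, table, plane$basis)
  structure(list(plane = plane, pairs = assign$pairs,
                 interfaces = assign$interfaces,
                 inclination = inc, pair_angle = pa,
                 interface_rotation = ir),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("<geometry_report>\n")
  cat(sprintf("  particles: %d   pairs: %d   interfaces: %d\n",
              length(x$inclination$per_particle), nrow(x$pairs),
              nrow(x$interfaces)))
  cat(sprintf("  inclination       : %6.2f +/- %.2f deg\n",
              x$inclination$mean, x$inclination$sd))
  cat(sprintf("  pair angle        : %6.2f +/- %.2f deg\n",
              x$pair_angle$mean, x$pair_angle$sd))
  cat(sprintf("  interface rotation: %6.2f +/- %.2f deg\n",
              x$interface_rotation$mean, x$interface_rotation$sd))
  invisible(x)
}
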