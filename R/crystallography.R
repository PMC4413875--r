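# Electron-crystallographic processing of tomographic z-slices.

#' Projection image
#'
#' @param pixels numeric matrix indexed `[ix, iy]` (0-based pixel centres).
#' @param pixel_size Angstrom per pixel (> 0).
#' @param z_range provenance: physical z range (A) of the source slices.
#' @return Object of class `projection_image`.
#' @export
projection_image <- function(pixels, pixel_size, z_range = c(NA, NA)) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size, z_range = z_range),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d px @ %.3f A/px (z %s..%s A)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              format(x$z_range[1]), format(x$z_range[2])))
  invisible(x)
}

#' Project tomographic z-slices
#'
#' Extracts the voxel layers spanning `[z_min, z_max)` (Angstrom along the
#' tomogram z axis) and returns either one projection image per layer
#' (count = `round((z_max - z_min) / voxel_size)`) or their sum.
#'
#' @param tomogram a [density_volume()].
#' @param z_min,z_max physical z range in Angstrom.
#' @param per_slice return one image per layer (`TRUE`) or the summed
#'   projection (`FALSE`, default).
#' @return A list of [projection_image()]s, or a single one.
#' @export
slice_projections <- function(tomogram, z_min, z_max, per_slice = FALSE) {
  vs <- tomogram$voxel_size
  count <- round((z_max - z_min) / vs)
  if (count < 1) stop("empty z range")
  i0 <- round(z_min / vs) + 1
  layers <- i0:(i0 + count - 1)
  d <- dim(tomogram$grid)
  if (any(layers < 1) || any(layers > d[1]))
    stop("z range outside the volume")
  imgs <- lapply(layers, function(iz)
    projection_image(t(tomogram$grid[iz, , ]), vs,
                     z_range = (c(iz - 1, iz) - 0.5) * vs))
  if (per_slice) return(imgs)
  acc <- Reduce(`+`, lapply(imgs, `[[`, "pixels"))
  projection_image(acc, vs, z_range = c(z_min, z_max))
}

# direct DFT of an image at arbitrary spatial frequencies (cycles/pixel);
# q: matrix with columns qx, qy.  Exact sub-pixel sampling of the transform.
image_dft <- function(pixels, q) {
  nx <- nrow(pixels); ny <- ncol(pixels)
  vapply(seq_len(nrow(q)), function(i) {
    ex <- exp(-2i * pi * q[i, 1] * (0:(nx - 1)))
    ey <- exp(-2i * pi * q[i, 2] * (0:(ny - 1)))
    as.complex((ex %*% pixels %*% ey)[1, 1])
  }, complex(1))
}

bilinear_2d <- function(img, xq, yq) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(xq); y0 <- floor(yq)
  fx <- xq - x0; fy <- yq - y0
  gv <- function(ix, iy) {
    ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
    v <- numeric(length(ix))
    v[ok] <- img[cbind(ix[ok] + 1, iy[ok] + 1)]
    v
  }
  gv(x0, y0) * (1 - fx) * (1 - fy) + gv(x0 + 1, y0) * fx * (1 - fy) +
    gv(x0, y0 + 1) * (1 - fx) * fy + gv(x0 + 1, y0 + 1) * fx * fy
}

# Lagrange (Gauss) reduction: shortest pair of lattice basis vectors.
reduce_basis_2d <- function(G) {
  v1 <- G[, 1]; v2 <- G[, 2]
  for (it in 1:50) {
    if (sum(v2^2) < sum(v1^2)) { tmp <- v1; v1 <- v2; v2 <- tmp }
    r <- round(sum(v1 * v2) / sum(v1^2))
    if (r == 0) break
    v2 <- v2 - r * v1
  }
  cbind(v1, v2)
}

#' Detect the 2D lattice of a crystal image
#'
#' Power-spectrum peak search (Hann-windowed, zero-padded FFT) with
#' extreme-value significance thresholding, consensus selection of the
#' reciprocal basis (the candidate pair of independent peak vectors that
#' indexes the most spectral power), least-squares refinement of the
#' basis over all indexed peaks, Lagrange reduction to the two shortest
#' reciprocal vectors, and a final direct refinement maximising the
#' summed transform amplitude at the predicted reflection positions.
#' Cell parameters are reported with `a >= b` and `gamma` folded into
#' `[90, 180)` (the lattice is invariant under `b -> -b`).
#'
#' @param image a [projection_image()].
#' @param pad zero-padding factor for the spectrum.
#' @param max_peaks cap on the number of peaks used.
#' @return List of class `lattice_fit`: `cell` (a [unit_cell_2d()]),
#'   `recip` (2x2 matrix, columns a* and b* in cycles/pixel), `real_px`
#'   (real-space basis, pixels), `peaks` (data frame), `pixel_size`.
#' @export
detect_lattice <- function(image, pad = 4, max_peaks = 40) {
  img <- image$pixels
  nx <- nrow(img); ny <- ncol(img)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  w <- outer(hann(nx), hann(ny))
  img0w <- (img - mean(img)) * w
  big_n <- nextn(pad * max(nx, ny), c(2, 3, 5))
  big <- matrix(0, big_n, big_n)
  big[1:nx, 1:ny] <- img0w
  P <- Mod(fft(big))^2
  fi <- freq_index(big_n)
  RAD <- sqrt(outer(fi^2, fi^2, `+`))
  rmin <- 2.5 * pad
  band <- RAD > rmin & RAD <= big_n / 2
  mean_bg <- mean(P[band])
  thr <- mean_bg * (log(sum(band)) + 8)   # extreme-value level for noise
  cand <- which(P > thr & band)
  if (!length(cand)) stop("lattice not found: no significant spectral peaks")
  cand <- cand[order(P[cand], decreasing = TRUE)]
  sep <- 2.5 * pad
  keep <- matrix(numeric(0), ncol = 2)
  vals <- numeric(0)
  for (ci in cand) {
    co <- arrayInd(ci, dim(P))
    qi <- c(fi[co[1]], fi[co[2]])
    if (nrow(keep) &&
        (any(sqrt(rowSums(sweep(keep, 2, qi)^2)) < sep) ||
         any(sqrt(rowSums(sweep(keep, 2, -qi)^2)) < sep))) next
    keep <- rbind(keep, qi)
    vals <- c(vals, P[ci])
    if (nrow(keep) >= max_peaks) break
  }
  # power-centroid sub-pixel refinement over a window around each maximum
  wrapi <- function(i) ((round(i) %% big_n) + big_n) %% big_n + 1
  wr <- round(1.5 * pad)
  off <- -wr:wr
  ref <- t(apply(keep, 1, function(qi) {
    sub <- P[cbind(rep(wrapi(qi[1] + off), times = length(off)),
                   rep(wrapi(qi[2] + off), each = length(off)))]
    sub <- matrix(sub, length(off), length(off))
    qi + c(sum(off * rowSums(sub)), sum(off * colSums(sub))) / sum(sub)
  }))
  # discard peaks whose centroid drifted onto the central envelope
  drift <- sqrt(rowSums((ref - keep)^2))
  good <- drift <= 2 & sqrt(rowSums(ref^2)) > rmin
  ref <- ref[good, , drop = FALSE]; vals <- vals[good]
  if (!nrow(ref)) stop("lattice not found: no significant spectral peaks")
  flipme <- ref[, 2] < 0 | (abs(ref[, 2]) < 1e-9 & ref[, 1] < 0)
  ref[flipme, ] <- -ref[flipme, ]
  q <- ref / big_n                       # cycles / pixel
  amp <- sqrt(vals)
  # consensus basis: the independent peak pair indexing the most power;
  # only peaks carrying real power may serve as basis candidates
  n_base <- min(nrow(q), 15)
  best <- NULL; best_score <- -Inf
  for (i in seq_len(n_base)) for (j in seq_len(n_base)) {
    if (i == j) next
    if (vals[i] < 0.05 * max(vals) || vals[j] < 0.05 * max(vals)) next
    v1 <- q[i, ]; v2 <- q[j, ]
    cr <- abs(v1[1] * v2[2] - v1[2] * v2[1]) /
      (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    if (!is.finite(cr) || cr < 0.17) next
    G0 <- cbind(v1, v2)
    hk <- t(round(solve(G0, t(q))))
    resid <- sqrt(rowSums((q - t(G0 %*% t(hk)))^2))
    tol <- max(0.15 * sqrt(min(sum(v1^2), sum(v2^2))), 1.2 / big_n)
    ok <- resid < tol & rowSums(abs(hk)) > 0
    score <- sum(amp[ok]) - 1e-6 * (sum(v1^2) + sum(v2^2))
    if (score > best_score) { best_score <- score; best <- G0 }
  }
  if (is.null(best))
    stop("lattice not found: fewer than two independent spectral peaks")
  # index all peaks against the consensus basis and LS-refine it (twice)
  G <- best
  for (pass in 1:2) {
    hk <- t(round(solve(G, t(q))))
    resid <- sqrt(rowSums((q - t(G %*% t(hk)))^2))
    tol <- max(0.15 * sqrt(min(colSums(G^2))), 1.2 / big_n)
    ok <- resid < tol & rowSums(abs(hk)) > 0
    if (sum(ok) < 2) break
    H <- hk[ok, , drop = FALSE]; Q <- q[ok, , drop = FALSE]
    G <- t(solve(t(H) %*% H, t(H) %*% Q))
  }
  G <- reduce_basis_2d(G)
  # real-space refinement: with few lattice repeats the spectral lobes
  # are interference-broadened (percent-level biases), whereas the
  # per-unit-cell cross-correlation nodes are sharp.  Fit the lattice
  # vectors through the node positions by least squares.
  A <- t(solve(G))                       # real-space basis, pixels
  nd <- try(locate_lattice_nodes(img, A), silent = TRUE)
  if (!inherits(nd, "try-error") && nrow(nd) >= 6) {
    nd <- nd[nd$cc >= 0.3 * max(nd$cc), , drop = FALSE]
    X <- cbind(1, nd$m, nd$n)
    cf <- solve(t(X) %*% X, t(X) %*% cbind(nd$x + nd$dx, nd$y + nd$dy))
    A <- t(cf[2:3, ])                    # columns a, b in pixels
    G <- t(solve(A))
  }
  la <- sqrt(sum(A[, 1]^2)) * image$pixel_size
  lb <- sqrt(sum(A[, 2]^2)) * image$pixel_size
  gamma <- acos(max(-1, min(1, sum(A[, 1] * A[, 2]) /
                              sqrt(sum(A[, 1]^2) * sum(A[, 2]^2))))) * 180 / pi
  if (gamma < 90) gamma <- 180 - gamma
  if (lb > la) G <- G[, 2:1]             # convention: a is the longer axis
  A <- t(solve(G))
  cell <- unit_cell_2d(max(la, lb), min(la, lb), gamma)
  hk_all <- t(round(solve(G, t(q))))
  structure(list(cell = cell, recip = G, real_px = A,
                 peaks = data.frame(qx = q[, 1], qy = q[, 2],
                                    h = hk_all[, 1], k = hk_all[, 2],
                                    power = vals),
                 pixel_size = image$pixel_size),
            class = "lattice_fit")
}

#' @export
print.lattice_fit <- function(x, ...) {
  cat(sprintf("<lattice_fit> a = %.2f A, b = %.2f A, gamma = %.2f deg (%d peaks)\n",
              x$cell$a, x$cell$b, x$cell$gamma, nrow(x$peaks)))
  invisible(x)
}

# amplitude and off-lattice background of one reflection (exact DFT)
reflection_measure <- function(pixels, q, bg_radius_px = 4, n_bg = 8) {
  n <- max(dim(pixels))
  amp <- Mod(image_dft(pixels, matrix(q, ncol = 2)))
  th <- 2 * pi * (seq_len(n_bg) - 0.5) / n_bg
  offs <- cbind(q[1] + bg_radius_px / n * cos(th),
                q[2] + bg_radius_px / n * sin(th))
  bg <- mean(Mod(image_dft(pixels, offs)))
  c(amp = amp, bg = bg)
}

#' Extract structure factors from a crystal image
#'
#' Reads amplitude and phase at every reciprocal-lattice position within
#' the resolution limit by exact (sub-pixel) Fourier sampling; the
#' background is the mean amplitude on an off-lattice ring around each
#' reflection, and `snr = amplitude / background`.  One Friedel
#' representative per reflection is stored (`h > 0`, or `h = 0, k > 0`).
#'
#' @param image a [projection_image()].
#' @param lattice a `lattice_fit` from [detect_lattice()] (or a list with
#'   a 2x2 `recip` matrix in cycles/pixel).
#' @param resolution_limit in Angstrom (default 30).
#' @return Data frame of class `structure_factor_set` with columns `h`,
#'   `k`, `amp`, `phase` (degrees), `background`, `snr`; attributes
#'   `recip`, `pixel_size`, `resolution_limit`.
#' @export
extract_structure_factors <- function(image, lattice, resolution_limit = 30) {
  G <- lattice$recip
  px <- image$pixel_size
  qlim <- px / resolution_limit          # cycles/pixel
  hmax <- ceiling(qlim / sqrt(sum(G[, 1]^2)))
  kmax <- ceiling(qlim / sqrt(sum(G[, 2]^2)))
  hk <- expand.grid(h = -hmax:hmax, k = -kmax:kmax)
  hk <- hk[hk$h > 0 | (hk$h == 0 & hk$k > 0), ]
  q <- t(G %*% t(as.matrix(hk)))
  keep <- sqrt(rowSums(q^2)) <= qlim + 1e-12
  hk <- hk[keep, , drop = FALSE]; q <- q[keep, , drop = FALSE]
  img0 <- image$pixels - mean(image$pixels)
  F <- image_dft(img0, q)
  bg <- vapply(seq_len(nrow(q)), function(i)
    reflection_measure(img0, q[i, ])["bg"], 0)
  out <- data.frame(h = hk$h, k = hk$k, amp = Mod(F),
                    phase = Arg(F) * 180 / pi, background = bg,
                    snr = Mod(F) / pmax(bg, 1e-300))
  attr(out, "recip") <- G
  attr(out, "pixel_size") <- px
  attr(out, "resolution_limit") <- resolution_limit
  class(out) <- c("structure_factor_set", "data.frame")
  out
}

#' Write structure factors as TSV
#' @param sfset a `structure_factor_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_factors <- function(sfset, path) {
  write.table(as.data.frame(sfset), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Fourier synthesis of a projection map
#'
#' Real-space map from an indexed reflection list (p1, no symmetry):
#' `sum over reflections and Friedel mates of amp * cos(2 pi q.r + phase)`.
#'
#' @param sfset a `structure_factor_set` (carries the reciprocal basis).
#' @param map_size integer (nx, ny) of the output, defaults to a square
#'   map of the source size implied by the basis.
#' @param pixel_size A/pixel of the output (defaults to the source's).
#' @return A [projection_image()].
#' @export
synthesize_projection_map <- function(sfset, map_size = c(128, 128),
                                      pixel_size = NULL) {
  if (!nrow(sfset)) stop("empty structure factor set")
  G <- attr(sfset, "recip")
  pixel_size <- pixel_size %||% attr(sfset, "pixel_size")
  nx <- map_size[1]; ny <- map_size[2]
  X <- matrix(0:(nx - 1), nx, ny)
  Y <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  map <- matrix(0, nx, ny)
  for (i in seq_len(nrow(sfset))) {
    q <- G %*% c(sfset$h[i], sfset$k[i])
    map <- map + 2 * sfset$amp[i] *
      cos(2 * pi * (q[1] * X + q[2] * Y) + sfset$phase[i] * pi / 180)
  }
  projection_image(map, pixel_size)
}

#' Plane-group phase residual (p1 / p2)
#'
#' For p2 the reflection phases must be 0 or 180 degrees at the correct
#' phase origin; the residual is the snr-weighted mean absolute deviation
#' from the nearer of the two, minimised over the phase origin by a grid
#' search plus local refinement.  p1 imposes nothing (residual 0).
#'
#' @param sfset a `structure_factor_set`.
#' @param group `"p1"` or `"p2"`.
#' @param snr_min only reflections with `snr >= snr_min` are used.
#' @param grid_n origin grid per axis.
#' @return List: `residual` (degrees), `origin` (fractional cell coords),
#'   `n_reflections`.
#' @export
plane_group_residual <- function(sfset, group = c("p2", "p1"), snr_min = 3,
                                 grid_n = 36) {
  group <- match.arg(group)
  sel <- sfset$snr >= snr_min
  if (sum(sel) < 3)
    stop("too few significant reflections for a plane-group test")
  if (group == "p1")
    return(list(residual = 0, origin = c(0, 0), n_reflections = sum(sel)))
  h <- sfset$h[sel]; k <- sfset$k[sel]
  ph <- sfset$phase[sel]; w <- sfset$amp[sel]   # amplitude-weighted residual
  res_at <- function(o) {
    p2 <- ph - 360 * (h * o[1] + k * o[2])
    dev <- abs(((p2 + 90) %% 180) - 90)
    sum(w * dev) / sum(w)
  }
  gr <- (seq_len(grid_n) - 1) / grid_n
  best <- c(0, 0); bestv <- Inf
  for (u in gr) for (v in gr) {
    r <- res_at(c(u, v))
    if (r < bestv) { bestv <- r; best <- c(u, v) }
  }
  opt <- optim(best, res_at, method = "Nelder-Mead",
               control = list(reltol = 1e-10))
  list(residual = opt$value, origin = opt$par %% 1,
       n_reflections = sum(sel))
}

#' Axial reflection amplitude ratio
#'
#' Ratio of summed amplitudes of the `(0, k)` family to the `(h, 0)`
#' family over the given orders.  Continuous density along the `a`
#' (row) direction concentrates power in the `(0, k)` reflections, so a
#' large ratio indicates line-like density along one lattice direction
#' only.
#'
#' @param sfset a `structure_factor_set`.
#' @param orders reflection orders to sum (default 1:3).
#' @return Numeric ratio.
#' @export
axial_amplitude_ratio <- function(sfset, orders = 1:3) {
  num <- sum(sfset$amp[sfset$h == 0 & abs(sfset$k) %in% orders])
  den <- sum(sfset$amp[sfset$k == 0 & abs(sfset$h) %in% orders])
  num / max(den, 1e-300)
}

# Locate per-unit-cell cross-correlation nodes of a crystal image.
# Builds a Fourier-filtered reference (lattice-point neighbourhoods only),
# windows it to roughly one cell, cross-correlates, anchors the node grid
# at the global maximum, and refines each node peak to sub-pixel.
# `A` is the real-space lattice basis in pixels (columns a, b).  Returns a
# data frame (m, n, x, y, dx, dy, cc): ideal position (x, y) and measured
# displacement (dx, dy).
locate_lattice_nodes <- function(img, A, reference_radius = 1.5,
                                 search_radius = NULL) {
  nx <- nrow(img); ny <- ncol(img)
  img0 <- img - mean(img)
  G <- t(solve(A))
  F <- fft(img0)
  fx <- freq_index(nx); fy <- freq_index(ny)
  hmax <- ceiling(0.45 / sqrt(sum(G[, 1]^2)))
  kmax <- ceiling(0.45 / sqrt(sum(G[, 2]^2)))
  mask <- matrix(FALSE, nx, ny)
  IX <- matrix(fx, nx, ny); IY <- matrix(rep(fy, each = nx), nx, ny)
  for (h in -hmax:hmax) for (k in -kmax:kmax) {
    if (h == 0 && k == 0) next
    q <- G %*% c(h, k)
    if (sqrt(sum(q^2)) > 0.45) next
    mask <- mask | ((IX / nx - q[1])^2 + (IY / ny - q[2])^2 <
                      (reference_radius / nx)^2 + (reference_radius / ny)^2)
  }
  Ff <- F; Ff[!mask] <- 0
  ref_full <- Re(fft(Ff, inverse = TRUE)) / (nx * ny)
  # compact reference patch: narrow enough that the correlation peak of a
  # node is insensitive to whether its neighbour cells exist (edge cells)
  sig <- 0.35 * min(sqrt(colSums(A^2)))
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  PX <- matrix(0:(nx - 1), nx, ny)
  PY <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  W <- exp(-((PX - cx)^2 + (PY - cy)^2) / (2 * sig^2))
  patch <- ref_full * W
  CC <- Re(fft(fft(img0) * Conj(fft(patch)), inverse = TRUE)) / (nx * ny)
  anchor_i <- arrayInd(which.max(CC), dim(CC)) - 1
  anchor <- c(cx, cy) + ifelse(anchor_i > c(nx, ny) / 2,
                               anchor_i - c(nx, ny), anchor_i)
  if (is.null(search_radius))
    search_radius <- 0.25 * min(sqrt(colSums(A^2)))
  # CC index (i, j) corresponds to the patch shifted by the integer
  # vector s = (i-1, j-1) (mod wrap), i.e. a patch centre at (cx + sx,
  # cy + sy) — a half-integer position grid when the image is even.
  nodes <- list()
  span <- ceiling((nx + ny) / min(sqrt(colSums(A^2))))
  rng <- -round(search_radius):round(search_radius)
  for (m in -span:span) for (n in -span:span) {
    p <- anchor + m * A[, 1] + n * A[, 2]
    if (p[1] < search_radius + 2 || p[1] > nx - search_radius - 3 ||
        p[2] < search_radius + 2 || p[2] > ny - search_radius - 3) next
    sx <- round(p[1] - cx) + rng         # integer patch shifts to sample
    sy <- round(p[2] - cy) + rng
    sub <- CC[cbind(rep((sx %% nx) + 1, times = length(sy)),
                    rep((sy %% ny) + 1, each = length(sx)))]
    sub <- matrix(sub, length(sx), length(sy))
    bi <- arrayInd(which.max(sub), dim(sub))
    ox <- if (bi[1] > 1 && bi[1] < nrow(sub))
      parabolic_offset(sub[bi[1] - 1, bi[2]], sub[bi[1], bi[2]],
                       sub[bi[1] + 1, bi[2]]) else 0
    oy <- if (bi[2] > 1 && bi[2] < ncol(sub))
      parabolic_offset(sub[bi[1], bi[2] - 1], sub[bi[1], bi[2]],
                       sub[bi[1], bi[2] + 1]) else 0
    nodes[[length(nodes) + 1]] <-
      data.frame(m = m, n = n, x = p[1], y = p[2],
                 dx = cx + sx[bi[1]] + ox - p[1],
                 dy = cy + sy[bi[2]] + oy - p[2],
                 cc = sub[bi[1], bi[2]])
  }
  if (!length(nodes)) return(data.frame())
  nd <- do.call(rbind, nodes)
  # drop peaks clamped at the search boundary or far below the median
  ok <- pmax(abs(nd$dx), abs(nd$dy)) < search_radius - 0.5 &
    nd$cc > 0.2 * max(nd$cc)
  nd[ok, , drop = FALSE]
}

#' Correct smooth lattice distortions (unbending)
#'
#' Builds a Fourier-filtered reference keeping only the neighbourhoods of
#' the reciprocal-lattice points, locates the cross-correlation peak of
#' every unit cell against a windowed reference patch, interpolates the
#' per-cell displacements from the ideal lattice into a smooth field and
#' resamples the image against it.  If the image shows no significant
#' lattice (snr of the (1,0) and (0,1) reflections below 3) or fewer than
#' 4 correlation peaks are found, unbending is skipped with a warning.
#' The corrected image is only returned if it does not degrade the (1,0)
#' peak-to-background ratio; otherwise the input is passed through.
#'
#' @param image a [projection_image()].
#' @param lattice a `lattice_fit`.
#' @param reference_radius Fourier mask radius around each lattice point,
#'   in index pixels of the image transform.
#' @param search_radius real-space peak search radius in pixels (default:
#'   a quarter of the shorter lattice repeat).
#' @return List of class `unbend_result`: `image` (corrected
#'   [projection_image()]), `nodes` (per-cell displacements, pixels),
#'   `rms_displacement`, `improved`, `skipped`,
#'   `peak_ratio` (named before/after).
#' @export
unbend_image <- function(image, lattice, reference_radius = 1.5,
                         search_radius = NULL) {
  img <- image$pixels
  nx <- nrow(img); ny <- ncol(img)
  img0 <- img - mean(img)
  G <- lattice$recip
  A <- lattice$real_px                  # real-space lattice vectors, pixels
  skip <- function(msg) {
    warning("unbending skipped: ", msg)
    structure(list(image = image, nodes = NULL, rms_displacement = 0,
                   improved = FALSE, skipped = TRUE,
                   peak_ratio = c(before = NA, after = NA)),
              class = "unbend_result")
  }
  s10 <- reflection_measure(img0, as.numeric(G %*% c(1, 0)))
  s01 <- reflection_measure(img0, as.numeric(G %*% c(0, 1)))
  if (s10["amp"] / s10["bg"] < 3 || s01["amp"] / s01["bg"] < 3)
    return(skip("no significant lattice reflections"))
  nd <- try(locate_lattice_nodes(img, A, reference_radius, search_radius),
            silent = TRUE)
  if (inherits(nd, "try-error") || nrow(nd) < 4)
    return(skip("fewer than 4 correlation peaks"))
  # refit the lattice (origin + basis) through the measured node
  # positions: a slightly wrong starting cell or a common translation is
  # not a distortion, only the residuals are
  Xd <- cbind(1, nd$m, nd$n)
  cf <- solve(t(Xd) %*% Xd, t(Xd) %*% cbind(nd$x + nd$dx, nd$y + nd$dy))
  A <- t(cf[2:3, ])
  G <- t(solve(A))
  ideal <- Xd %*% cf
  nd$dx <- (nd$x + nd$dx) - ideal[, 1]
  nd$dy <- (nd$y + nd$dy) - ideal[, 2]
  nd$x <- ideal[, 1]
  nd$y <- ideal[, 2]
  # displacement field: bilinear in lattice-index space over the node grid
  mr <- range(nd$m); nr_ <- range(nd$n)
  DX <- matrix(0, diff(mr) + 1, diff(nr_) + 1)
  DY <- matrix(0, diff(mr) + 1, diff(nr_) + 1)
  HAS <- matrix(FALSE, diff(mr) + 1, diff(nr_) + 1)
  DX[cbind(nd$m - mr[1] + 1, nd$n - nr_[1] + 1)] <- nd$dx
  DY[cbind(nd$m - mr[1] + 1, nd$n - nr_[1] + 1)] <- nd$dy
  HAS[cbind(nd$m - mr[1] + 1, nd$n - nr_[1] + 1)] <- TRUE
  DX[!HAS] <- mean(nd$dx); DY[!HAS] <- mean(nd$dy)
  Ainv <- solve(A)
  # origin of the node grid: position of node (m, n) = (0, 0)
  origin <- c(nd$x[1], nd$y[1]) - as.numeric(A %*% c(nd$m[1], nd$n[1]))
  PX <- matrix(0:(nx - 1), nx, ny); PY <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  mn_x <- Ainv[1, 1] * (PX - origin[1]) + Ainv[1, 2] * (PY - origin[2])
  mn_y <- Ainv[2, 1] * (PX - origin[1]) + Ainv[2, 2] * (PY - origin[2])
  mq <- pmin(pmax(mn_x - mr[1], 0), nrow(DX) - 1.0001)
  nq <- pmin(pmax(mn_y - nr_[1], 0), ncol(DX) - 1.0001)
  dxf <- bilinear_2d(DX, as.numeric(mq), as.numeric(nq))
  dyf <- bilinear_2d(DY, as.numeric(mq), as.numeric(nq))
  corrected <- matrix(bilinear_2d(img, as.numeric(PX) + dxf,
                                  as.numeric(PY) + dyf), nx, ny)
  # only correct inside the measured node hull (half a cell of slack);
  # beyond it the field is extrapolation, not measurement
  inside <- mn_x >= mr[1] - 0.5 & mn_x <= mr[2] + 0.5 &
    mn_y >= nr_[1] - 0.5 & mn_y <= nr_[2] + 0.5
  corrected[!inside] <- img[!inside]
  q10 <- as.numeric(G %*% c(1, 0))
  s10b <- reflection_measure(img0, q10)
  before <- s10b["amp"] / s10b["bg"]
  a_after <- reflection_measure(corrected - mean(corrected), q10)
  after <- a_after["amp"] / a_after["bg"]
  improved <- is.finite(after) && after >= before
  out_img <- if (improved) projection_image(corrected, image$pixel_size,
                                            image$z_range) else image
  structure(list(image = out_img, nodes = nd,
                 rms_displacement = sqrt(mean(nd$dx^2 + nd$dy^2)),
                 improved = improved, skipped = FALSE,
                 peak_ratio = c(before = unname(before),
                                after = unname(after))),
            class = "unbend_result")
}
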