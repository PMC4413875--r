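# Gold-standard iterative alignment and averaging.

# Wedge-compensated average of aligned subvolumes: each member is rotated
# back to the reference frame, its (rotated) wedge accumulated per Fourier
# voxel, and the summed transform divided by the per-voxel wedge count
# (threshold >= 1).
average_aligned <- function(data, members, Rlist, shifts, voxel_size,
                            wedge_theta = 60) {
  d <- dim(data)[1:3]
  S <- array(0 + 0i, d)
  C <- array(0, d)
  # soft spherical premask fitting inside the box faces: without it the
  # rotation clips box corners full of crystal content, and the implied
  # box-mask convolution leaks the (shared) low-frequency structure into
  # the high-resolution shells of every average
  # (content inside the inscribed sphere never clips under a rotation
  # about the centre, so the mask only removes corner content)
  pre <- soft_sphere_mask(d, voxel_size,
                          d[1] * voxel_size / 2 - voxel_size,
                          edge_width = 1)
  for (i in members) {
    Tr <- transform_from_matrix(Rlist[[i]], shifts[[i]])
    v <- density_volume(array(data[, , , i], d) * pre, voxel_size)
    aligned <- rotate_volume(v, invert_transform(Tr))
    w <- rotated_wedge_mask(d, t(Rlist[[i]]), wedge_theta)
    F <- fft(aligned$grid)
    F[!w] <- 0
    S <- S + F
    C <- C + w
  }
  avg <- Re(fft(S / pmax(C, 1), inverse = TRUE)) / prod(d)
  avg[C == 0] <- 0
  density_volume(array(avg, d), voxel_size)
}

# Principal long axis of a particle map (unit xyz vector): dominant
# eigenvector of the thresholded density's second-moment tensor, oriented
# towards the density centroid (the head side carries the larger mass).
map_long_axis <- function(grid, threshold_quantile = 0.85) {
  d <- dim(grid)
  w <- pmax(grid - stats::quantile(grid, threshold_quantile), 0)
  ctr <- (d - 1) / 2
  iz <- slice.index(w, 1) - 1 - ctr[1]
  iy <- slice.index(w, 2) - 1 - ctr[2]
  ix <- slice.index(w, 3) - 1 - ctr[3]
  sw <- sum(w)
  if (sw <= 0) stop("empty map after thresholding")
  cen <- c(sum(w * ix), sum(w * iy), sum(w * iz)) / sw   # xyz, from centre
  cx <- ix - cen[1]; cy <- iy - cen[2]; cz <- iz - cen[3]
  S <- matrix(c(sum(w * cx * cx), sum(w * cx * cy), sum(w * cx * cz),
                sum(w * cx * cy), sum(w * cy * cy), sum(w * cy * cz),
                sum(w * cx * cz), sum(w * cy * cz), sum(w * cz * cz)),
              3, 3) / sw
  u <- eigen(S, symmetric = TRUE)$vectors[, 1]
  if (sum(u * cen) < 0) u <- -u
  u
}

# reference conditioning for one stage: bin, low-pass, soft real-space mask
condition_reference <- function(ref, binning, resolution, mask_radius,
                                mask_shape = "cylinder") {
  r <- if (binning > 1) bin_volume(ref, binning) else ref
  r <- lowpass_volume(r, resolution)
  m <- alignment_mask(mask_shape, dim(r$grid), r$voxel_size, mask_radius)
  if (!is.null(m)) r <- as_volume_like(r$grid * m, r)
  r
}

rotated_ref_ft <- function(ref_grid, d, R, M) {
  ctr <- (rev(d) - 1) / 2
  A <- t(R)
  g <- cpp_affine_sample(ref_grid, d, d, A, as.numeric(ctr - A %*% ctr))
  Fr <- fft(g)
  Fr[!M] <- 0
  Fr
}

#' Gold-standard subtomogram refinement
#'
#' Particles are split into two half-sets that are aligned and averaged
#' independently through a coarse-to-fine schedule; the half-maps are
#' never compared during refinement.  Each iteration aligns every particle
#' to its half-set reference by wedge-masked constrained cross-correlation
#' (free z spin, off-axis rotation and per-axis shifts bounded by
#' `constraints`), then rebuilds the reference by wedge-compensated
#' averaging.  The first iteration searches the full constrained grid;
#' subsequent iterations refine locally around each particle's current
#' orientation.  Down-face particles enter flipped 180 degrees about x and
#' their refined transforms are mapped back through the flip.
#'
#' @param stack a `subvolume_stack` from [extract_subvolumes()].
#' @param schedule a [refinement_schedule()].
#' @param constraints an [alignment_constraints()].
#' @param wedge_theta maximal tilt (degrees) defining the particles'
#'   missing wedge; `NULL` disables wedge weighting (wedge-free phantoms).
#' @param mask_radius soft mask radius (A) applied to the reference and
#'   the particles each iteration (crowded-field suppression); `NULL`
#'   for none.
#' @param mask_shape `"cylinder"` (default; z-axis cylinder, which keeps
#'   a particle's own missing-wedge ghosts but excludes the neighbouring
#'   unit cells of the lattice) or `"sphere"`.
#' @param highpass scoring high-pass in Angstrom (`Inf` for none): in a
#'   crowded 2D crystal the near-uniform membrane slab otherwise rewards
#'   any pose that buries reference density at membrane level.
#' @param bootstrap initial-reference strategy.  `"seed_grow"` (default)
#'   seeds each half-set's reference with a single member subvolume and
#'   grows it from the best-matching partners before the schedule runs;
#'   `"average"` starts from the plain unaligned average (the classic
#'   choice, which for multi-azimuth crystal motifs can settle into a
#'   stable spin-degenerate fixed point).
#' @param bootstrap_resolution band limit (A) of the seed-grow alignment.
#' @param bootstrap_rounds number of seed-grow rounds.
#' @param canonical_axis_offset height (A) of the picked positions above
#'   the particles' mid-membrane points, used to canonicalise the
#'   reference frame against the particle positions after refinement
#'   (`NULL` disables canonicalisation).
#' @param canonical_template optional [density_volume()] (same box) of a
#'   known model: if supplied, it is rigid-body fitted into the merged
#'   average and the fit defines the frame convention exactly — the
#'   docking move used to assign molecular axes to subtomogram averages.
#' @param seed seed for the random half-set split (used only if the table
#'   has no `halfset` labels yet; recorded in the result).
#' @param verbose print per-iteration mean scores.
#' @return List of class `subtomo_refinement`: `halfmaps` (list `A`, `B`
#'   of [density_volume()]), `table` (refined [particle_table()]: updated
#'   positions, orientations, scores), `log` (per-iteration data frame),
#'   plus the inputs needed to repeat the final iteration.
#' @export
refine_gold_standard <- function(stack, schedule = refinement_schedule(),
                                 constraints = alignment_constraints(),
                                 wedge_theta = 60, mask_radius = 75,
                                 mask_shape = c("cylinder", "sphere"),
                                 highpass = 180,
                                 bootstrap = c("seed_grow", "average"),
                                 bootstrap_resolution = 24,
                                 bootstrap_rounds = 3,
                                 canonical_axis_offset = 80,
                                 canonical_template = NULL,
                                 seed = 1, verbose = FALSE) {
  mask_shape <- match.arg(mask_shape)
  bootstrap <- match.arg(bootstrap)
  table <- stack$table
  n <- nrow(table)
  if (n < 2) stop("need at least two particles for a gold-standard split")
  if (all(is.na(table$halfset))) {
    set.seed(seed)
    half <- sample(rep(c("A", "B"), length.out = n))
    table$halfset <- half
  }
  members <- list(A = which(table$halfset == "A"),
                  B = which(table$halfset == "B"))
  if (!all(lengths(members) > 0)) stop("both half-sets must be non-empty")
  work <- flipped_stack_data(stack)
  vs <- stack$voxel_size
  box <- stack$box
  Rcur <- rep(list(diag(3)), n)
  shift <- rep(list(c(0, 0, 0)), n)   # (z, y, x), full-sampling voxels
  score <- rep(NA_real_, n)
  refs <- lapply(members, function(m)
    make_initial_reference(stack, m))
  log <- list()
  first_iteration <- TRUE
  stopped <- FALSE
  if (bootstrap == "seed_grow") {
    # Seed-and-grow reference bootstrap.  The unaligned average of a 2D
    # crystal is azimuthally multi-lobed (the motif's tilt azimuths form a
    # few clusters), and iterating from it settles into a stable wrong
    # fixed point in which each cluster locks into its own lobe.  Seeding
    # each half-set's reference with a single member and growing it from
    # the best-matching partners breaks the degeneracy deterministically.
    db0 <- rep(box, 3)
    wedge0 <- if (is.null(wedge_theta)) NULL else wedge_mask(db0, wedge_theta)
    M0 <- score_mask(db0, vs, bootstrap_resolution, wedge0, highpass)
    mi0 <- which(M0)
    pmask0 <- alignment_mask(mask_shape, db0, vs, mask_radius)
    orientations0 <- global_orientation_grid(15, constraints$max_xy_rot)
    pv0 <- lapply(seq_len(n), function(i) {
      g <- array(work[, , , i], db0)
      if (!is.null(pmask0)) g <- g * pmask0
      v <- fft(g)[mi0]
      nv <- sqrt(sum(Mod(v)^2))
      if (nv > 0) v / nv else v
    })
    grow_from_seed <- function(mem, seed_idx) {
      Rm <- rep(list(diag(3)), n)
      sm <- rep(-Inf, n)
      gseed <- array(work[, , , seed_idx], db0)
      if (!is.null(pmask0)) gseed <- gseed * pmask0
      ref_h <- density_volume(gseed, vs)
      for (round in seq_len(bootstrap_rounds)) {
        refc <- lowpass_volume(ref_h, bootstrap_resolution)
        if (!is.null(pmask0))
          refc <- as_volume_like(refc$grid * pmask0, refc)
        refvecs <- lapply(orientations0, function(R) {
          v <- rotated_ref_ft(refc$grid, db0, R, M0)[mi0]
          nv <- sqrt(sum(Mod(v)^2))
          if (nv > 0) v / nv else v
        })
        for (i in mem) {
          sc <- vapply(refvecs, function(rv)
            sum(Re(pv0[[i]] * Conj(rv))), 0)
          k <- which.max(sc)
          Rm[[i]] <- orientations0[[k]]
          sm[i] <- sc[k]
        }
        frac <- c(1 / 8, 1 / 3, 1)[min(round, 3)]
        K <- if (round < bootstrap_rounds)
          min(length(mem), max(4, ceiling(length(mem) * frac)))
        else length(mem)
        top <- mem[order(sm[mem], decreasing = TRUE)[seq_len(K)]]
        ref_h <- average_aligned(work, top, Rm, shift, vs,
                                 wedge_theta %||% 90)
      }
      list(ref = ref_h, R = Rm, score = sm, mean = mean(sm[mem]))
    }
    for (h in c("A", "B")) {
      mem <- members[[h]]
      # try two seeds; keep the better-converged solution (higher mean
      # correlation = the self-consistent, non-degenerate assignment)
      cands <- lapply(mem[seq_len(min(2, length(mem)))],
                      function(sd) grow_from_seed(mem, sd))
      best <- cands[[which.max(vapply(cands, `[[`, 0, "mean"))]]
      refs[[h]] <- best$ref
      for (i in mem) {
        Rcur[[i]] <- best$R[[i]]
        score[i] <- best$score[i]
      }
      if (verbose)
        message(sprintf("bootstrap %s: mean seed-grow score %.4f", h,
                        best$mean))
    }
    # register half-set B's reference frame onto A's (a pure rotation of
    # the orientation bookkeeping: no density ever crosses the half-sets)
    reg <- try({
      refA <- lowpass_volume(refs$A, bootstrap_resolution)
      refB <- lowpass_volume(refs$B, bootstrap_resolution)
      if (!is.null(pmask0)) {
        refA <- as_volume_like(refA$grid * pmask0, refA)
        refB <- as_volume_like(refB$grid * pmask0, refB)
      }
      FA <- fft(refA$grid)[mi0]
      nA <- sqrt(sum(Mod(FA)^2))
      best <- list(s = -Inf, R = diag(3))
      for (R in orientations0) {
        v <- rotated_ref_ft(refB$grid, db0, R, M0)[mi0]
        nv <- sqrt(sum(Mod(v)^2))
        if (nv == 0) next
        sc <- sum(Re(FA * Conj(v))) / (nA * nv)
        if (sc > best$s) best <- list(s = sc, R = R)
      }
      for (R in local_orientation_grid(best$R, 4, 180)) {
        v <- rotated_ref_ft(refB$grid, db0, R, M0)[mi0]
        nv <- sqrt(sum(Mod(v)^2))
        if (nv == 0) next
        sc <- sum(Re(FA * Conj(v))) / (nA * nv)
        if (sc > best$s) best <- list(s = sc, R = R)
      }
      best$R
    }, silent = TRUE)
    if (!inherits(reg, "try-error")) {
      # ref_A approx rotate(ref_B, R_reg) => particle_i = rotate(ref_B, A_i)
      #                                   = rotate(ref_A, A_i %*% t(R_reg))
      for (i in members$B) Rcur[[i]] <- Rcur[[i]] %*% t(reg)
      refs$B <- average_aligned(work, members$B, Rcur, shift, vs,
                                wedge_theta %||% 90)
    }
    first_iteration <- FALSE
  }
  for (s in seq_along(schedule$stages)) {
    st <- schedule$stages[[s]]
    b <- st$binning
    db <- rep(box %/% b, 3)
    vb <- vs * b
    data_b <- if (b == 1) work else {
      arr <- array(0, c(db, n))
      for (i in seq_len(n))
        arr[, , , i] <- bin_volume(density_volume(array(work[, , , i],
                                                        rep(box, 3)), vs), b)$grid
      arr
    }
    wedge_b <- if (is.null(wedge_theta)) NULL else wedge_mask(db, wedge_theta)
    M <- score_mask(db, vb, st$resolution, wedge_b, highpass)
    if (!any(M)) stop("empty wedge/band intersection at stage ", s)
    pmask <- alignment_mask(mask_shape, db, vb, mask_radius)
    Fp <- vector("list", n); np <- numeric(n)
    for (i in seq_len(n)) {
      g <- array(data_b[, , , i], db)
      if (!is.null(pmask)) g <- g * pmask
      F <- fft(g)
      F[!M] <- 0
      Fp[[i]] <- F
      np[i] <- sqrt(sum(Mod(F)^2))
    }
    ms_stage <- st$max_shift %||% constraints$max_shift
    if (is.na(ms_stage)) ms_stage <- constraints$max_shift
    si <- shift_index(db[1], max(0, floor(ms_stage / b)))
    mi <- which(M)
    kk <- freq_grids(db)
    kzv <- kk$kz[mi]; kyv <- kk$ky[mi]; kxv <- kk$kx[mi]
    prev_mean <- -Inf           # scores are only comparable within a stage
    decreases <- 0
    for (it in seq_len(st$iterations)) {
      refs_b <- lapply(refs, condition_reference, binning = b,
                       resolution = st$resolution, mask_radius = mask_radius,
                       mask_shape = mask_shape)
      # coarse-step stages re-search the full constrained grid: binned
      # ones with the full FFT translation search, unbinned ones over
      # masked Fourier vectors at the current translations (after a
      # seed-grow bootstrap the binned coarse stages refine locally, so
      # low-resolution spin ambiguity cannot undo the bootstrap)
      global_search <- first_iteration ||
        (bootstrap == "average" && st$step >= 10) ||
        (b == 1 && st$step >= 10)
      if (global_search && b > 1) {
        # binned global search with full FFT translation search
        orientations <- global_orientation_grid(st$step, constraints$max_xy_rot)
        best_score <- rep(-Inf, n)
        for (R in orientations) {
          Fr <- lapply(refs_b, function(r) rotated_ref_ft(r$grid, db, R, M))
          nr <- vapply(Fr, function(F) sqrt(sum(Mod(F)^2)), 0)
          for (h in c("A", "B")) {
            if (nr[[h]] == 0) next
            for (i in members[[h]]) {
              bs <- best_shift(Fp[[i]], Fr[[h]], np[i], nr[[h]], si)
              if (bs$score > best_score[i] + 1e-12) {
                best_score[i] <- bs$score
                Rcur[[i]] <- R
                shift[[i]] <- bs$shift * b
              }
            }
          }
        }
        score <- best_score
        first_iteration <- FALSE
      } else if (global_search) {
        # unbinned global search over masked Fourier vectors at each
        # particle's current translation (positions are already known to
        # about a voxel; translations are re-refined in the local stages)
        orientations <- global_orientation_grid(st$step, constraints$max_xy_rot)
        refvecs <- lapply(c(A = "A", B = "B"), function(h) {
          lapply(orientations, function(R) {
            Fr <- rotated_ref_ft(refs_b[[h]]$grid, db, R, M)
            v <- Fr[mi]
            nv <- sqrt(sum(Mod(v)^2))
            if (nv > 0) v / nv else v
          })
        })
        for (h in c("A", "B")) {
          for (i in members[[h]]) {
            s_b <- shift[[i]] / b
            pv <- Fp[[i]][mi] *
              exp(2i * pi * (kzv * s_b[1] + kyv * s_b[2] + kxv * s_b[3]))
            pv <- pv / sqrt(sum(Mod(pv)^2))
            sc <- vapply(refvecs[[h]], function(rv)
              sum(Re(pv * Conj(rv))), 0)
            best <- which.max(sc)
            score[i] <- sc[best]
            Rcur[[i]] <- orientations[[best]]
          }
        }
        first_iteration <- FALSE
      } else {
        for (h in c("A", "B")) {
          rg <- refs_b[[h]]$grid
          for (i in members[[h]]) {
            cands <- local_orientation_grid(Rcur[[i]], st$step,
                                            constraints$max_xy_rot)
            bsc <- -Inf; bR <- Rcur[[i]]; bsh <- shift[[i]]
            for (R in cands) {
              Fr <- rotated_ref_ft(rg, db, R, M)
              nr <- sqrt(sum(Mod(Fr)^2))
              if (nr == 0) next
              bs <- best_shift(Fp[[i]], Fr, np[i], nr, si)
              if (bs$score > bsc + 1e-12) {
                bsc <- bs$score; bR <- R; bsh <- bs$shift * b
              }
            }
            score[i] <- bsc; Rcur[[i]] <- bR; shift[[i]] <- bsh
          }
        }
      }
      for (h in c("A", "B"))
        refs[[h]] <- average_aligned(work, members[[h]], Rcur, shift, vs,
                                     wedge_theta %||% 90)
      mean_score <- mean(score)
      log[[length(log) + 1]] <- data.frame(stage = s, iteration = it,
                                           resolution = st$resolution,
                                           binning = b,
                                           mean_score = mean_score)
      if (verbose)
        message(sprintf("stage %d iter %d: mean score %.4f", s, it, mean_score))
      if (mean_score < prev_mean) decreases <- decreases + 1 else decreases <- 0
      prev_mean <- mean_score
      if (decreases >= 2) {
        warning("refinement diverging (mean score fell twice); stopping early")
        stopped <- TRUE
        break
      }
    }
    if (stopped) break
  }
  # canonicalise the orientation frame: the refined orientations live in
  # an arbitrary reference frame (set by the bootstrap seed), so the
  # reference map itself is the phantom rotated by the unknown common
  # frame rotation.  Its long axis — the principal inertia axis of the
  # thresholded average — is therefore exactly the reference-frame
  # direction u that maps onto the particle long axes; rotate the
  # bookkeeping so u becomes +z.  The residual common spin about the
  # axis is unobservable and cancels in every relative measurement.
  if (!is.null(canonical_axis_offset) && n >= 6) {
    u <- try(map_long_axis((refs$A$grid + refs$B$grid) / 2), silent = TRUE)
    if (!inherits(u, "try-error")) {
      ax <- c(-u[2], u[1], 0)
      s_ax <- sqrt(sum(ax^2))
      Q <- if (s_ax <= 1e-12) diag(3) else {
        ax <- ax / s_ax
        th <- acos(max(-1, min(1, u[3])))
        K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1],
                      -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
        diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K   # z -> u
      }
      for (i in seq_len(n)) Rcur[[i]] <- Rcur[[i]] %*% Q
      Tq <- transform_from_matrix(t(Q))
      refs <- lapply(refs, rotate_volume, transform = Tq)
    }
  }
  # if a template (the known model) is supplied, anchor the frame exactly
  # by rigid-body fitting it into the merged average — the same move as
  # docking a known structure into a subtomogram average to define the
  # molecular axes.  Per-particle orientations remain purely data-driven;
  # only the global frame convention is taken from the fit.
  if (!is.null(canonical_template)) {
    G <- try({
      merged <- (refs$A$grid + refs$B$grid) / 2
      db0 <- dim(merged)
      Mreg <- score_mask(db0, vs, 24, NULL, highpass)
      mir <- which(Mreg)
      pm <- alignment_mask(mask_shape, db0, vs, mask_radius)
      mg <- if (is.null(pm)) merged else merged * pm
      Fm <- fft(array(mg, db0))[mir]
      Fm <- Fm / sqrt(sum(Mod(Fm)^2))
      tg <- canonical_template$grid
      if (!is.null(pm)) tg <- tg * pm
      # the residual frame error is an arbitrary spin about z plus a
      # small tilt (the axis was already canonicalised), so search the
      # full z-twist circle crossed with modest off-axis perturbations
      cands <- list()
      for (tw in seq(0, 345, by = 15))
        for (ax in c(-10, 0, 10)) for (ay in c(-10, 0, 10))
          cands[[length(cands) + 1]] <- rot_x(ax) %*% rot_y(ay) %*% rot_z(tw)
      best <- list(s = -Inf, R = diag(3))
      for (R in cands) {
        v <- rotated_ref_ft(tg, db0, R, Mreg)[mir]
        nv <- sqrt(sum(Mod(v)^2))
        if (nv == 0) next
        s <- sum(Re(Fm * Conj(v))) / nv
        if (s > best$s) best <- list(s = s, R = R)
      }
      for (step_l in c(5, 1.5, 0.5)) {
        for (R in local_orientation_grid(best$R, step_l, 180, n_steps = 3)) {
          v <- rotated_ref_ft(tg, db0, R, Mreg)[mir]
          nv <- sqrt(sum(Mod(v)^2))
          if (nv == 0) next
          s <- sum(Re(Fm * Conj(v))) / nv
          if (s > best$s) best <- list(s = s, R = R)
        }
      }
      best$R
    }, silent = TRUE)
    if (!inherits(G, "try-error")) {
      for (i in seq_len(n)) Rcur[[i]] <- Rcur[[i]] %*% G
      Tg <- transform_from_matrix(t(G))
      refs <- lapply(refs, rotate_volume, transform = Tg)
    }
  }
  # write back: undo the x-flip for down-face particles
  Rf <- transform_matrix(x_flip_transform())
  for (i in seq_len(n)) {
    R <- Rcur[[i]]; sh <- shift[[i]]
    if (stack$flip[i]) {
      R <- Rf %*% R
      sh <- c(-sh[1], -sh[2], sh[3])
    }
    e <- matrix_to_euler(R)
    table$rot[i] <- e[1]; table$tilt[i] <- e[2]; table$psi[i] <- e[3]
    table$x[i] <- table$x[i] + sh[3]
    table$y[i] <- table$y[i] + sh[2]
    table$z[i] <- table$z[i] + sh[1]
    table$score[i] <- score[i]
  }
  structure(list(halfmaps = refs, table = particle_table(as.data.frame(table)),
                 log = do.call(rbind, log), schedule = schedule,
                 constraints = constraints, wedge_theta = wedge_theta,
                 mask_radius = mask_radius, mask_shape = mask_shape,
                 highpass = highpass, seed = seed,
                 members = members,
                 final_transforms = list(R = Rcur, shift = shift)),
            class = "subtomo_refinement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.subtomo_refinement <- function(x, ...) {
  cat(sprintf("<subtomo_refinement> %d particles, %d/%d per half-set\n",
              nrow(x$table), length(x$members$A), length(x$members$B)))
  print(x$log, row.names = FALSE)
  invisible(x)
}
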