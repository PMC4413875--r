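ref_phantom <- function() memo("ref_phantom", build_phantom(phantom_spec(), 6.66, 40))

test_that("extraction is centred, ordered, and invertible", {
  sim <- mini_sim(jitter = 0)
  tomo <- sim$volume
  tab <- sim$table
  st <- extract_subvolumes(tomo, tab, box = 32)
  expect_equal(dim(st$data)[4], nrow(tab))
  expect_identical(st$table$id, tab$id)
  expect_identical(st$flip, tab$face == "down")

  # particle on the box-centre lattice (an even box centres between
  # voxels): extraction is a plain copy, and re-inserting it reproduces
  # the local tomogram values exactly
  t1 <- tab[1, ]
  t1$x <- round(t1$x) + 0.5; t1$y <- round(t1$y) + 0.5
  t1$z <- round(t1$z) + 0.5
  s1 <- extract_subvolumes(tomo, particle_table(t1), box = 32)
  sub <- array(s1$data[, , , 1], c(32, 32, 32))
  iz <- t1$z - 15.5; iy <- t1$y - 15.5; ix <- t1$x - 15.5
  expect_identical(sub, tomo$grid[iz + (1:32), iy + (1:32), ix + (1:32)])
  back <- array(0, dim(tomo$grid))
  crystomo:::cpp_paste_add(back, dim(back), sub, dim(sub),
                           as.integer(c(iz, iy, ix)))
  expect_identical(back[iz + (1:32), iy + (1:32), ix + (1:32)],
                   tomo$grid[iz + (1:32), iy + (1:32), ix + (1:32)])

  # out-of-bounds handling
  t2 <- tab[1, ]; t2$x <- 2
  expect_warning(extract_subvolumes(tomo, particle_table(t2), box = 32,
                                    out_of_bounds = "skip"), "skipping")
  padded <- extract_subvolumes(tomo, particle_table(t2), box = 32)
  expect_equal(dim(padded$data)[4], 1)
})

test_that("initial references average with the face flip", {
  ph <- ref_phantom()
  n <- 6
  data <- array(rep(ph$grid, n), c(dim(ph$grid), n))
  tab <- particle_table(data.frame(
    id = 1:n, x = 20, y = 20, z = 20, rot = 0, tilt = 0, psi = 0,
    face = "up", halfset = NA, score = NA, stringsAsFactors = FALSE))
  st <- list(data = data, table = tab, flip = rep(FALSE, n),
             voxel_size = 6.66, box = 40)
  class(st) <- "subvolume_stack"
  r <- make_initial_reference(st)
  expect_equal(r$grid, ph$grid, tolerance = 1e-12)
  expect_error(make_initial_reference(st, integer(0)), "empty")

  # averaging N noisy copies reduces noise as 1/sqrt(N)
  set.seed(3)
  noisy <- data + array(rnorm(length(data), 0, 1), dim(data))
  stn <- st; stn$data <- noisy
  rn <- make_initial_reference(stn)
  expect_equal(sd(rn$grid - ph$grid), 1 / sqrt(n), tolerance = 0.1 / sqrt(n) * 3)

  # up-only vs up-plus-flipped-down references on a z-symmetric phantom
  sym <- density_volume(ph$grid + rotate_volume(ph, rigid_transform(
    tilt = 180, psi = 180))$grid, 6.66)
  data2 <- array(rep(sym$grid, 2), c(dim(sym$grid), 2))
  st2 <- st; st2$data <- data2; st2$table <- tab[1:2, ]
  st2$flip <- c(FALSE, TRUE)
  r2 <- make_initial_reference(st2)
  r1 <- make_initial_reference(list(data = data2[, , , 1, drop = FALSE],
                                    table = tab[1, ], flip = FALSE,
                                    voxel_size = 6.66, box = 40))
  expect_gt(cor(as.numeric(r1$grid), as.numeric(r2$grid)), 0.99)
})

test_that("alignment recovers known transforms within the grid resolution", {
  ph <- ref_phantom()
  # identity: score 1, identity transform
  res0 <- align_subvolume(ph, ph, alignment_constraints(max_shift = 4),
                          step = 30)
  expect_equal(res0$score, 1, tolerance = 1e-6)
  expect_lt(crystomo:::rotation_angle(transform_matrix(res0$transform)), 1e-6)
  expect_lt(max(abs(res0$transform$shift)), 1e-6)

  # known rotation + shift recovered within one fine grid step / a voxel
  true_t <- rigid_transform(rot = 25, tilt = 10, shift = c(1, -2, 3))
  moved <- rotate_volume(ph, true_t)
  res <- align_subvolume(moved, ph, alignment_constraints(max_shift = 6),
                         step = 15)
  res <- align_subvolume(moved, ph, alignment_constraints(max_shift = 6),
                         step = 5, around = res$transform)
  dR <- t(transform_matrix(true_t)) %*% transform_matrix(res$transform)
  expect_lt(crystomo:::rotation_angle(dR), 5 * sqrt(3))
  expect_lt(max(abs(res$transform$shift - true_t$shift)), 1)
})

test_that("the off-axis constraint clamps the returned orientation", {
  ph <- bin_volume(ref_phantom(), 2)   # binned: the 90-degree grid is large
  true_t <- rigid_transform(rot = 0, tilt = 60, psi = 0)
  moved <- rotate_volume(ph, true_t)
  unconstrained <- align_subvolume(moved, ph,
                                   alignment_constraints(max_xy_rot = 90,
                                                         max_shift = 2),
                                   step = 10)
  constrained <- align_subvolume(moved, ph,
                                 alignment_constraints(max_xy_rot = 45,
                                                       max_shift = 2),
                                 step = 10)
  expect_lte(constrained$transform$euler["tilt"], 45 + 1e-9)
  expect_lt(constrained$score, unconstrained$score)
})

test_that("alignment is equivariant under rotations of the reference", {
  ph <- bin_volume(ref_phantom(), 2)
  set.seed(11)
  for (k in 1:5) {
    tt <- rigid_transform(runif(1, 0, 360), runif(1, 0, 40),
                          runif(1, 0, 360))
    moved <- rotate_volume(ph, tt)
    res <- align_subvolume(moved, ph, alignment_constraints(max_shift = 3),
                           step = 20)
    res <- align_subvolume(moved, ph, alignment_constraints(max_shift = 3),
                           step = 4, around = res$transform)
    dR <- t(transform_matrix(tt)) %*% transform_matrix(res$transform)
    expect_lt(crystomo:::rotation_angle(dR), 8)
  }
})

test_that("wedge-free scoring equals plain normalised cross-correlation", {
  ph <- ref_phantom()
  shifted <- rotate_volume(ph, rigid_transform(shift = c(2, 0, -1)))
  res <- align_subvolume(shifted, ph, alignment_constraints(max_shift = 4),
                         step = 90)
  # oracle: direct normalised correlation of the mean-subtracted volumes
  a <- as.numeric(shifted$grid) - mean(shifted$grid)
  b0 <- rotate_volume(ph, rigid_transform(shift = res$transform$shift))
  b <- as.numeric(b0$grid) - mean(b0$grid)
  expect_equal(res$score, sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
               tolerance = 0.02)
})

test_that("half-map merging is the voxelwise mean", {
  a <- gaussian_blob_volume(16)
  b <- density_volume(-a$grid, 1)
  expect_equal(max(abs(merge_halfmaps(a, b)$grid)), 0)
  set.seed(2)
  r1 <- density_volume(array(rnorm(16^3), c(16, 16, 16)), 1)
  r2 <- density_volume(array(rnorm(16^3), c(16, 16, 16)), 1)
  expect_identical(merge_halfmaps(r1, r2)$grid, (r1$grid + r2$grid) / 2)
  expect_error(merge_halfmaps(r1, gaussian_blob_volume(8)), "shape")
})
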