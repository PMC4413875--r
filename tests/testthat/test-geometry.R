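jittered_table <- function() mini_sim(jitter = 0)$table

test_that("re-insertion reproduces the generator volume", {
  sim <- mini_sim(jitter = 0)
  ph <- build_phantom(phantom_spec(), 6.66, 40)
  shape <- dim(sim$volume$grid)
  repos <- reposition_average(shape, sim$table, ph)
  # compare in the protein region (where the repositioned map has density)
  sel <- repos$grid > 0.2
  expect_gt(cor(repos$grid[sel], sim$volume$grid[sel]), 0.9)

  # single particle at identity lands as a plain copy
  t1 <- particle_table(data.frame(id = 1, x = 30.5, y = 30.5, z = 30.5,
                                  rot = 0, tilt = 0, psi = 0, face = "up",
                                  halfset = NA, score = NA,
                                  stringsAsFactors = FALSE))
  single <- reposition_average(c(64, 64, 64), t1, ph)
  expect_equal(single$grid[30 - 19 + (1:40), 30 - 19 + (1:40), 30 - 19 + (1:40)],
               ph$grid, tolerance = 1e-9)
  # overlapping particles add
  t2 <- particle_table(rbind(as.data.frame(t1),
                             within(as.data.frame(t1), id <- 2L)))
  dbl <- reposition_average(c(64, 64, 64), t2, ph)
  expect_equal(dbl$grid, 2 * single$grid, tolerance = 1e-12)
})

test_that("pair assignment is order-invariant and matches brute force", {
  tab <- jittered_table()
  pr <- find_pairs(tab, 6.66, axis_offset = 80)
  set.seed(5)
  perm <- sample(nrow(tab))
  tabp <- particle_table(as.data.frame(tab)[perm, ])
  prp <- find_pairs(tabp, 6.66, axis_offset = 80)
  canon <- function(p, map = seq_len(nrow(tab))) {
    s <- t(apply(cbind(map[p[[1]]], map[p[[2]]]), 1, sort))
    s[order(s[, 1], s[, 2]), , drop = FALSE]
  }
  expect_equal(canon(pr$pairs), canon(prp$pairs, perm), ignore_attr = TRUE)
  # brute-force oracle: all-pairs mutual nearest neighbour
  pos <- crystomo:::particle_positions(tab) * 6.66 -
    crystomo:::particle_axes(tab) * 80
  D <- as.matrix(dist(pos)); diag(D) <- Inf
  same <- outer(tab$face, tab$face, `==`)
  D[!same] <- Inf
  oracle <- NULL
  for (i in seq_len(nrow(tab))) {
    j <- which.min(D[i, ])
    if (D[i, j] <= 130 && which.min(D[j, ]) == i && i < j)
      oracle <- rbind(oracle, c(i, j))
  }
  expect_equal(canon(pr$pairs), oracle[order(oracle[, 1]), , drop = FALSE],
               ignore_attr = TRUE)
  # zero cutoff gives no pairs
  none <- find_pairs(tab, 6.66, same_face_cutoff = 0, cross_face_cutoff = 0,
                     axis_offset = 80)
  expect_equal(nrow(none$pairs), 0)
  expect_equal(nrow(none$interfaces), 0)
})

test_that("angle measurements read back generator parameters", {
  tab <- jittered_table()
  inc <- measure_inclination(tab, axis_offset = 80 / 6.66)
  expect_equal(inc$mean, 16, tolerance = 2)
  # theta = 0 generator
  cs0 <- crystal_spec(inclination_theta = 0, jitter_sigma_xy = 0,
                      jitter_sigma_angle = 0, n_cells = c(2, 2))
  sim0 <- build_crystal_volume(cs0, phantom_spec(), c(80, 96, 96), 6.66)
  inc0 <- measure_inclination(sim0$table, plane_normal = c(0, 0, 1))
  expect_lt(inc0$mean, 0.5)
  # interface rotation 0 generator
  csr <- crystal_spec(interface_rotation = 0, jitter_sigma_xy = 0,
                      jitter_sigma_angle = 0, n_cells = c(2, 2))
  simr <- build_crystal_volume(csr, phantom_spec(), c(80, 96, 96), 6.66)
  prr <- find_pairs(simr$table, 6.66, axis_offset = 80)
  irr <- measure_interface_rotation(prr$interfaces, simr$table, basis = diag(3))
  expect_lt(irr$mean, 0.5)
  # identical axes give a zero pair angle
  fake <- particle_table(data.frame(
    id = 1:2, x = c(0, 10), y = 0, z = 0, rot = 0, tilt = 20, psi = 0,
    face = "up", halfset = NA, score = NA, stringsAsFactors = FALSE))
  pa0 <- measure_pair_angle(data.frame(i = 1, j = 2, distance = 10), fake)
  expect_equal(pa0$mean, 0, tolerance = 1e-9)
})

test_that("measurements are equivariant under a global rigid rotation", {
  tab <- jittered_table()
  plane <- crystomo:::fit_crystal_plane(tab, 80 / 6.66)
  pr <- find_pairs(tab, 6.66, axis_offset = 80)
  inc <- measure_inclination(tab, plane$normal)
  pa <- measure_pair_angle(pr$pairs, tab)
  ir <- measure_interface_rotation(pr$interfaces, tab, plane$basis)

  Q <- transform_matrix(c(25, 18, -40))
  rot_tab <- as.data.frame(tab)
  ctr <- colMeans(crystomo:::particle_positions(tab))
  newpos <- t(Q %*% t(sweep(crystomo:::particle_positions(tab), 2, ctr))) +
    matrix(ctr, nrow(tab), 3, byrow = TRUE)
  rot_tab$x <- newpos[, 1]; rot_tab$y <- newpos[, 2]; rot_tab$z <- newpos[, 3]
  for (i in seq_len(nrow(tab))) {
    e <- matrix_to_euler(Q %*% transform_matrix(c(tab$rot[i], tab$tilt[i],
                                                  tab$psi[i])))
    rot_tab$rot[i] <- e[1]; rot_tab$tilt[i] <- e[2]; rot_tab$psi[i] <- e[3]
  }
  rot_tab <- particle_table(rot_tab)
  basis_q <- Q %*% plane$basis
  pr2 <- find_pairs(rot_tab, 6.66, axis_offset = 80)
  inc2 <- measure_inclination(rot_tab, as.numeric(Q %*% plane$normal))
  pa2 <- measure_pair_angle(pr2$pairs, rot_tab)
  ir2 <- measure_interface_rotation(pr2$interfaces, rot_tab, basis_q)
  expect_equal(inc2$mean, inc$mean, tolerance = 1e-6)
  expect_equal(pa2$mean, pa$mean, tolerance = 1e-6)
  expect_equal(ir2$mean, ir$mean, tolerance = 1e-6)
})

test_that("pair angle, inclination and azimuth satisfy the spherical identity", {
  tab <- jittered_table()
  ax <- crystomo:::particle_axes(tab)
  pr <- find_pairs(tab, 6.66, axis_offset = 80)
  for (r in seq_len(nrow(pr$pairs))) {
    a1 <- ax[pr$pairs$i[r], ]; a2 <- ax[pr$pairs$j[r], ]
    if (a1[3] < 0) a1 <- -a1
    if (a2[3] < 0) a2 <- -a2
    t1 <- acos(a1[3]); t2 <- acos(a2[3])
    dphi <- atan2(a2[2], a2[1]) - atan2(a1[2], a1[1])
    lhs <- sum(a1 * a2)
    rhs <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(dphi)
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("dimer angle prediction is twice the kink", {
  expect_equal(predict_dimer_angle(43), 86)
  expect_equal(predict_dimer_angle(0), 0)
  expect_equal(predict_dimer_angle(45), 90)
  expect_error(predict_dimer_angle(95))
})

test_that("head height is recovered from the noiseless crystal volume", {
  sim <- mini_sim(jitter = 0)
  h <- measure_head_height(sim$volume, sim$z_mid)
  expect_equal(h, 150 * cos(16 * pi / 180), tolerance = 6.66)
})
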