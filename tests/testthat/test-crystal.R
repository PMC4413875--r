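test_that("ground-truth table reproduces the generator geometry exactly", {
  sim <- mini_sim(jitter = 0)
  tab <- sim$table
  expect_equal(nrow(tab), 16)
  inc <- measure_inclination(tab, plane_normal = c(0, 0, 1))
  expect_equal(inc$per_particle, rep(16, 16), tolerance = 1e-9)

  pr <- find_pairs(tab, 6.66, axis_offset = 80)
  expect_equal(nrow(pr$pairs), 8)       # one up and one down pair per cell
  expect_equal(nrow(pr$interfaces), 8)
  pa <- measure_pair_angle(pr$pairs, tab)
  # spherical-trigonometry oracle: cos a = cos^2 t + sin^2 t cos dphi
  t <- 16 * pi / 180
  oracle <- acos(cos(t)^2 + sin(t)^2 * cos(98.1 * pi / 180)) * 180 / pi
  expect_equal(pa$per_pair, rep(oracle, 8), tolerance = 1e-6)
  expect_equal(pa$mean, 24.0, tolerance = 0.2)

  ir <- measure_interface_rotation(pr$interfaces, tab,
                                   basis = diag(3))
  expect_equal(ir$per_interface, rep(90, 8), tolerance = 1e-6)
})

test_that("pair-angle identity holds across generator settings", {
  for (theta in c(5, 16, 30)) for (dphi in c(40, 98.1, 150)) {
    cs <- crystal_spec(inclination_theta = theta, pair_azimuth_delta = dphi,
                       jitter_sigma_xy = 0, jitter_sigma_angle = 0,
                       n_cells = c(1, 1))
    sim <- build_crystal_volume(cs, phantom_spec(), c(80, 96, 96), 6.66)
    pr <- find_pairs(sim$table, 6.66, axis_offset = 80,
                     same_face_cutoff = 200)
    pa <- measure_pair_angle(pr$pairs, sim$table)
    t <- theta * pi / 180
    oracle <- acos(cos(t)^2 + sin(t)^2 * cos(dphi * pi / 180)) * 180 / pi
    expect_equal(mean(pa$per_pair), oracle, tolerance = 1e-6)
  }
})

test_that("the membrane mesh kinks by kappa at each particle row", {
  sim <- mini_sim(jitter = 0)
  mm <- sim$membrane
  # angle between adjacent segment directions of the analytic mesh
  x <- seq(mm$phase, by = mm$period, length.out = 3)
  sl <- diff(crystomo:::membrane_height(mm, x + 1)) -
        diff(crystomo:::membrane_height(mm, x))
  a1 <- atan((crystomo:::membrane_height(mm, x[1] + 10) -
              crystomo:::membrane_height(mm, x[1] + 9))) * 180 / pi
  a2 <- atan((crystomo:::membrane_height(mm, x[2] + 10) -
              crystomo:::membrane_height(mm, x[2] + 9))) * 180 / pi
  expect_equal(unname(abs(a1 - a2)), 43, tolerance = 1e-6)
  # ridge tracing the noiseless crystal volume recovers kappa
  kk <- trace_membrane_kink(sim$volume, mm$period, mm$phase, sim$z_mid)
  expect_equal(kk$mean, 43, tolerance = 1.5)
  # flat membrane: kappa 0
  cs0 <- crystal_spec(kink_kappa = 0, jitter_sigma_xy = 0,
                      jitter_sigma_angle = 0, n_cells = c(2, 2))
  sim0 <- build_crystal_volume(cs0, phantom_spec(), c(80, 96, 96), 6.66)
  kk0 <- trace_membrane_kink(sim0$volume, sim0$membrane$period,
                             sim0$membrane$phase, sim0$z_mid)
  expect_lt(kk0$mean, 1)
})

test_that("zigzag cross-sections show alternating membrane slopes", {
  sim <- mini_sim(jitter = 0)
  kk <- trace_membrane_kink(sim$volume, sim$membrane$period,
                            sim$membrane$phase, sim$z_mid)
  sl <- kk$segment_angles
  expect_true(all(abs(abs(sl) - 21.5) < 4))
  expect_true(all(diff(sign(sl)) != 0))   # alternating signs
})

test_that("row-anchored kink matches the generator on ground truth", {
  sim <- mini_sim(jitter = 0)
  kk <- measure_kink_from_rows(sim$table, sim$membrane$period,
                               sim$membrane$phase, 6.66)
  expect_equal(kk$mean, 43, tolerance = 1e-6)
})
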