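test_that("FSC behaves for identical, noisy, and band-limited map pairs", {
  v <- gaussian_blob_volume(32, center = c(14, 17, 15), sigma = 3)
  f_same <- compute_fsc(v, v)
  expect_true(all(abs(f_same$correlation[f_same$n_voxels > 0] - 1) < 1e-9))
  expect_equal(f_same$correlation[1], 1)

  set.seed(21)
  n1 <- density_volume(array(rnorm(32^3), c(32, 32, 32)), 1)
  n2 <- density_volume(array(rnorm(32^3), c(32, 32, 32)), 1)
  f_noise <- compute_fsc(n1, n2)
  beyond <- f_noise$shell > 0 & f_noise$n_voxels > 0
  z <- abs(f_noise$correlation[beyond]) * sqrt(f_noise$n_voxels[beyond])
  # per-shell correlations scatter like 1/sqrt(n); 3/sqrt(n) is a ~3-sigma
  # level, so allow at most one marginal exceedance across the shells
  expect_lte(sum(z > 3), 1)
  expect_lt(max(z), 4.5)

  vol <- density_volume(v$grid, 2)
  lp <- lowpass_volume(vol, 8)       # cutoff at shell 8 of 32
  f_lp <- compute_fsc(vol, lp)
  kc <- 32 * 2 / 8
  expect_true(all(abs(f_lp$correlation[f_lp$shell < kc - 1] - 1) < 1e-6))
  # above the cutoff the low-passed map carries (numerically) no power
  aa <- Mod(fft(lp$grid))^2
  sh <- round(crystomo:::freq_radius(dim(lp$grid)) * 32)
  expect_lt(sum(aa[sh > kc + 1]) / sum(aa), 1e-12)
  # symmetry
  f_ab <- compute_fsc(n1, vol); f_ba <- compute_fsc(vol, n1)
  expect_equal(f_ab$correlation, f_ba$correlation, tolerance = 1e-12)
})

test_that("threshold crossing is interpolated linearly", {
  # synthetic curve crossing 0.5 halfway between 1/25 and 1/23 per A
  freq <- c(0, 0.01, 1 / 25, 1 / 23, 0.06)
  curve <- data.frame(shell = 0:4, frequency = freq,
                      correlation = c(1, 0.9, 0.6, 0.4, 0.1),
                      n_voxels = rep(10, 5))
  class(curve) <- c("fsc_curve", "data.frame")
  # hand interpolation: 0.5 sits halfway between the 1/25 and 1/23 shells
  f_half <- 1 / 25 + 0.5 * (1 / 23 - 1 / 25)
  expect_equal(as.numeric(resolution_at_threshold(curve, 0.5)), 1 / f_half,
               tolerance = 1e-9)
  expect_lte(as.numeric(resolution_at_threshold(curve, 0.143)),
             as.numeric(resolution_at_threshold(curve, 0.5)))
  flat <- curve; flat$correlation <- rep(1, 5)
  res <- resolution_at_threshold(flat)
  expect_equal(as.numeric(res), 1 / 0.06)
  expect_true(attr(res, "at_nyquist"))
})

test_that("phase randomisation preserves amplitudes and realness", {
  v <- mini_sim(jitter = 0)$volume
  sub <- density_volume(v$grid[1:48, 1:48, 1:48], v$voxel_size)
  pr <- phase_randomize_beyond(sub, cutoff = 40, seed = 3)
  # every amplitude shell conserved
  a0 <- Mod(fft(sub$grid)); a1 <- Mod(fft(pr$grid))
  expect_equal(a1, a0, tolerance = 1e-6 * max(a0))
  f <- compute_fsc(sub, pr)
  kc <- 48 * sub$voxel_size / 40
  expect_true(all(f$correlation[f$shell < kc - 1] > 0.99))
  # beyond the cutoff the correlation scatters like a noise FSC whose
  # effective voxel count is amplitude-weighted (the crystal concentrates
  # power in a few reflections): n_eff = (sum a^2)^2 / sum a^4 per shell
  a2 <- a0^2
  sh <- round(crystomo:::freq_radius(dim(sub$grid)) * 48)
  n_eff <- tapply(a2, sh, function(x) sum(x)^2 / sum(x^2))
  bey_sh <- f$shell[f$shell > kc + 1 & f$n_voxels > 50]
  corr <- f$correlation[match(bey_sh, f$shell)]
  expect_true(all(abs(corr) <
                    4.5 / sqrt(n_eff[as.character(bey_sh)]) + 0.05))
  # realness is enforced by construction; check imaginary residue directly
  F <- fft(sub$grid)
  set.seed(3)
  expect_lt(max(abs(Im(fft(fft(pr$grid), inverse = TRUE) / length(F)) )), 1e-8)
  expect_error(phase_randomize_beyond(sub, cutoff = 5), "Nyquist")
})

test_that("the Fermi filter has the analytic transfer function", {
  v <- gaussian_blob_volume(32, sigma = 4)
  vol <- density_volume(v$grid, 6.66)
  ff <- fermi_filter(vol, cutoff = 18, temperature = 0.002)
  F0 <- fft(vol$grid); F1 <- fft(ff$grid)
  r <- crystomo:::freq_radius(dim(vol$grid))
  kc <- 6.66 / 18
  # per-voxel transfer matches 1 / (1 + exp((k - kc) / T)) exactly, and
  # is 0.5 at the cutoff by construction of that form
  at <- abs(r - kc) < 0.02 & Mod(F0) > 1e-6
  expect_equal(Mod(F1)[at] / Mod(F0)[at],
               1 / (1 + exp((r[at] - kc) / 0.002)), tolerance = 1e-6)
  expect_equal(1 / (1 + exp(0 / 0.002)), 0.5)
  expect_equal(Re(F1[1, 1, 1]) / Re(F0[1, 1, 1]), 1, tolerance = 1e-6)
  # T -> 0 approaches a sharp low-pass except at the cutoff shell
  sharp <- lowpass_volume(vol, 18)
  cold <- fermi_filter(vol, 18, temperature = 1e-9)
  off_shell <- abs(r - kc) > 0.01
  expect_lt(max(Mod(fft(cold$grid) - fft(sharp$grid))[off_shell]) /
              max(Mod(F0)), 1e-3)
})
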