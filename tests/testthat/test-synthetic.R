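test_that("sampled harmonic coefficients follow the equipartition variances", {
  p <- model_params(kappa = 2, sigma_bar = 50)
  n <- 10000
  sh <- sample_equilibrium_modes(p, l_sim = 10, n = n, seed = 7)
  l <- attr(sh, "l"); m <- attr(sh, "m")
  expect_true(all(l >= 2))
  for (lm in list(c(2, 0), c(5, 3))) {
    col <- which(l == lm[1] & m == lm[2])
    v_hat <- var(sh[, col])
    v <- 1 / (2 * (lm[1] + 2) * (lm[1] - 1) * (lm[1] * (lm[1] + 1) + 50))
    se <- v * sqrt(2 / n)
    expect_lt(abs(v_hat - v), 3 * se)
  }
  # doubling kappa rescales the same draw by exactly 1/sqrt(2)
  sh2 <- sample_equilibrium_modes(model_params(4, 50), l_sim = 10, n = n, seed = 7)
  expect_equal(unclass(sh2), unclass(sh) / sqrt(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(sample_equilibrium_modes(model_params(1, 50), l_sim = 1))
})

test_that("equatorial sections have the expected geometry", {
  p <- model_params(1, 0, radius = 0.8)
  sh <- sample_equilibrium_modes(p, l_sim = 6, n = 1, seed = 1)
  zero <- sh; zero[1, ] <- 0
  ct <- equatorial_contour(zero)
  expect_s3_class(ct, "contour")
  expect_equal(ct$radii, rep(0.8, 400), tolerance = 1e-14)
  expect_length(ct$angles, 400)
  # a pure zonal (l, m) = (2, 0) mode leaves the equator circular
  zonal <- zero
  zonal[1, attr(sh, "l") == 2 & attr(sh, "m") == 0] <- 0.05
  ctz <- equatorial_contour(zonal)
  expect_lt(diff(range(ctz$radii)), 1e-14)
  expect_equal(max(Mod(decompose_contour(ctz))), 0, tolerance = 1e-12)
  # apparent mean radius shrinks with off-equator sectioning (gently
  # fluctuating shape so the geometric cos(tilt) factor dominates)
  sh2 <- sample_equilibrium_modes(model_params(500, 0, radius = 0.8),
                                  l_sim = 6, n = 1, seed = 2)
  mr <- sapply(c(0, 10, 20, 30), function(tt)
    mean(equatorial_contour(sh2, tilt_deg = tt)$radii))
  expect_true(all(diff(mr) < 0))
  expect_equal(mr, 0.8 * cos(c(0, 10, 20, 30) * pi / 180), tolerance = 0.02)
})

test_that("stochastic generators are reproducible from their seed", {
  p <- model_params(2, 50)
  a <- sample_equilibrium_modes(p, l_sim = 12, n = 5, seed = 3)
  b <- sample_equilibrium_modes(p, l_sim = 12, n = 5, seed = 3)
  expect_identical(a, b)
  v1 <- simulate_droplet_video(p, optics_model(), n_frames = 3, seed = 9,
                               l_sim = 12)
  v2 <- simulate_droplet_video(p, optics_model(), n_frames = 3, seed = 9,
                               l_sim = 12)
  expect_identical(v1$frames[[2]]$pixels, v2$frames[[2]]$pixels)
  r1 <- simulate_rigid_rotation(rigid_config(seed = 5, n_rotations = 10))
  r2 <- simulate_rigid_rotation(rigid_config(seed = 5, n_rotations = 10))
  expect_identical(r1$radii, r2$radii)
  # the RNG state of the caller is left untouched
  set.seed(42); x <- rnorm(1)
  set.seed(42); invisible(sample_equilibrium_modes(p, l_sim = 12, seed = 1))
  expect_identical(rnorm(1), x)
})

test_that("rigid rotations freeze into a static shape as the step size vanishes", {
  cs <- simulate_rigid_rotation(rigid_config(beta = -40, n_rotations = 40, seed = 2))
  expect_equal(nrow(cs$radii), 40)
  ms <- aggregate_modes(decompose_contour(cs), min_frames = 30)
  expect_lt(max(ms$F2), 1e-12)
  expect_gt(max(ms$C2), 0)  # the quenched shape itself is rough
  # and a full-size rotation series produces genuine mode variance
  cs2 <- simulate_rigid_rotation(rigid_config(beta = 0, n_rotations = 100, seed = 2))
  expect_equal(nrow(cs2$radii), 100)
  ms2 <- aggregate_modes(decompose_contour(cs2))
  expect_gt(max(ms2$F2), 1e-6)
})

test_that("rendered frames honour the optics model", {
  ct <- contour(rep(12, 400), unit = "px")
  # no PSF, no noise: a clean disc of the right area
  fr0 <- render_frame(ct, optics_model(psf_sigma = 0, snr = Inf,
                                       background_level = 0))
  expect_equal(sum(fr0$pixels), pi * 12^2, tolerance = 0.01)
  # measured SNR close to the configured target
  opt <- optics_model(psf_sigma = 1.3, snr = 5)
  f1 <- render_frame(ct, opt, seed = 1)
  f2 <- render_frame(ct, opt, seed = 2)
  noise_sd <- sd(f1$pixels - f2$pixels) / sqrt(2)
  expect_lt(abs((1 - 0.2) / noise_sd - 5) / 5, 0.1)
  expect_error(render_frame(ct, opt, frame_dim = c(20, 20)), "too large")
})

test_that("fixed-cell mimics carry almost no fluctuating power", {
  p <- model_params(2, 50, radius = 0.78, l_max = 30)
  fixed <- simulate_droplet_video(p, optics_model(), n_frames = 40, seed = 11,
                                  fixed_shape = TRUE, l_sim = 30, m_max = 15)
  live <- simulate_droplet_video(p, optics_model(), n_frames = 40, seed = 12,
                                 l_sim = 30, m_max = 15)
  # ground-truth contours: the mimic is exactly static
  msF <- aggregate_modes(decompose_contour(fixed$contours), min_frames = 30)
  msL <- aggregate_modes(decompose_contour(live$contours), min_frames = 30)
  expect_lt(max(msF$F2), 1e-12)
  expect_gt(mean(msL$F2[2:10]), 1e-6)
})

test_that("off-equator sectioning shifts fits only modestly within 20 degrees", {
  z <- zplane_robustness(model_params(2, 50, l_max = 40), c(0, 10, 20),
                         n_frames = 400, seed = 5, l_sim = 40, m_max = 20)
  expect_equal(z$kappa_rel_dev[z$tilt_deg == 0], 0)
  expect_true(all(diff(z$mean_radius) < 0))
  # small relative to the population log-normal band (about a factor 2.4)
  expect_lt(max(abs(z$sigma_rel_dev)), 0.5)
  expect_lt(max(abs(z$kappa_rel_dev)), 0.5)
})
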