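test_that("Fourier decomposition follows the stated amplitude convention", {
  phi <- 2 * pi * (0:399) / 400
  # perfect circle: no power anywhere
  expect_equal(max(Mod(decompose_contour(contour(rep(7, 400))))), 0,
               tolerance = 1e-12)
  # D = R(1 + 2 eps cos q phi)  ->  |v_q| = eps
  eps <- 0.013
  ct <- contour(5 * (1 + 2 * eps * cos(4 * phi)))
  v <- decompose_contour(ct)
  expect_equal(unname(Mod(v[4])), eps, tolerance = 1e-10)
  expect_lt(max(Mod(v[-4])), 1e-12)
  # Parseval for a band-limited profile: var(D/Rbar) = 2 sum |v_q|^2
  set.seed(1)
  a <- rnorm(10, 0, 0.01)
  prof <- 1 + sapply(phi, function(p) sum(a * cos((1:10) * p + (1:10))))
  v2 <- decompose_contour(contour(10 * prof), q_max = 15)
  expect_equal(2 * sum(Mod(v2)^2), mean((prof / mean(prof) - 1)^2),
               tolerance = 1e-4)
})

test_that("base-shape correction splits static from fluctuating power", {
  phi <- 2 * pi * (0:399) / 400
  # identical frames: everything is static
  radii <- matrix(rep(6 * (1 + 0.04 * cos(2 * phi)), 40), 40, byrow = TRUE)
  ms <- aggregate_modes(decompose_contour(contour_series(radii)))
  expect_equal(ms$F2, rep(0, 15), tolerance = 1e-14)
  expect_equal(ms$C2[2], 0.02^2, tolerance = 1e-10)
  expect_equal(ms$circularity, ms$C2[2])
  # zero-mean fluctuation in one mode: C2 ~ 0, F2 ~ the injected variance
  set.seed(4)
  amp <- rnorm(2000, 0, 0.01)
  radii2 <- 8 * (1 + outer(2 * amp, cos(3 * phi)))
  ms2 <- aggregate_modes(decompose_contour(contour_series(radii2)))
  expect_lt(ms2$C2[3], 1e-5)
  expect_equal(ms2$F2[3], var(amp) * (2000 - 1) / 2000, tolerance = 0.01)
  # exact algebra and frame-order invariance
  expect_equal(ms2$F2 + ms2$C2, ms2$mean_power, tolerance = 1e-14)
  perm <- sample(nrow(radii2))
  ms3 <- aggregate_modes(decompose_contour(contour_series(radii2[perm, ])))
  expect_equal(ms3$F2, ms2$F2, tolerance = 1e-12)
  expect_error(aggregate_modes(decompose_contour(contour_series(radii2[1:10, ]))),
               "valid frames")
})

test_that("mode autocorrelation separates correlated dynamics from white noise", {
  set.seed(2)
  n <- 4000
  white <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)), ncol = 1)
  aw <- mode_autocorrelation(white, 1, lag_max = 10)
  expect_lt(max(abs(aw$acf[aw$lag >= 1])), 4 / sqrt(n))
  # Ornstein-Uhlenbeck with lag-1 correlation phi
  phi <- exp(-1 / 8)
  x <- as.numeric(stats::arima.sim(list(ar = phi), n, sd = 1))
  ou <- matrix(complex(real = x), ncol = 1)
  ao <- mode_autocorrelation(ou, 1, lag_max = 10)
  expect_equal(ao$acf[ao$lag == 1], phi, tolerance = 0.1)
  expect_warning(out <- mode_autocorrelation(matrix(complex(real = rep(1, 200)),
                                                    ncol = 1), 1),
                 "constant")
  expect_null(out)
})

test_that("a small center shift perturbs mode 1 strongly but higher modes weakly", {
  # star-convex shape with a q = 3 ripple, re-sampled about a shifted center
  n <- 4000
  th <- 2 * pi * (0:(n - 1)) / n
  R <- 10 * (1 + 0.02 * cos(3 * th))
  x <- R * cos(th); y <- R * sin(th)
  resample <- function(dx) {
    ang <- atan2(y, x - dx) %% (2 * pi)
    r <- sqrt((x - dx)^2 + y^2)
    o <- order(ang)
    grid <- 2 * pi * (0:399) / 400
    approx(c(ang[o], ang[o][1] + 2 * pi), c(r[o], r[o][1]), xout = grid)$y
  }
  v0 <- decompose_contour(resample(0))
  v1 <- decompose_contour(resample(0.1))
  expect_gt(Mod(v1[1]), 0.004)                        # ~ delta / (2 R)
  expect_lt(abs(Mod(v1[3]) - Mod(v0[3])), 1e-4)       # second-order only
})
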