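test_that("the fit error is a symmetric RMS log measure", {
  expect_equal(fit_error(c(1, 2, 4), c(1, 2, 4)), 0)
  expect_equal(fit_error(c(1, 2, 4), 10 * c(1, 2, 4)), 1)     # exact log10 offset
  a <- c(0.5, 1, 3); b <- c(0.7, 0.9, 2)
  expect_equal(fit_error(a, b), fit_error(b, a))
  expect_error(fit_error(c(1, -1, 2), c(1, 1, 1)), "non-positive")
  sp <- model_spectrum(model_params(1, 10))
  ms <- aggregate_modes(matrix(complex(real = rnorm(40 * 15, 0, 0.01)), 40, 15))
  expect_gte(fit_error(ms, sp), 0)
})

test_that("noiseless model spectra are recovered essentially exactly", {
  sp <- model_spectrum(model_params(kappa = 2, sigma_bar = 50))
  fit <- helfrich_fit(data.frame(q = sp$q, F2 = sp$power), radius_um = 1)
  expect_lt(abs(coef(fit)[["kappa"]] / 2 - 1), 0.01)
  expect_lt(abs(coef(fit)[["sigma_bar"]] / 50 - 1), 0.01)
  expect_lt(fit$errors[["full"]], 1e-6)
  expect_true(fit$converged)
  expect_false(fit$crossover_beyond_qmax)
  expect_equal(residuals(fit), rep(0, 14), tolerance = 1e-5)
  expect_equal(predict(fit), fitted(fit))
  # deterministic: identical input gives bitwise-identical estimates
  fit2 <- helfrich_fit(data.frame(q = sp$q, F2 = sp$power), radius_um = 1)
  expect_identical(coef(fit), coef(fit2))
})

test_that("simulated granules are recovered within the expected tolerances", {
  p <- model_params(2, 50)
  reps <- t(sapply(1:10, function(s) {
    sh <- sample_equilibrium_modes(p, n = 1000, m_max = 15, seed = s)
    ms <- aggregate_modes(decompose_contour(equatorial_contour(sh)))
    f <- helfrich_fit(ms, radius_um = 1)
    c(k = coef(f)[["kappa"]], s = coef(f)[["kappa"]] * coef(f)[["sigma_bar"]],
      best = f$errors[["full"]] < f$errors[["tension_only"]] &&
             f$errors[["full"]] < f$errors[["bending_only"]])
  }))
  expect_lt(median(abs(reps[, "k"] / 2 - 1)), 0.2)
  expect_lt(median(abs(reps[, "s"] / 100 - 1)), 0.25)
  # with both terms present the full model always fits best
  expect_true(all(reps[, "best"] == 1))
})

test_that("rigidity degeneracy beyond the fitted window is flagged", {
  sp <- model_spectrum(model_params(2, 1e4))     # crossover mode ~ 100 >> 15
  fit <- helfrich_fit(data.frame(q = sp$q, F2 = sp$power), radius_um = 1)
  expect_true(fit$crossover_beyond_qmax)
  # a tension-only description is then essentially as good: small delta error
  expect_lt(fit$delta_error_bending, 0.03)
  # conversely an in-window crossover carries rigidity information
  sp2 <- model_spectrum(model_params(2, 50))
  fit2 <- helfrich_fit(data.frame(q = sp2$q, F2 = sp2$power), radius_um = 1)
  expect_gt(fit2$delta_error_bending, 0.03)
})

test_that("fits refuse inadequate spectra and flag bound solutions", {
  expect_error(helfrich_fit(data.frame(q = 2:5, F2 = c(1, 1, 1, 1) * 1e-4)),
               "fewer than 5")
  sp <- model_spectrum(model_params(2, 50))
  dat <- data.frame(q = sp$q, F2 = sp$power)
  dat$F2[dat$q > 8] <- -1        # killed modes are dropped, enough survive
  fit <- helfrich_fit(dat, radius_um = 1)
  expect_equal(nrow(fit$data), 7)
  # an un-modellable rising spectrum drives the optimizer to its bounds
  rising <- data.frame(q = 2:15, F2 = 1e-6 * (2:15)^3)
  frise <- helfrich_fit(rising, radius_um = 1)
  expect_false(frise$converged)
})

test_that("fit methods print, plot and simulate coherently", {
  sp <- model_spectrum(model_params(2, 50))
  fit <- helfrich_fit(data.frame(q = sp$q, F2 = sp$power), radius_um = 0.8)
  expect_output(print(fit), "kappa")
  expect_output(print(summary(fit)), "delta error")
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f); plot(fit); plot(sp); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
  # physical tension follows the unit conversion
  u <- convert_units(fit)
  expect_equal(u$sigma_physical, fit$sigma_physical, tolerance = 1e-12)
  # parametric bootstrap: simulated series reproduce the fitted spectrum
  cs <- simulate(fit, nsim = 2000, seed = 5, l_sim = 40, m_max = 15)
  ms <- aggregate_modes(decompose_contour(cs))
  refit <- helfrich_fit(ms, radius_um = 0.8)
  expect_lt(abs(coef(refit)[["kappa"]] / coef(fit)[["kappa"]] - 1), 0.25)
})
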