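test_that("the gradient stencil is exact on polynomials up to degree four", {
  nr <- 21; nc <- 19
  r <- matrix(seq_len(nr), nr, nc); c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  g <- gradient_field(3 * r + 2 * c)
  inner <- function(M) M[3:(nr - 2), 3:(nc - 2)]
  expect_equal(inner(g$gr), matrix(3, nr - 4, nc - 4), tolerance = 1e-12)
  expect_equal(inner(g$gc), matrix(2, nr - 4, nc - 4), tolerance = 1e-12)
  # random quartics in each axis, exact through degree 4
  set.seed(3)
  a <- rnorm(5, 0, 0.1); b <- rnorm(5, 0, 0.1)
  I <- outer(seq_len(nr), seq_len(nc), function(x, y)
    a[1]*x + a[2]*x^2 + a[3]*x^3 + a[4]*x^4 + b[1]*y + b[2]*y^3 + b[5]*y^4)
  g2 <- gradient_field(I)
  dr_true <- outer(seq_len(nr), seq_len(nc), function(x, y)
    a[1] + 2*a[2]*x + 3*a[3]*x^2 + 4*a[4]*x^3)
  expect_equal(inner(g2$gr), inner(dr_true), tolerance = 1e-9)
  expect_error(gradient_field(matrix(0, 4, 4)), "stencil")
})

test_that("the gradient of a smooth blob matches its analytic derivative", {
  s <- 4
  I <- outer(1:41, 1:41, function(x, y) exp(-((x - 21)^2 + (y - 21)^2) / (2 * s^2)))
  g <- gradient_field(I)
  dr_true <- outer(1:41, 1:41, function(x, y) -(x - 21) / s^2 *
                     exp(-((x - 21)^2 + (y - 21)^2) / (2 * s^2)))
  err <- max(abs((g$gr - dr_true)[5:37, 5:37]))
  expect_lt(err, 1e-3)   # fourth-order accurate at unit grid spacing
})

test_that("difference-of-Gaussians detection finds discs and ignores noise", {
  fr <- disc_frame(radius = 12, seed = 1)
  det <- detect_granules(fr)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt(sum((c(det$row, det$col) - frame_center(fr))^2)), 1)
  # blank and pure-noise frames yield nothing
  expect_equal(nrow(detect_granules(matrix(0.3, 64, 64))), 0)
  set.seed(9)
  noise <- matrix(0.2 + rnorm(64 * 64, 0, 0.16), 64, 64)
  expect_equal(nrow(detect_granules(pmax(noise, 0))), 0)
  # two discs with separated centers give two seeds
  f1 <- disc_frame(12, snr = Inf, frame_dim = c(100, 100), center = c(35, 35))
  f2 <- disc_frame(12, snr = Inf, frame_dim = c(100, 100), center = c(65, 65))
  set.seed(2)
  two <- f1$pixels + f2$pixels - 0.2 + matrix(rnorm(1e4, 0, 0.16), 100)
  d2 <- detect_granules(image_frame(pmax(two, 0)))
  expect_equal(nrow(d2), 2)
})

test_that("flood-fill extent thresholds at half maximum and rejects small areas", {
  # uniform disc on zero background: mask recovers the disc exactly
  disc <- matrix(0, 50, 50)
  rr <- row(disc) - 25; cc <- col(disc) - 25
  disc[rr^2 + cc^2 <= 10^2] <- 1
  ext <- estimate_extent(disc, c(25, 25))
  expect_identical(ext$mask, disc == 1)
  expect_true(ext$accepted)
  expect_equal(ext$centroid, c(25, 25), tolerance = 1e-9)
  # a radius-5 granule (area ~ 79 px) is below the 100 px cut
  fr5 <- disc_frame(5, seed = 2, frame_dim = c(48, 48))
  e5 <- estimate_extent(fr5, frame_center(fr5))
  expect_false(e5$accepted)
  expect_lt(e5$area, 100)
  # radius 10, clean rendering: half-maximum threshold recovers the area
  # within 10% (camera noise shifts the global maximum and shrinks the mask)
  fr10 <- disc_frame(10, snr = Inf)
  e10 <- estimate_extent(fr10, frame_center(fr10))
  expect_true(e10$accepted)
  expect_lt(abs(e10$area - pi * 100) / (pi * 100), 0.1)
  # seed below threshold: empty mask
  e0 <- estimate_extent(disc, c(2, 2))
  expect_equal(e0$area, 0L)
})

test_that("ray casting recovers boundaries to sub-pixel precision", {
  fr <- disc_frame(12, psf_sigma = 0.8, snr = Inf)
  ct <- extract_contour(fr, frame_center(fr), scale = 12, smooth_sigma = 0)
  expect_length(ct$radii, 400)
  expect_equal(diff(ct$angles), rep(2 * pi / 400, 399), tolerance = 1e-12)
  expect_true(all(ct$ray_valid))
  expect_lt(sqrt(mean((ct$radii - 12)^2)), 0.05)
  # a q = 3 ripple of 0.3 px amplitude is recovered from a single clean frame
  fr3 <- disc_frame(12, ripple_q = 3, ripple_amp = 0.3, psf_sigma = 0.8,
                    snr = Inf)
  ct3 <- extract_contour(fr3, frame_center(fr3), scale = 12, smooth_sigma = 0)
  amp <- 2 * unname(Mod(decompose_contour(ct3)[3])) * ct3$mean_radius
  expect_equal(amp, 0.3, tolerance = 0.25)
})

test_that("noisy round trips stay within the empirical extraction error", {
  p <- model_params(2, 50, radius = 0.78, l_max = 30)
  vid <- simulate_droplet_video(p, optics_model(), n_frames = 10, seed = 21,
                                l_sim = 30, m_max = 15)
  errs <- sapply(1:10, function(k) {
    fr <- vid$frames[[k]]
    det <- detect_granules(fr)
    ct <- extract_contour(fr, frame_center(fr), scale = det$scale[1])
    sqrt(mean((ct$radii[ct$ray_valid] -
                 vid$contours$radii[k, ct$ray_valid])^2))
  })
  expect_lt(mean(errs), 0.6)   # per-ray RMS at SNR 5 (mode averages do better)
})

test_that("discontinuous boundaries are rejected and circles always pass", {
  circ <- contour(rep(10, 400))
  for (jt in c(0.01, 0.1, 0.5)) expect_true(validate_contour(circ, jt))
  bad <- rep(10, 400); bad[200] <- 15   # one 0.5 * mean-radius jump
  v <- validate_contour(contour(bad))
  expect_false(as.logical(v))
  expect_true(all(attr(v, "bad_rays") %in% c(199, 200)))
  # two shallowly merged discs: the overhang produces a discontinuity
  v2 <- validate_contour(merged_disc_contour(R = 10, d = 19))
  expect_false(as.logical(v2))
  # a contour with a failed ray is invalid regardless of jumps
  miss <- contour(rep(10, 400), ray_valid = c(FALSE, rep(TRUE, 399)))
  expect_false(as.logical(validate_contour(miss)))
})

test_that("tracking links detections across frames deterministically", {
  static <- replicate(100, seed_row(20, 20), simplify = FALSE)
  tr <- track_granules(static)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 100)
  # steady drift of 0.2 px/frame stays one track
  drift <- lapply(1:100, function(f) seed_row(20 + 0.2 * f, 20))
  expect_length(track_granules(drift), 1)
  # a second granule appearing at frame 50 starts a second track
  appear <- lapply(1:100, function(f)
    if (f < 50) seed_row(20, 20) else rbind(seed_row(20, 20), seed_row(60, 60)))
  tr2 <- track_granules(appear)
  expect_length(tr2, 2)
  expect_equal(min(tr2[[2]]$frame), 50)
  # a gap longer than the 5-frame memory breaks the track
  gap <- lapply(1:40, function(f)
    if (f <= 15 || f > 22) seed_row(20, 20) else seed_row(20, 20)[0, ])
  expect_length(track_granules(gap), 2)
  # permutation of detections within frames does not change the linking
  two <- lapply(1:50, function(f) rbind(seed_row(20 + 0.1 * f, 20),
                                        seed_row(60 - 0.1 * f, 60)))
  two_rev <- lapply(two, function(d) d[2:1, ])
  t_a <- track_granules(two); t_b <- track_granules(two_rev)
  key <- function(tr) {
    k <- lapply(tr, function(d) d[order(d$frame), c("frame", "row", "col")])
    k[order(vapply(k, function(d) d$row[1], numeric(1)))]   # canonical order
  }
  expect_equal(key(t_a), key(t_b), ignore_attr = TRUE)
})
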