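# Shared fixtures, all generated in code.

# A rendered bright disc (optionally rippled) on a noisy background.
disc_frame <- function(radius = 12, ripple_q = 0, ripple_amp = 0,
                       psf_sigma = 1.3, snr = 5, seed = 1,
                       frame_dim = NULL, center = NULL) {
  phi <- 2 * pi * (0:399) / 400
  ct <- contour(radius + ripple_amp * cos(ripple_q * phi), unit = "px")
  render_frame(ct, optics_model(psf_sigma = psf_sigma, snr = snr),
               seed = seed, frame_dim = frame_dim, center = center)
}

frame_center <- function(fr) (dim(fr$pixels) + 1) / 2

# Radial profile of the union of two overlapping discs (radius R, centers
# separated by d along +x), about the center of the first disc: a classic
# overhang/merger shape with a discontinuous radial function.
merged_disc_contour <- function(R = 10, d = 14, n = 400) {
  phi <- 2 * pi * (0:(n - 1)) / n
  r1 <- rep(R, n)
  disc2 <- R^2 - d^2 * sin(phi)^2
  hit <- disc2 > 0 & cos(phi) > 0
  r2 <- ifelse(hit, d * cos(phi) + sqrt(pmax(0, disc2)), 0)
  contour(pmax(r1, r2), unit = "px")
}

# Closed-form log10 of the projection weight N_lq^2 P_lq(0)^2, an oracle
# independent of the package's recurrence (log-gamma / double factorials).
log10_weight_oracle <- function(l, q) {
  if ((l + q) %% 2 == 1) return(-Inf)
  ldf <- function(n) if (n <= 0) 0 else sum(log(seq(n, 1, by = -2)))
  logN2 <- log((2 * l + 1) / (4 * pi)) + lgamma(l - q + 1) - lgamma(l + q + 1)
  (logN2 + 2 * (ldf(l + q - 1) - ldf(l - q))) / log(10)
}

# Synthetic detection lists (no imaging) for tracking tests.
seed_row <- function(row, col, scale = 10, response = 1)
  data.frame(row = row, col = col, scale = scale, response = response)
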