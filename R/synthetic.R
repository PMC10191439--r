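#' Sample equilibrium spherical-harmonic interface modes
#'
#' Draws real spherical-harmonic deformation coefficients \eqn{u_{lm}} of a
#' quasi-spherical interface from the Boltzmann distribution of the Helfrich
#' free energy. Each independent real coefficient is zero-mean Gaussian with
#' \deqn{\langle u_{lm}^2 \rangle =
#'   \frac{k_B T}{\kappa (l+2)(l-1)[l(l+1) + \bar\sigma]}}
#' (with \eqn{\kappa} in \eqn{k_B T} units this is dimensionless). Degrees
#' \eqn{l = 0, 1} (volume and translation) are excluded by construction.
#'
#' Orders with \eqn{|m| > q_{max}} are exactly orthogonal to equatorial contour
#' modes \eqn{q \le q_{max}}, so Monte-Carlo studies of the projected spectrum
#' may band-limit with `m_max` at no cost in exactness; the default keeps all
#' orders.
#'
#' @param params a [model_params()] object; `l_max` is used as the simulated
#'   degree cutoff unless `l_sim` is given.
#' @param l_sim highest simulated degree (default `params$l_max`).
#' @param n number of independent shape draws.
#' @param m_max azimuthal band limit (default `l_sim`, i.e. no limit).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return an `n` x n_coeff matrix of coefficients (class `harmonic_shape`)
#'   with attributes `l` (degree), `m` (signed order: positive = cosine,
#'   negative = sine, zero = zonal), `base_radius` (um) and `params`.
#' @examples
#' sh <- sample_equilibrium_modes(model_params(2, 50), l_sim = 20, n = 3, seed = 1)
#' dim(sh)
#' @export
sample_equilibrium_modes <- function(params, l_sim = params$l_max, n = 1,
                                     m_max = l_sim, seed = NULL) {
  stopifnot(inherits(params, "model_params"), l_sim >= 2, n >= 1)
  if (params$sigma_bar < 0) stop("sigma_bar must be >= 0")
  idx <- harmonic_index(l_sim, m_max)
  l <- idx$l
  sd_lm <- sqrt(1 / (params$kappa * (l + 2) * (l - 1) *
                       (l * (l + 1) + params$sigma_bar)))
  u <- with_seed(seed, matrix(stats::rnorm(n * length(l)), nrow = n))
  u <- u * rep(sd_lm, each = n)    # column-wise scaling, matrix is column-major
  structure(u, l = l, m = idx$m, base_radius = params$radius, params = params,
            class = c("harmonic_shape", "matrix", "array"))
}

# Signed-order index (l, m) for real harmonics: l = 2..l_sim, m = -min(l,m_max)
# .. +min(l,m_max); m > 0 cosine, m < 0 sine, m = 0 zonal.
harmonic_index <- function(l_sim, m_max = l_sim) {
  l <- integer(0); m <- integer(0)
  for (ll in 2:l_sim) {
    mm <- min(ll, m_max)
    m <- c(m, seq(-mm, mm))
    l <- c(l, rep(ll, 2 * mm + 1))
  }
  list(l = l, m = m)
}

# Real orthonormal spherical-harmonic basis matrix: rows = coefficients
# indexed by (l, m signed), cols = surface points (theta, phi).
harmonic_basis <- function(l, m, theta, phi) {
  l_max <- max(l); m_max <- max(abs(m))
  P <- alegendre_norm(l_max, cos(theta), m_max = m_max)
  Pl <- attr(P, "l"); Pm <- attr(P, "m")
  B <- matrix(0, length(l), length(theta))
  key_p <- paste(Pl, Pm)
  rowmap <- match(paste(l, abs(m)), key_p)
  for (i in seq_along(l)) {
    p <- P[rowmap[i], ]
    B[i, ] <- if (m[i] == 0) p
              else if (m[i] > 0) sqrt(2) * p * cos(m[i] * phi)
              else sqrt(2) * p * sin(-m[i] * phi)
  }
  B
}

#' Equatorial (or off-equator) cross-section contour of a harmonic shape
#'
#' At `tilt_deg = 0`, evaluates \eqn{r(\phi) = R[1 + u(\pi/2, \phi)]} around
#' the equator; the Fourier modes of this contour follow the projected
#' Helfrich spectrum. A non-zero tilt emulates imaging a plane parallel to the
#' equator but displaced along the optical axis by \eqn{h = R\sin(tilt)}, as
#' happens when the focal plane misses the granule equator: the section is the
#' small circle at constant polar angle \eqn{\theta_0 = \pi/2 - tilt}, whose
#' apparent in-plane radius is, to first order in the deformation,
#' \deqn{\rho(\phi) = R\sin\theta_0\,[1 + u(\theta_0, \phi)/\sin^2\theta_0].}
#' The mean apparent radius therefore shrinks as \eqn{\cos(tilt)} while the
#' relative fluctuations are amplified by \eqn{1/\cos^2(tilt)}.
#'
#' @param shape a `harmonic_shape` (one or more rows).
#' @param tilt_deg angular offset of the sectioning plane from the equator,
#'   degrees (|tilt| < 90).
#' @param n_points number of contour points (default 400).
#' @return a [contour()] (single shape) or a `contour_series` (multiple rows),
#'   radii in micrometres.
#' @export
equatorial_contour <- function(shape, tilt_deg = 0, n_points = 400) {
  stopifnot(inherits(shape, "harmonic_shape"), abs(tilt_deg) < 90)
  l <- attr(shape, "l"); m <- attr(shape, "m")
  R <- attr(shape, "base_radius")
  theta0 <- pi / 2 - tilt_deg * pi / 180
  phi <- 2 * pi * (seq_len(n_points) - 1) / n_points
  B <- harmonic_basis(l, m, rep(theta0, n_points), phi)
  u <- unclass(shape) %*% B
  radii <- R * sin(theta0) * (1 + u / sin(theta0)^2)
  if (nrow(radii) == 1) contour(radii[1, ], unit = "um")
  else contour_series(radii, unit = "um")
}

#' Configuration for the rotating rigid-body simulator
#'
#' @param beta rotation-magnitude exponent: per-step rotation angles are drawn
#'   from Normal(0, SD = 2^beta) radians. Default 0 (SD of 1 radian).
#' @param n_rotations number of random rotations (default 100).
#' @param l_range spherical-harmonic degrees of the quenched roughness
#'   (default 2:15).
#' @param base_radius droplet radius (simulation units; default 1).
#' @param amplitude overall scale of the quenched deformation (default 0.05
#'   relative units, keeping shapes star-convex).
#' @param n_points contour points per cross-section (default 400).
#' @param seed optional integer seed.
#' @return object of class `rigid_config`.
#' @export
rigid_config <- function(beta = 0, n_rotations = 100, l_range = 2:15,
                         base_radius = 1, amplitude = 0.05,
                         n_points = 400, seed = NULL) {
  stopifnot(n_rotations >= 1, all(l_range >= 2))
  structure(list(beta = beta, n_rotations = as.integer(n_rotations),
                 l_range = as.integer(l_range), base_radius = base_radius,
                 amplitude = amplitude, n_points = as.integer(n_points),
                 seed = seed),
            class = "rigid_config")
}

# Rodrigues rotation matrix for axis (unit 3-vector) and angle (radians).
rotation_matrix <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Simulate a randomly rotating quenched rigid body
#'
#' Generates a rigid rough shape with pink-spectrum harmonic amplitudes
#' (\eqn{U_{lm}} uniform on \eqn{[0,1]} scaled by \eqn{1/l}, random phases) and
#' subjects it to a series of cumulative random rotations: each step rotates
#' about an axis drawn uniformly on the unit hemisphere by an angle drawn from
#' Normal(0, \eqn{2^\beta}). After each rotation the equatorial cross-section
#' is recorded. Such series mimic non-fluctuating (solid-like) granules whose
#' apparent boundary motion is rotation, not thermal flicker; their spectra
#' fit the Helfrich model poorly.
#'
#' @param config a [rigid_config()].
#' @return a `contour_series` with `n_rotations` contours; the quenched
#'   coefficients and rotation draws are reproducible from `config$seed`.
#' @export
simulate_rigid_rotation <- function(config) {
  stopifnot(inherits(config, "rigid_config"))
  with_seed(config$seed, {
    idx <- harmonic_index(max(config$l_range))
    keep <- idx$l %in% config$l_range
    l <- idx$l[keep]; m <- idx$m[keep]
    # pink-noise quenched amplitudes with random phases
    coef <- config$amplitude * (stats::runif(length(l)) / l) *
      cos(2 * pi * stats::runif(length(l)))
    t <- 2 * pi * (seq_len(config$n_points) - 1) / config$n_points
    equator <- rbind(cos(t), sin(t), 0)
    Rcum <- diag(3)
    radii <- matrix(NA_real_, config$n_rotations, config$n_points)
    for (k in seq_len(config$n_rotations)) {
      ax <- stats::rnorm(3)
      ax <- ax / sqrt(sum(ax^2))
      if (ax[3] < 0) ax <- -ax            # uniform on the upper hemisphere
      ang <- stats::rnorm(1, 0, 2^config$beta)
      Rcum <- rotation_matrix(ax, ang) %*% Rcum
      body <- t(Rcum) %*% equator         # body-frame directions of the lab equator
      theta <- acos(pmin(1, pmax(-1, body[3, ])))
      phi <- atan2(body[2, ], body[1, ])
      u <- as.numeric(coef %*% harmonic_basis(l, m, theta, phi))
      radii[k, ] <- config$base_radius * (1 + u)
    }
    contour_series(radii, unit = "um")
  })
}

#' Robustness of fitted parameters to off-equator sectioning
#'
#' Simulates one set of equipartition shape draws and re-sections the same
#' shapes with planes tilted away from the equator, refitting the spectrum at
#' each tilt. Pairing the tilts on identical draws isolates the geometric
#' effect of imaging off the granule equator from Monte-Carlo noise.
#'
#' @param params a [model_params()] ground truth.
#' @param tilt_grid tilts in degrees (within +/- 30); 0 is included as baseline
#'   if absent.
#' @param n_frames number of shape draws (default 1000).
#' @param seed integer seed.
#' @param l_sim,m_max passed to [sample_equilibrium_modes()].
#' @return data frame with one row per tilt: fitted `kappa`, `sigma_bar`,
#'   apparent `mean_radius`, and relative deviations of kappa and sigma from
#'   the tilt-0 fit.
#' @export
zplane_robustness <- function(params, tilt_grid = c(0, 10, 20), n_frames = 1000,
                              seed = NULL, l_sim = params$l_max,
                              m_max = l_sim) {
  stopifnot(all(abs(tilt_grid) <= 30))
  if (!any(tilt_grid == 0)) tilt_grid <- c(0, tilt_grid)
  shapes <- sample_equilibrium_modes(params, l_sim = l_sim, n = n_frames,
                                     m_max = m_max, seed = seed)
  rows <- lapply(tilt_grid, function(tt) {
    cs <- equatorial_contour(shapes, tilt_deg = tt)
    ms <- aggregate_modes(decompose_contour(cs, q_max = params$q_max),
                          mean_radius = mean(cs$radii))
    fit <- helfrich_fit(ms, radius_um = ms$mean_radius,
                        temperature = params$temperature,
                        l_max = params$l_max)
    data.frame(tilt_deg = tt,
               kappa = coef(fit)[["kappa"]],
               sigma_bar = coef(fit)[["sigma_bar"]],
               sigma_uN_per_m = fit$sigma_physical * 1e6,
               mean_radius = ms$mean_radius,
               error_full = fit$errors[["full"]])
  })
  out <- do.call(rbind, rows)
  base <- out[out$tilt_deg == 0, ][1, ]
  out$kappa_rel_dev <- out$kappa / base$kappa - 1
  out$sigma_rel_dev <- out$sigma_uN_per_m / base$sigma_uN_per_m - 1
  out
}
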