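#' @keywords internal
kB_SI <- 1.380649e-23   # Boltzmann constant, J/K (CODATA exact)

#' Model parameters for the Helfrich fluctuation spectrum
#'
#' Bundles the mechanical and geometric parameters of a quasi-spherical
#' condensate interface governed by the Helfrich free energy: bending rigidity
#' \eqn{\kappa} (in units of \eqn{k_B T}), dimensionless interfacial tension
#' \eqn{\bar\sigma = \sigma R^2 / \kappa}, mean radius \eqn{R} and absolute
#' temperature.
#'
#' @param kappa bending rigidity in \eqn{k_B T} units (> 0).
#' @param sigma_bar dimensionless interfacial tension (\eqn{\ge 0}).
#' @param radius mean granule radius in micrometres (> 0).
#' @param temperature absolute temperature in kelvin; default 310 K
#'   (live mammalian cells).
#' @param l_max truncation degree of the spherical-harmonic sum (default 75).
#' @param q_max highest contour mode used (default 15; microscope resolution
#'   limits reliable modes to about 15 for the smallest granules).
#' @return an object of class `model_params`.
#' @examples
#' model_params(kappa = 2, sigma_bar = 50, radius = 1)
#' @export
model_params <- function(kappa, sigma_bar, radius = 1, temperature = 310,
                         l_max = 75, q_max = 15) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa > 0, is.finite(kappa),
            is.numeric(sigma_bar), length(sigma_bar) == 1, sigma_bar >= 0,
            is.finite(sigma_bar),
            radius > 0, temperature > 0,
            q_max >= 2, l_max >= q_max)
  structure(list(kappa = kappa, sigma_bar = sigma_bar, radius = radius,
                 temperature = temperature,
                 l_max = as.integer(l_max), q_max = as.integer(q_max)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "Helfrich interface parameters:\n  kappa     = %g kB*T\n  sigma_bar = %g (sigma*R^2/kappa)\n  radius    = %g um, T = %g K, l_max = %d, q_max = %d\n",
    x$kappa, x$sigma_bar, x$radius, x$temperature, x$l_max, x$q_max))
  invisible(x)
}

# Per-degree denominator sum S_q(sigma_bar) = sum_l w_lq / ((l+2)(l-1)[l(l+1)+sigma_bar]).
# W is a projection_matrix(q_max, l_max). Returns vector over q = 2..q_max.
spectrum_sum <- function(W, sigma_bar, tension_limit = FALSE) {
  l <- seq_len(ncol(W)) - 1
  denom <- if (tension_limit) (l + 2) * (l - 1)
           else (l + 2) * (l - 1) * (l * (l + 1) + sigma_bar)
  denom[l < 2] <- Inf   # l = 0, 1 never carry weight; guard the division
  as.numeric(W %*% (1 / denom))
}

#' Theoretical time-averaged equatorial fluctuation spectrum
#'
#' Predicted mean-square Fourier amplitudes \eqn{\langle |v_q|^2 \rangle} of
#' the relative radial profile \eqn{(D(\phi) - \bar R)/\bar R} of the
#' equatorial cross-section of a thermally fluctuating Helfrich interface:
#' \deqn{\langle |v_q|^2 \rangle = \frac{k_B T}{\kappa} \sum_{l=q}^{l_{max}}
#'   \frac{N_{lq}^2 P_{lq}(0)^2}{(l+2)(l-1)[l(l+1) + \bar\sigma]}.}
#' With \eqn{\kappa} expressed in \eqn{k_B T} the spectrum is dimensionless.
#'
#' The `tension_only` variant is the analytic \eqn{\kappa \to 0} limit at fixed
#' physical tension (naively setting \eqn{\kappa = 0} is singular): the
#' denominator collapses to \eqn{(l+2)(l-1)\,\sigma R^2/(k_B T)}, so the single
#' parameter is \eqn{s = \kappa\,\bar\sigma = \sigma R^2/(k_B T)}. The
#' `bending_only` variant sets \eqn{\bar\sigma = 0}.
#'
#' @param params a [model_params()] object.
#' @param variant one of `"full"`, `"tension_only"`, `"bending_only"`.
#' @param conv_tol if non-`NULL`, the sum is re-evaluated with
#'   `l_max + 25`; a relative change above `conv_tol` in any mode triggers a
#'   warning flagging non-convergence. Default `NULL` (skip the check; the
#'   default `l_max = 75` converges to better than 1e-3 for `q <= 15`).
#' @return object of class `helfrich_spectrum`: a data frame with columns
#'   `q` (mode index `2..q_max`) and `power` (dimensionless
#'   \eqn{\langle |v_q|^2 \rangle}).
#' @examples
#' sp <- model_spectrum(model_params(kappa = 2, sigma_bar = 50))
#' plot(sp)
#' @export
model_spectrum <- function(params, variant = c("full", "tension_only", "bending_only"),
                           conv_tol = NULL) {
  stopifnot(inherits(params, "model_params"))
  variant <- match.arg(variant)
  pw <- function(l_max) {
    W <- projection_matrix(params$q_max, l_max)
    switch(variant,
      full         = spectrum_sum(W, params$sigma_bar) / params$kappa,
      bending_only = spectrum_sum(W, 0) / params$kappa,
      tension_only = spectrum_sum(W, 0, tension_limit = TRUE) /
                       (params$kappa * params$sigma_bar))
  }
  if (variant == "tension_only" && params$sigma_bar <= 0)
    stop("tension_only variant requires sigma_bar > 0")
  power <- pw(params$l_max)
  if (!is.null(conv_tol)) {
    power2 <- pw(params$l_max + 25L)
    rel <- max(abs(power2 - power) / power)
    if (rel > conv_tol)
      warning(sprintf(
        "spectrum sum not converged at l_max = %d (relative change %.2g when extended by 25 degrees)",
        params$l_max, rel))
  }
  structure(data.frame(q = 2:params$q_max, power = power),
            class = c("helfrich_spectrum", "data.frame"),
            params = params, variant = variant)
}

#' @export
plot.helfrich_spectrum <- function(x, ...) {
  graphics::plot(x$q, x$power, log = "xy", type = "b", pch = 16,
                 xlab = "mode q",
                 ylab = expression(paste("<|", v[q], "|"^2, ">")), ...)
  invisible(x)
}

#' Convert dimensionless fitted parameters to physical units
#'
#' Given a bending rigidity in \eqn{k_B T} units and a dimensionless tension
#' \eqn{\bar\sigma = \sigma R^2/\kappa}, returns the physical rigidity
#' \eqn{\kappa_{phys} = \kappa k_B T} (joules) and tension
#' \eqn{\sigma = \bar\sigma\,\kappa_{phys}/R^2} (N/m).
#'
#' @param kappa bending rigidity in \eqn{k_B T} units, or a [helfrich_fit()]
#'   object (in which case `sigma_bar`, `temperature` and `radius_m` default to
#'   the fit's values).
#' @param sigma_bar dimensionless interfacial tension.
#' @param temperature absolute temperature in K.
#' @param radius_m granule radius in metres.
#' @return list with components `sigma_physical` (N/m) and `kappa_physical` (J).
#' @examples
#' convert_units(1, sigma_bar = 1, temperature = 310, radius_m = 1e-6)
#' @export
convert_units <- function(kappa, sigma_bar = NULL, temperature = NULL,
                          radius_m = NULL) {
  if (inherits(kappa, "helfrich_fit")) {
    fit <- kappa
    if (is.null(sigma_bar)) sigma_bar <- fit$coefficients[["sigma_bar"]]
    if (is.null(temperature)) temperature <- fit$temperature
    if (is.null(radius_m)) radius_m <- fit$radius_um * 1e-6
    kappa <- fit$coefficients[["kappa"]]
  }
  stopifnot(kappa > 0, sigma_bar >= 0, temperature > 0, radius_m > 0)
  kappa_J <- kappa * kB_SI * temperature
  list(sigma_physical = sigma_bar * kappa_J / radius_m^2,
       kappa_physical = kappa_J)
}
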