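#' Fourier decomposition of a radial contour
#'
#' Computes the one-sided Fourier amplitudes of the relative radial profile,
#' \deqn{v_q = \frac{1}{N} \sum_k \frac{D(\phi_k) - \bar R}{\bar R}
#'   e^{-i q \phi_k}, \qquad q = 1..q_{max}.}
#' Under this convention a pure cosine ripple \eqn{D = R(1 + 2\epsilon\cos
#' q\phi)} has \eqn{|v_q| = \epsilon}. Mode 1 mixes with center-placement
#' error and is computed but excluded from spectrum fits.
#'
#' @param x a [contour()], a `contour_series`, or a numeric radii vector.
#' @param q_max highest mode returned (default 15).
#' @param base_radius optional reference radius replacing the realized mean
#'   \eqn{\bar R} in the normalization. Measured data must use the default
#'   (the true radius is unknown); ground-truth analyses of simulated shapes
#'   may pass the known base radius, which makes the amplitudes exactly
#'   linear in the harmonic coefficients even for large deformations.
#' @param ... unused.
#' @return for a single contour, a complex vector of length `q_max` named
#'   `q1..q15`; for a series, a complex matrix (frames x modes), rows of
#'   invalid contours set to `NA`.
#' @examples
#' phi <- 2 * pi * (0:399) / 400
#' Mod(decompose_contour(contour(10 * (1 + 0.02 * cos(3 * phi)))))[3]  # 0.01
#' @export
decompose_contour <- function(x, q_max = 15, base_radius = NULL, ...)
  UseMethod("decompose_contour")

#' @export
decompose_contour.default <- function(x, q_max = 15, base_radius = NULL, ...) {
  radii <- as.numeric(x)
  n <- length(radii)
  stopifnot(n > 2 * q_max, all(is.finite(radii)))
  rbar <- if (is.null(base_radius)) mean(radii) else base_radius
  co <- stats::fft((radii - rbar) / rbar) / n
  out <- co[2:(q_max + 1)]
  names(out) <- paste0("q", 1:q_max)
  out
}

#' @export
decompose_contour.contour <- function(x, q_max = 15, base_radius = NULL, ...) {
  if (!x$valid) stop("contour is invalid; refusing to decompose")
  decompose_contour.default(x$radii, q_max, base_radius)
}

#' @export
decompose_contour.contour_series <- function(x, q_max = 15, base_radius = NULL,
                                             ...) {
  n <- ncol(x$radii)
  stopifnot(n > 2 * q_max)
  rbar <- if (is.null(base_radius)) rowMeans(x$radii)
          else rep(base_radius, nrow(x$radii))
  rel <- x$radii / rbar - 1
  co <- t(stats::mvfft(t(rel))) / n     # row-wise DFT
  out <- co[, 2:(q_max + 1), drop = FALSE]
  colnames(out) <- paste0("q", 1:q_max)
  out[!x$valid, ] <- NA
  structure(out, mean_radius = mean(rbar[x$valid]), unit = x$unit)
}

#' Time-averaged mode statistics with base-shape correction
#'
#' Aggregates per-frame mode amplitudes into time statistics, splitting each
#' mode into a fluctuating and a static (base-shape) part:
#' \deqn{|F_q|^2 = \langle |v_q|^2 \rangle - |\langle v_q \rangle|^2, \qquad
#'       |C_q|^2 = |\langle v_q \rangle|^2.}
#' \eqn{|F_q|^2} replaces the raw \eqn{\langle |v_q|^2 \rangle} as the thermal
#' fluctuation measure; \eqn{|C_2|^2} measures how elongated the granule's
#' mean shape is (circularity).
#'
#' @param amps complex matrix of per-frame amplitudes from
#'   [decompose_contour()] (frames x modes); rows with `NA` (invalid frames)
#'   are dropped.
#' @param min_frames minimum number of valid frames required (default 30).
#' @param mean_radius mean granule radius to attach (um); taken from the
#'   `mean_radius` attribute of `amps` when present.
#' @return object of class `mode_stats`: list with `q`, `mean_power`
#'   \eqn{\langle|v_q|^2\rangle}, `F2` \eqn{=|F_q|^2}, `C2` \eqn{=|C_q|^2},
#'   `circularity` \eqn{=|C_2|^2}, `n_frames`, `mean_radius`.
#' @export
aggregate_modes <- function(amps, min_frames = 30, mean_radius = NA_real_) {
  stopifnot(is.matrix(amps))
  ok <- stats::complete.cases(amps)
  amps <- amps[ok, , drop = FALSE]
  if (nrow(amps) < min_frames)
    stop(sprintf("only %d valid frames; need at least %d", nrow(amps), min_frames))
  if (is.na(mean_radius) && !is.null(attr(amps, "mean_radius")))
    mean_radius <- attr(amps, "mean_radius")
  q <- seq_len(ncol(amps))
  mean_power <- colMeans(Mod(amps)^2)
  static <- Mod(colMeans(amps))^2
  F2 <- pmax(0, mean_power - static)
  structure(list(q = q, mean_power = unname(mean_power), F2 = unname(F2),
                 C2 = unname(static), circularity = unname(static[q == 2]),
                 n_frames = nrow(amps), mean_radius = mean_radius),
            class = "mode_stats")
}

#' @export
print.mode_stats <- function(x, ...) {
  cat(sprintf("Mode statistics over %d frames (mean radius %.3g):\n",
              x$n_frames, x$mean_radius))
  cat(sprintf("  circularity |C2|^2 = %.3g\n", x$circularity))
  df <- data.frame(q = x$q, mean_power = x$mean_power, F2 = x$F2, C2 = x$C2)
  print(utils::head(df, 8), row.names = FALSE)
  if (length(x$q) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.mode_stats <- function(x, ...) {
  data.frame(q = x$q, mean_power = x$mean_power, F2 = x$F2, C2 = x$C2)
}

#' Temporal autocorrelation of one fluctuation mode
#'
#' Normalized autocorrelation of \eqn{Re(v_q(t) - \langle v_q \rangle)} versus
#' lag. Live thermal fluctuations decorrelate over a finite time, whereas
#' frame-to-frame detection noise is white; constant series (zero variance)
#' are flagged undefined.
#'
#' @param amps complex amplitude matrix (frames x modes).
#' @param q mode index.
#' @param lag_max maximum lag (default 50).
#' @return data frame with columns `lag` and `acf`, or `NULL` (with a warning)
#'   if the series is constant.
#' @export
mode_autocorrelation <- function(amps, q, lag_max = 50) {
  stopifnot(is.matrix(amps), q >= 1, q <= ncol(amps))
  x <- Re(amps[, q])
  x <- x[is.finite(x)]
  if (length(x) < 100) stop("need at least 100 valid frames")
  if (stats::var(x) == 0) {
    warning("constant mode series; autocorrelation undefined")
    return(NULL)
  }
  a <- stats::acf(x - mean(x), lag.max = lag_max, plot = FALSE,
                  demean = FALSE)
  data.frame(lag = drop(a$lag), acf = drop(a$acf))
}
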