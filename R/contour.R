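#' Construct a radial boundary contour
#'
#' A contour is the radial boundary \eqn{D(\phi)} of one granule in one frame,
#' sampled at `n` evenly spaced angles on \eqn{[0, 2\pi)}.
#'
#' @param radii radial distances \eqn{D(\phi)} from the center, one per angle.
#' @param center numeric `(row, col)` sub-pixel center, or `NA` for synthetic
#'   contours with no image attached.
#' @param ray_valid logical vector flagging rays where the edge was found.
#' @param unit `"px"` or `"um"`.
#' @return object of class `contour` with fields `angles`, `radii`, `center`,
#'   `ray_valid`, `valid` (overall flag set by [validate_contour()]),
#'   `mean_radius`.
#' @export
contour <- function(radii, center = c(NA_real_, NA_real_),
                    ray_valid = rep(TRUE, length(radii)), unit = "px") {
  n <- length(radii)
  stopifnot(n >= 4, length(ray_valid) == n)
  structure(list(
    angles = 2 * pi * (seq_len(n) - 1) / n,
    radii = as.numeric(radii),
    center = center,
    ray_valid = ray_valid,
    valid = all(ray_valid) && all(radii > 0, na.rm = TRUE),
    mean_radius = mean(radii[ray_valid]),
    unit = unit), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("Radial contour: %d rays, mean radius %.3f %s, %d invalid rays%s\n",
              length(x$radii), x$mean_radius, x$unit, sum(!x$ray_valid),
              if (x$valid) "" else " [invalid]"))
  invisible(x)
}

# A time series of contours sharing one angular grid: radii is an
# (n_frames x n_points) matrix.
contour_series <- function(radii, unit = "px",
                           valid = rep(TRUE, nrow(radii))) {
  stopifnot(is.matrix(radii), length(valid) == nrow(radii))
  n <- ncol(radii)
  structure(list(angles = 2 * pi * (seq_len(n) - 1) / n,
                 radii = radii, valid = valid, unit = unit),
            class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf("Contour series: %d frames x %d rays (%d valid frames), unit %s\n",
              nrow(x$radii), ncol(x$radii), sum(x$valid), x$unit))
  invisible(x)
}
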