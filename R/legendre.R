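#' Fully normalized associated Legendre functions
#'
#' Evaluates \eqn{\bar P_{lm}(x) = N_{lm} P_{lm}(x)} for all degrees
#' \eqn{l \le l_{max}} and orders \eqn{m \le \min(l, m_{max})}, where
#' \eqn{N_{lm}^2 = (2l+1)/(4\pi) \cdot (l-m)!/(l+m)!} is the spherical-harmonic
#' normalization. The orthonormal real harmonics are then
#' \eqn{Y_{l0} = \bar P_{l0}} and
#' \eqn{Y_{lm}^{c,s} = \sqrt 2\, \bar P_{lm} \{\cos, \sin\}(m\phi)} for
#' \eqn{m > 0}.
#'
#' Uses the standard stable three-term recurrence on the normalized functions
#' (no factorials are ever formed), accurate well beyond \eqn{l = 150} where a
#' naive evaluation of \eqn{P_{lm}} overflows.
#'
#' @param l_max maximum degree (integer \eqn{\ge 0}).
#' @param x numeric vector of evaluation points in \eqn{[-1, 1]}
#'   (\eqn{x = \cos\theta}).
#' @param m_max maximum order to evaluate (default `l_max`).
#' @return numeric matrix with one row per \eqn{(l, m)} pair and one column per
#'   element of `x`; attributes `l` and `m` give the degree and order of each
#'   row (ordered by m, then l).
#' @keywords internal
alegendre_norm <- function(l_max, x, m_max = l_max) {
  stopifnot(l_max >= 0, m_max >= 0, all(abs(x) <= 1 + 1e-12))
  x <- pmin(1, pmax(-1, as.numeric(x)))
  m_max <- min(m_max, l_max)
  nx <- length(x)
  sx <- sqrt(pmax(0, 1 - x^2))

  l_idx <- integer(0); m_idx <- integer(0)
  rows <- vector("list", m_max + 1)
  pmm <- rep(1 / sqrt(4 * pi), nx)      # \bar P_00
  for (m in 0:m_max) {
    if (m > 0) pmm <- sqrt((2 * m + 1) / (2 * m)) * sx * pmm
    block <- matrix(0, l_max - m + 1, nx)
    block[1, ] <- pmm
    if (l_max > m) {
      block[2, ] <- sqrt(2 * m + 3) * x * pmm
      if (l_max > m + 1) {
        for (l in (m + 2):l_max) {
          a_l  <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          a_l1 <- sqrt((4 * (l - 1)^2 - 1) / ((l - 1)^2 - m^2))
          block[l - m + 1, ] <- a_l * (x * block[l - m, ] - block[l - m - 1, ] / a_l1)
        }
      }
    }
    rows[[m + 1]] <- block
    l_idx <- c(l_idx, m:l_max)
    m_idx <- c(m_idx, rep(m, l_max - m + 1))
  }
  out <- do.call(rbind, rows)
  attr(out, "l") <- l_idx
  attr(out, "m") <- m_idx
  out
}

#' Geometric projection weights for the equatorial fluctuation spectrum
#'
#' Computes the dimensionless weights \eqn{N_{lq}^2 P_{lq}(0)^2} that project
#' three-dimensional spherical-harmonic interface modes onto the Fourier modes
#' of the equatorial contour. Entries with odd \eqn{l + q} are exactly zero
#' (the associated Legendre function vanishes at the equator by parity).
#'
#' @param q_max highest contour mode (integer \eqn{\ge 2}).
#' @param l_max highest spherical-harmonic degree summed over
#'   (default 75, which is sufficient for the spectrum sum to converge for
#'   \eqn{q \le 15}).
#' @return data frame with columns `l`, `q`, `weight` covering
#'   `q = 2..q_max`, `l = q..l_max`.
#' @examples
#' pt <- projection_table(4, 20)
#' subset(pt, (l + q) %% 2 == 1)$weight  # all exactly zero
#' @export
projection_table <- function(q_max, l_max = 75) {
  if (length(q_max) != 1 || q_max != round(q_max) ||
      length(l_max) != 1 || l_max != round(l_max))
    stop("q_max and l_max must be single integers")
  if (q_max < 2) stop("q_max must be >= 2")
  if (l_max < q_max) stop("l_max must be >= q_max")
  P0 <- alegendre_norm(l_max, 0, m_max = q_max)
  l <- attr(P0, "l"); m <- attr(P0, "m")
  keep <- m >= 2
  data.frame(l = l[keep], q = m[keep], weight = as.numeric(P0[keep, 1])^2)
}

# Projection weights as a dense (q_max-1) x (l_max+1) matrix W[q-1, l+1];
# zero where l < q. Internal fast path used by the spectrum sum.
projection_matrix <- function(q_max, l_max = 75) {
  pt <- projection_table(q_max, l_max)
  W <- matrix(0, q_max - 1, l_max + 1)
  W[cbind(pt$q - 1, pt$l + 1)] <- pt$weight
  W
}
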