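# Run code under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream" (no restoration).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Bilinear interpolation of matrix M at fractional (row, col) positions.
# Positions outside [1, nrow] x [1, ncol] return NA.
interp_bilinear <- function(M, r, c) {
  nr <- nrow(M); nc <- ncol(M)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  r0 <- pmin(floor(r[ok]), nr - 1); c0 <- pmin(floor(c[ok]), nc - 1)
  fr <- r[ok] - r0; fc <- c[ok] - c0
  out[ok] <- (1 - fr) * (1 - fc) * M[cbind(r0, c0)] +
             fr       * (1 - fc) * M[cbind(r0 + 1, c0)] +
             (1 - fr) * fc       * M[cbind(r0, c0 + 1)] +
             fr       * fc       * M[cbind(r0 + 1, c0 + 1)]
  out
}
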