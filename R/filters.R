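#' Sequential population filters for per-granule fits
#'
#' Applies the three quality filters used to select analyzable granules, in
#' order: (1) a closed outline in at least `min_pass_rate` of the frames;
#' (2) the fit must actually be sensitive to bending rigidity, i.e. the
#' increase in fit error when rigidity is dropped,
#' `delta_error_bending`, is at least `min_delta_error` (granules whose
#' tension/bending crossover lies beyond the fitted modes carry no rigidity
#' information); (3) the full-model fit error must not exceed
#' `max_error` (large irregular granules fit poorly and are excluded).
#'
#' @param results data frame with one row per granule and columns
#'   `pass_rate`, `delta_error_bending`, `error_full` (as written by
#'   [run_pipeline()] or assembled from [helfrich_fit()] objects).
#' @param min_pass_rate stage-1 threshold (default 0.60).
#' @param min_delta_error stage-2 threshold (default 0.03).
#' @param max_error stage-3 threshold (default 0.5).
#' @return list of class `filter_result`: `kept` (surviving rows of
#'   `results`), `counts` (named vector: `input`, `after_outline`,
#'   `after_delta_error`, `after_error`), `removed` (per-stage removals), and
#'   `stage_reached` (per-granule: 0 = removed at outline filter, 1 = at
#'   delta-error, 2 = at error, 3 = kept).
#' @examples
#' res <- data.frame(pass_rate = c(0.5, 0.9), delta_error_bending = c(NA, 0.1),
#'                   error_full = c(NA, 0.2))
#' apply_filters(res)$counts
#' @export
apply_filters <- function(results, min_pass_rate = 0.60,
                          min_delta_error = 0.03, max_error = 0.5) {
  stopifnot(is.data.frame(results),
            all(c("pass_rate", "delta_error_bending", "error_full") %in%
                  names(results)),
            min_pass_rate > 0, min_delta_error > 0, max_error > 0)
  n <- nrow(results)
  s1 <- !is.na(results$pass_rate) & results$pass_rate >= min_pass_rate
  s2 <- s1 & !is.na(results$delta_error_bending) &
        results$delta_error_bending >= min_delta_error
  s3 <- s2 & !is.na(results$error_full) & results$error_full <= max_error
  stage <- ifelse(s3, 3L, ifelse(s2, 2L, ifelse(s1, 1L, 0L)))
  counts <- c(input = n, after_outline = sum(s1),
              after_delta_error = sum(s2), after_error = sum(s3))
  structure(list(kept = results[s3, , drop = FALSE],
                 counts = counts,
                 removed = c(outline = n - sum(s1),
                             delta_error = sum(s1) - sum(s2),
                             error = sum(s2) - sum(s3)),
                 stage_reached = stage,
                 thresholds = c(min_pass_rate = min_pass_rate,
                                min_delta_error = min_delta_error,
                                max_error = max_error)),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Granule filtering:\n")
  cat(sprintf("  input                      : %d\n", x$counts[["input"]]))
  cat(sprintf("  outline pass rate >= %.2f  : %d  (-%d)\n",
              x$thresholds[["min_pass_rate"]], x$counts[["after_outline"]],
              x$removed[["outline"]]))
  cat(sprintf("  delta error >= %.2f        : %d  (-%d)\n",
              x$thresholds[["min_delta_error"]], x$counts[["after_delta_error"]],
              x$removed[["delta_error"]]))
  cat(sprintf("  fit error <= %.2f          : %d  (-%d)\n",
              x$thresholds[["max_error"]], x$counts[["after_error"]],
              x$removed[["error"]]))
  invisible(x)
}

#' Log-normal population summary of fitted granule parameters
#'
#' Interfacial tension and bending rigidity are approximately log-normal
#' across granule populations, so the natural summary is the geometric mean
#' with a +/- 1 SD band in log space (the band containing ~67% of granules).
#'
#' @param sigma vector of interfacial tensions (any consistent unit, > 0).
#' @param kappa vector of bending rigidities (\eqn{k_B T} units, > 0).
#' @return data frame with one row per quantity (`sigma`, `kappa`):
#'   `n`, `geometric_mean`, `band_lo`, `band_hi`.
#' @examples
#' population_stats(rlnorm(100, 0, 1), rlnorm(100, 0.7, 0.8))
#' @export
population_stats <- function(sigma, kappa) {
  one <- function(v, name) {
    v <- v[is.finite(v)]
    if (length(v) < 1) stop("no finite values for ", name)
    if (any(v <= 0)) stop("non-positive fitted values for ", name)
    lg <- log(v)
    s <- if (length(v) > 1) stats::sd(lg) else 0
    data.frame(quantity = name, n = length(v),
               geometric_mean = exp(mean(lg)),
               band_lo = exp(mean(lg) - s), band_hi = exp(mean(lg) + s))
  }
  rbind(one(sigma, "sigma"), one(kappa, "kappa"))
}
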