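# Shift a matrix by (dr, dc), padding with NA.
shift_mat <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- M[rs[ok_r], cs[ok_c]]
  out
}

#' Fourth-order intensity gradient field
#'
#' Central-difference gradient of the image intensity using the five-point
#' fourth-order stencil
#' \deqn{\partial I \approx \tfrac{1}{12}(I_{-2} - 8 I_{-1} + 8 I_{+1} - I_{+2}),}
#' applied along rows and columns. The stencil is exact for polynomials up to
#' degree 4. A border of width 2 cannot be evaluated and is returned as `NA`.
#'
#' @param frame an [image_frame()] or intensity matrix, at least 5 x 5.
#' @param smooth_sigma optional Gaussian pre-smoothing of the intensity (in
#'   pixels) before differentiation, suppressing pixel noise at the expense of
#'   slightly widening the edge response; 0 disables (default).
#' @return list with matrices `gr` (d/d row) and `gc` (d/d col).
#' @export
gradient_field <- function(frame, smooth_sigma = 0) {
  I <- frame_pixels(frame)
  if (nrow(I) < 5 || ncol(I) < 5) stop("frame smaller than the 5-point stencil")
  if (smooth_sigma > 0) I <- EBImage::gblur(I, sigma = smooth_sigma)
  gr <- (shift_mat(I, -2, 0) - 8 * shift_mat(I, -1, 0) +
         8 * shift_mat(I, 1, 0) - shift_mat(I, 2, 0)) / 12
  gc <- (shift_mat(I, 0, -2) - 8 * shift_mat(I, 0, -1) +
         8 * shift_mat(I, 0, 1) - shift_mat(I, 0, 2)) / 12
  list(gr = gr, gc = gc)
}

#' Detection settings for the difference-of-Gaussians granule detector
#'
#' @param radius_range blob radii covered, pixels (default 3 to 30).
#' @param scale_ratio geometric ladder ratio between successive scales
#'   (default 1.6).
#' @param threshold_frac detection threshold as a fraction of the frame
#'   intensity range applied to the band-pass response (default 0.08).
#' @return object of class `detect_config`.
#' @export
detect_config <- function(radius_range = c(3, 30), scale_ratio = 1.6,
                          threshold_frac = 0.08) {
  stopifnot(radius_range[1] > 0, radius_range[2] > radius_range[1],
            scale_ratio > 1, threshold_frac > 0)
  structure(list(radius_range = radius_range, scale_ratio = scale_ratio,
                 threshold_frac = threshold_frac), class = "detect_config")
}

#' Detect granules with a multi-scale difference-of-Gaussians filter
#'
#' Band-pass filters the frame at a geometric ladder of scales, finds local
#' maxima of the response above a contrast threshold, refines centers to
#' sub-pixel precision by quadratic interpolation of the response, and
#' suppresses duplicate detections across scales. Difference-of-Gaussians
#' responds to locally correlated bright features, so it works on the
#' non-zero, cell-to-cell-varying cytoplasmic background where global
#' thresholding fails.
#'
#' @param frame an [image_frame()] or matrix, at least 32 x 32.
#' @param config a [detect_config()].
#' @return data frame of seeds: `row`, `col` (sub-pixel center), `scale`
#'   (characteristic radius estimate, pixels), `response` (detector score).
#'   Zero rows on a blank frame.
#' @export
detect_granules <- function(frame, config = detect_config()) {
  I <- frame_pixels(frame)
  if (nrow(I) < 32 || ncol(I) < 32) stop("frame must be at least 32 x 32")
  stopifnot(all(is.finite(I)))
  rng <- diff(range(I))
  if (rng == 0) return(data.frame(row = numeric(0), col = numeric(0),
                                  scale = numeric(0), response = numeric(0)))
  cfg <- config
  sig <- cfg$radius_range[1] / sqrt(2)
  sigmas <- c()
  while (sig <= cfg$radius_range[2] / sqrt(2) * cfg$scale_ratio) {
    sigmas <- c(sigmas, sig)
    sig <- sig * cfg$scale_ratio
  }
  if (length(sigmas) < 2) stop("frame too small for the configured scale range")
  # clamp the kernel to fit inside the frame (truncated tails on small frames)
  kmax <- min(dim(I)) - 1 + min(dim(I)) %% 2
  blurs <- lapply(sigmas, function(s)
    EBImage::gblur(I, sigma = s, boundary = "replicate",
                   radius = min(2 * ceiling(3 * s) + 1, kmax)))
  thr <- cfg$threshold_frac * rng
  seeds <- list()
  for (k in seq_len(length(sigmas) - 1)) {
    R <- blurs[[k]] - blurs[[k + 1]]
    ismax <- R > thr
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- shift_mat(R, dr, dc)
      ismax <- ismax & (is.na(nb) | R >= nb)
    }
    idx <- which(ismax, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    # sub-pixel quadratic refinement along each axis
    refine <- function(i, j) {
      if (i < 2 || i > nrow(R) - 1 || j < 2 || j > ncol(R) - 1) return(c(i, j))
      dr2 <- R[i - 1, j] - 2 * R[i, j] + R[i + 1, j]
      dc2 <- R[i, j - 1] - 2 * R[i, j] + R[i, j + 1]
      di <- if (dr2 < 0) 0.5 * (R[i - 1, j] - R[i + 1, j]) / dr2 else 0
      dj <- if (dc2 < 0) 0.5 * (R[i, j - 1] - R[i, j + 1]) / dc2 else 0
      c(i + max(-0.5, min(0.5, di)), j + max(-0.5, min(0.5, dj)))
    }
    ref <- t(apply(idx, 1, function(ij) refine(ij[1], ij[2])))
    seeds[[length(seeds) + 1]] <- data.frame(
      row = ref[, 1], col = ref[, 2],
      scale = sigmas[k] * sqrt(2),
      response = R[idx])
  }
  if (length(seeds) == 0)
    return(data.frame(row = numeric(0), col = numeric(0),
                      scale = numeric(0), response = numeric(0)))
  s <- do.call(rbind, seeds)
  s <- s[order(-s$response), ]
  # non-maximum suppression across scales: keep the strongest within a radius
  keep <- rep(TRUE, nrow(s))
  for (i in seq_len(nrow(s))) {
    if (!keep[i]) next
    if (i < nrow(s)) {
      j <- (i + 1):nrow(s)
      d2 <- (s$row[j] - s$row[i])^2 + (s$col[j] - s$col[i])^2
      keep[j][d2 < pmax(s$scale[j], s$scale[i])^2] <- FALSE
    }
  }
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate granule extent by thresholded flood fill
#'
#' Flood fills from the seed over pixels above `threshold_frac` times the
#' maximum image intensity (or, optionally, the local maximum around the
#' seed, useful when brightness varies strongly from cell to cell). Masks
#' smaller than `min_area` pixels are flagged rejected: such granules are too
#' small for reliable contour analysis.
#'
#' @param frame an [image_frame()] or matrix.
#' @param seed one row of [detect_granules()] output, or a `(row, col)` pair.
#' @param threshold_frac threshold as a fraction of the reference maximum
#'   (default 0.5).
#' @param min_area minimum mask area in pixels (default 100).
#' @param local if `TRUE`, the reference maximum is taken within a
#'   `4 * scale` box around the seed instead of the whole image.
#' @return list: `mask` (logical matrix), `area`, `accepted`, `centroid`
#'   (`(row, col)` of the mask, `NA` when the mask is empty).
#' @export
estimate_extent <- function(frame, seed, threshold_frac = 0.5,
                            min_area = 100, local = FALSE) {
  I <- frame_pixels(frame)
  if (is.data.frame(seed)) seed <- c(seed$row[1], seed$col[1], seed$scale[1])
  r0 <- round(seed[1]); c0 <- round(seed[2])
  stopifnot(r0 >= 1, r0 <= nrow(I), c0 >= 1, c0 <= ncol(I))
  ref <- if (local && length(seed) >= 3) {
    w <- ceiling(4 * seed[3])
    max(I[max(1, r0 - w):min(nrow(I), r0 + w),
          max(1, c0 - w):min(ncol(I), c0 + w)])
  } else max(I)
  thr <- threshold_frac * ref
  empty <- list(mask = matrix(FALSE, nrow(I), ncol(I)), area = 0L,
                accepted = FALSE, centroid = c(NA_real_, NA_real_))
  if (I[r0, c0] < thr) return(empty)
  lab <- EBImage::bwlabel(I >= thr)
  mask <- lab == lab[r0, c0]
  area <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  list(mask = mask, area = area, accepted = area >= min_area,
       centroid = c(mean(idx[, 1]), mean(idx[, 2])))
}

#' Extract a sub-pixel radial boundary contour
#'
#' Casts 400 evenly spaced rays from the granule center and places the edge
#' at the maximum of the outward intensity-descent \eqn{-g = -\nabla I \cdot
#' \hat r}, sampled every 0.25 px by bilinear interpolation of the
#' fourth-order gradient field and refined to sub-pixel precision by a
#' parabolic fit over the three samples around the discrete maximum.
#'
#' @param frame an [image_frame()] or matrix.
#' @param center `(row, col)` sub-pixel granule center.
#' @param scale characteristic radius estimate in pixels; the radial search
#'   window is `window * scale`.
#' @param n_rays number of rays (default 400).
#' @param step_px radial sampling step (default 0.25 px).
#' @param window search window as multiples of `scale` (default
#'   `c(0.3, 2)`).
#' @param smooth_sigma Gaussian pre-smoothing before the gradient (default
#'   1 px; set 0 for noise-free images).
#' @param noise_floor minimum peak descent required for a ray to count as
#'   found (default 0: any descending edge).
#' @param gradient optional precomputed [gradient_field()] (shared across
#'   granules of one frame).
#' @return a [contour()] in pixels; rays without an acceptable maximum are
#'   flagged invalid.
#' @export
extract_contour <- function(frame, center, scale, n_rays = 400,
                            step_px = 0.25, window = c(0.3, 2),
                            smooth_sigma = 1, noise_floor = 0,
                            gradient = NULL) {
  I <- frame_pixels(frame)
  stopifnot(center[1] >= 6, center[1] <= nrow(I) - 5,
            center[2] >= 6, center[2] <= ncol(I) - 5, scale > 0)
  if (is.null(gradient)) gradient <- gradient_field(I, smooth_sigma = smooth_sigma)
  phi <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  rgrid <- seq(window[1] * scale, window[2] * scale, by = step_px)
  nr <- length(rgrid)
  rr <- outer(sin(phi), rgrid) + center[1]     # n_rays x nr sample rows
  cc <- outer(cos(phi), rgrid) + center[2]
  gr <- matrix(interp_bilinear(gradient$gr, as.numeric(rr), as.numeric(cc)),
               n_rays, nr)
  gc <- matrix(interp_bilinear(gradient$gc, as.numeric(rr), as.numeric(cc)),
               n_rays, nr)
  g <- -(gr * sin(phi) + gc * cos(phi))        # outward intensity descent
  g[!is.finite(g)] <- -Inf
  k <- max.col(g, ties.method = "first")
  peak <- g[cbind(seq_len(n_rays), k)]
  # sub-pixel refinement: parabola fitted over a +/- 1 px window around the
  # discrete maximum (the 0.25 px samples are bilinearly interpolated, i.e.
  # piecewise linear, so a window narrower than the pixel grid carries no
  # curvature information)
  h <- max(1L, as.integer(round(1 / step_px)))
  valid <- is.finite(peak) & peak > noise_floor & k > h & k <= nr - h
  radii <- rep(NA_real_, n_rays)
  if (any(valid)) {
    i <- which(valid)
    t <- -h:h
    Y <- matrix(g[cbind(rep(i, each = length(t)),
                        rep(k[i], each = length(t)) + t)],
                nrow = length(t))
    St2 <- sum(t^2); St4 <- sum(t^4); n_t <- length(t)
    b <- colSums(Y * t) / St2
    cc2 <- (colSums(Y * t^2) - St2 / n_t * colSums(Y)) / (St4 - St2^2 / n_t)
    vertex <- -b / (2 * cc2)
    ok <- is.finite(vertex) & cc2 < 0 & abs(vertex) <= h
    delta <- ifelse(ok, vertex, 0)
    radii[i] <- rgrid[k[i]] + delta * step_px
    valid[i] <- valid[i] & ok & is.finite(colSums(Y))
  }
  radii[!valid] <- rgrid[k][!valid]            # placeholder, flagged invalid
  contour(radii, center = center, ray_valid = valid, unit = "px")
}

#' Validate a contour against discontinuous jumps
#'
#' A boundary is rejected when any two adjacent points differ by more than
#' `jump_threshold` times the mean radius (granule merging and overhangs make
#' the boundary non-radial), or when any ray failed edge detection.
#' Rejections are evaluated frame by frame; the per-granule fraction of
#' accepted frames is the outline pass rate used in filtering.
#'
#' @param contour a [contour()].
#' @param jump_threshold maximum adjacent-point jump relative to the mean
#'   radius (default 0.2).
#' @return logical flag; attribute `bad_rays` lists offending angle indices.
#' @export
validate_contour <- function(contour, jump_threshold = 0.2) {
  stopifnot(inherits(contour, "contour"), jump_threshold > 0)
  d <- contour$radii
  jumps <- abs(diff(c(d, d[1])))
  bad <- which(jumps > jump_threshold * contour$mean_radius)
  ok <- all(contour$ray_valid) && length(bad) == 0
  structure(ok, bad_rays = as.integer(bad))
}

#' Link per-frame detections into granule tracks
#'
#' Greedy nearest-center linking: candidate links between active tracks and
#' the new frame's detections are accepted in order of increasing distance,
#' up to a maximum displacement of the track's current scale estimate.
#' Unlinked detections start new tracks; a track ends after `max_miss`
#' consecutive missed frames. Linking in global distance order makes the
#' result independent of the order of detections within a frame.
#'
#' @param detections list (one element per frame) of [detect_granules()]
#'   data frames.
#' @param max_miss consecutive missed frames tolerated (default 5).
#' @return list of tracks, each a data frame `frame`, `row`, `col`, `scale`,
#'   `response`, ordered by first appearance.
#' @export
track_granules <- function(detections, max_miss = 5) {
  stopifnot(length(detections) >= 2)
  tracks <- list()       # each: list(rows = data.frame, last_frame, scale)
  active <- integer(0)
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    assigned <- rep(FALSE, nrow(det))
    if (length(active) > 0 && nrow(det) > 0) {
      cand <- expand.grid(tr = seq_along(active), de = seq_len(nrow(det)))
      last <- do.call(rbind, lapply(active, function(i) {
        r <- tracks[[i]]$rows
        c(r$row[nrow(r)], r$col[nrow(r)], tracks[[i]]$scale)
      }))
      cand$d <- sqrt((last[cand$tr, 1] - det$row[cand$de])^2 +
                     (last[cand$tr, 2] - det$col[cand$de])^2)
      cand <- cand[cand$d <= last[cand$tr, 3], ]
      cand <- cand[order(cand$d), ]
      used_tr <- rep(FALSE, length(active))
      for (ci in seq_len(nrow(cand))) {
        tr <- cand$tr[ci]; de <- cand$de[ci]
        if (used_tr[tr] || assigned[de]) next
        used_tr[tr] <- TRUE; assigned[de] <- TRUE
        ti <- active[tr]
        tracks[[ti]]$rows <- rbind(tracks[[ti]]$rows,
                                   cbind(frame = f, det[de, , drop = FALSE]))
        tracks[[ti]]$last_frame <- f
        tracks[[ti]]$scale <- det$scale[de]
      }
    }
    for (de in which(!assigned)) {
      tracks[[length(tracks) + 1]] <- list(
        rows = cbind(frame = f, det[de, , drop = FALSE]),
        last_frame = f, scale = det$scale[de])
    }
    active <- which(vapply(tracks, function(t) f - t$last_frame < max_miss,
                           logical(1)))
  }
  out <- lapply(tracks, function(t) { rownames(t$rows) <- NULL; t$rows })
  out[order(vapply(out, function(r) min(r$frame), numeric(1)))]
}
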