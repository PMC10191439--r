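#' Microscope optics / noise model for synthetic rendering
#'
#' Describes how a rendered boundary becomes a camera frame: Gaussian
#' point-spread blur, a uniform cytoplasmic background, and additive Gaussian
#' camera noise scaled to a target signal-to-noise ratio (defined as
#' (foreground - background) / noise SD).
#'
#' @param psf_sigma point-spread sigma in pixels (default 1.3, roughly the
#'   diffraction limit of a high-NA 100x system at the default pixel size).
#' @param snr target signal-to-noise ratio (default 5, matching typical
#'   spinning-disk condensate imaging); `Inf` disables noise.
#' @param pixel_size micrometres per pixel (default 0.065).
#' @param background_level background intensity as a fraction of the
#'   foreground (default 0.2; the cytoplasm retains diffuse fluorophore).
#' @param bit_depth camera bit depth used when writing integer TIFFs
#'   (default 16).
#' @return object of class `optics_model`.
#' @export
optics_model <- function(psf_sigma = 1.3, snr = 5, pixel_size = 0.065,
                         background_level = 0.2, bit_depth = 16) {
  stopifnot(psf_sigma >= 0, snr > 0, pixel_size > 0,
            background_level >= 0, background_level < 1)
  structure(list(psf_sigma = psf_sigma, snr = snr, pixel_size = pixel_size,
                 background_level = background_level,
                 bit_depth = as.integer(bit_depth)),
            class = "optics_model")
}

#' A single image frame
#'
#' @param pixels numeric intensity matrix (row, col), finite and non-negative.
#' @param pixel_size micrometres per pixel.
#' @param frame_index integer frame number.
#' @param timestamp acquisition time in seconds.
#' @return object of class `image_frame`.
#' @export
image_frame <- function(pixels, pixel_size = 0.065, frame_index = 1L,
                        timestamp = 0) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_index = as.integer(frame_index), timestamp = timestamp),
            class = "image_frame")
}

frame_pixels <- function(x) if (inherits(x, "image_frame")) x$pixels else x

#' Render a contour as a microscope-like frame
#'
#' Rasterizes the filled region bounded by the radial contour with a 1-pixel
#' anti-aliasing ramp, convolves with the Gaussian PSF, and adds the
#' background plus Gaussian noise at the configured SNR. Foreground intensity
#' is 1 in arbitrary units.
#'
#' @param contour a [contour()]; radii in pixels, or micrometres (converted
#'   using the optics pixel size).
#' @param optics an [optics_model()].
#' @param seed optional integer seed for the noise draw.
#' @param frame_dim `(rows, cols)` of the output; default sized to fit the
#'   contour with a margin.
#' @param center `(row, col)` placement of the granule center; default the
#'   frame center.
#' @param frame_index,timestamp metadata passed to [image_frame()].
#' @return an [image_frame()].
#' @export
render_frame <- function(contour, optics = optics_model(), seed = NULL,
                         frame_dim = NULL, center = NULL,
                         frame_index = 1L, timestamp = 0) {
  stopifnot(inherits(contour, "contour"), inherits(optics, "optics_model"))
  radii <- contour$radii
  if (identical(contour$unit, "um")) radii <- radii / optics$pixel_size
  if (is.null(frame_dim)) {
    d <- 2 * ceiling(max(radii) + 4 * optics$psf_sigma + 6)
    frame_dim <- c(d, d)
  }
  if (max(radii) > min(frame_dim) / 2 - 2)
    stop("contour too large for the frame")
  if (is.null(center)) center <- (frame_dim + 1) / 2
  nr <- frame_dim[1]; nc <- frame_dim[2]
  rr <- matrix(seq_len(nr), nr, nc) - center[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  rpix <- sqrt(rr^2 + cc^2)
  phi <- atan2(rr, cc) %% (2 * pi)
  # periodic linear interpolation of D(phi) at each pixel's angle
  n <- length(radii)
  pos <- phi / (2 * pi) * n
  i0 <- floor(pos); f <- pos - i0
  D <- radii[(i0 %% n) + 1] * (1 - f) + radii[((i0 + 1) %% n) + 1] * f
  cover <- 0.5 + (D - rpix)                        # 1 px anti-alias ramp
  cover[cover < 0] <- 0; cover[cover > 1] <- 1
  bg <- optics$background_level
  img <- bg + (1 - bg) * cover
  if (optics$psf_sigma > 0)
    img <- EBImage::gblur(img, sigma = optics$psf_sigma, boundary = bg)
  if (is.finite(optics$snr)) {
    sd_noise <- (1 - bg) / optics$snr
    img <- img + with_seed(seed, matrix(stats::rnorm(nr * nc, 0, sd_noise), nr, nc))
  }
  image_frame(pmax(img, 0), pixel_size = optics$pixel_size,
              frame_index = frame_index, timestamp = timestamp)
}

#' Simulate a time-lapse video of one fluctuating droplet
#'
#' Draws an independent equipartition shape per frame (the fitting target is
#' the time-averaged spectrum, so frame-to-frame dynamics are not modelled),
#' sections it at the equator, and renders each contour through the optics
#' model. With `fixed_shape = TRUE` a single quenched shape is rendered with
#' fresh noise every frame, mimicking a fixed (dead) cell in which only
#' microscope noise remains.
#'
#' @param params ground-truth [model_params()].
#' @param optics an [optics_model()].
#' @param n_frames number of frames (default 1000, a standard 40 s burst at
#'   10 ms exposure).
#' @param seed integer seed making the whole video reproducible.
#' @param fixed_shape render one quenched shape throughout (default FALSE).
#' @param l_sim,m_max,n_points contour generation controls.
#' @return list of class `droplet_video`: `frames` (list of [image_frame()]),
#'   `contours` (ground-truth `contour_series` in pixels), `truth` (params,
#'   optics, seed).
#' @export
simulate_droplet_video <- function(params, optics = optics_model(),
                                   n_frames = 1000, seed = NULL,
                                   fixed_shape = FALSE,
                                   l_sim = params$l_max, m_max = l_sim,
                                   n_points = 400) {
  stopifnot(inherits(params, "model_params"), n_frames >= 1)
  with_seed(seed, {
    shapes <- sample_equilibrium_modes(params, l_sim = l_sim,
                                       n = if (fixed_shape) 1 else n_frames,
                                       m_max = m_max)
    cs <- equatorial_contour(shapes, n_points = n_points)
    radii_um <- if (inherits(cs, "contour")) matrix(cs$radii, 1) else cs$radii
    radii_px <- radii_um / optics$pixel_size
    if (fixed_shape)
      radii_px <- radii_px[rep(1, n_frames), , drop = FALSE]
    d <- 2 * ceiling(params$radius / optics$pixel_size * 1.35 +
                       4 * optics$psf_sigma + 6)
    frames <- lapply(seq_len(n_frames), function(k)
      render_frame(contour(radii_px[k, ], unit = "px"), optics,
                   frame_dim = c(d, d), frame_index = k,
                   timestamp = (k - 1) * 0.04))
    structure(list(frames = frames,
                   contours = contour_series(radii_px, unit = "px"),
                   truth = list(params = params, optics = optics, seed = seed,
                                fixed_shape = fixed_shape)),
              class = "droplet_video")
  })
}

#' Write frames to a multi-page TIFF
#'
#' Intensities are clipped to `[0, 1]` and written as 16-bit grayscale pages.
#'
#' @param frames a `droplet_video`, or a list of [image_frame()] / matrices.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  if (inherits(frames, "droplet_video")) frames <- frames$frames
  mats <- lapply(frames, function(f) {
    m <- frame_pixels(f)
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(mats, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Pixel size and frame interval are supplied by the caller (from a sidecar
#' config), not parsed from vendor headers.
#'
#' @param path TIFF file.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames (default 0.04).
#' @return list of [image_frame()].
#' @export
read_stack <- function(path, pixel_size = 0.065, frame_interval = 0.04) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(k) {
    m <- pages[[k]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    image_frame(m, pixel_size = pixel_size, frame_index = k,
                timestamp = (k - 1) * frame_interval)
  })
}
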