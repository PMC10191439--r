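#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one object; defaults
#' follow the standard protocol (400 rays, modes 2..15, harmonic sum to
#' l = 75, 100 px minimum area, 60% outline pass rate, 0.03 minimum
#' delta-error, 0.5 maximum fit error).
#'
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames.
#' @param temperature sample temperature, K.
#' @param detection a [detect_config()].
#' @param n_rays,step_px,window,smooth_sigma,noise_floor contour extraction
#'   settings, see [extract_contour()].
#' @param jump_threshold contour rejection threshold, see
#'   [validate_contour()].
#' @param min_area flood-fill minimum area, px.
#' @param local_threshold use the local instead of global intensity maximum
#'   for the flood fill (default FALSE).
#' @param min_frames minimum valid frames per granule (default 30).
#' @param q_fit,l_max spectrum fit settings.
#' @param min_pass_rate,min_delta_error,max_error population filters, see
#'   [apply_filters()].
#' @param seed integer seed for any stochastic steps.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(pixel_size = 0.065, frame_interval = 0.04,
                            temperature = 310,
                            detection = detect_config(),
                            n_rays = 400, step_px = 0.25, window = c(0.3, 2),
                            smooth_sigma = 1, noise_floor = 0,
                            jump_threshold = 0.2,
                            min_area = 100, local_threshold = FALSE,
                            min_frames = 30,
                            q_fit = 2:15, l_max = 75,
                            min_pass_rate = 0.60, min_delta_error = 0.03,
                            max_error = 0.5, seed = NULL) {
  cfg <- as.list(environment())
  stopifnot(pixel_size > 0, frame_interval > 0, temperature > 0,
            n_rays >= 8, step_px > 0, jump_threshold > 0, min_area > 0,
            min_frames >= 5, min_pass_rate > 0, min_delta_error > 0,
            max_error > 0)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$detection <- unclass(x$detection)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  det <- x$detection
  x$detection <- NULL
  cfg <- do.call(pipeline_config, c(x, list(
    detection = do.call(detect_config, det))))
  cfg
}

#' Run the full flicker-spectroscopy pipeline
#'
#' Detect granules in every frame, link them into tracks, extract and
#' validate a sub-pixel boundary per granule per frame, decompose boundaries
#' into Fourier modes with the base-shape correction, fit the projected
#' Helfrich spectrum per granule, filter the population, and summarize.
#' Per-granule failures are logged and skipped; they never abort the run.
#'
#' @param input a `droplet_video`, a list of [image_frame()], or a path to a
#'   multi-page TIFF.
#' @param config a [pipeline_config()].
#' @param outdir optional output directory; when given, writes
#'   `contours.csv`, `mode_stats.csv`, `granules.csv`, `population.csv` and
#'   `run_report.yaml`.
#' @return list of class `pipeline_result`: `granules` (per-granule results
#'   data frame), `filter` ([apply_filters()] result), `population`
#'   ([population_stats()] data frame or `NULL`), `mode_stats` (per-granule
#'   `mode_stats` list), `contours` (per-granule contour radii), `log`
#'   (per-granule messages), `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), outdir = NULL) {
  frames <- if (inherits(input, "droplet_video")) input$frames
            else if (is.character(input)) read_stack(input, config$pixel_size,
                                                     config$frame_interval)
            else input
  stopifnot(length(frames) >= 2)
  n_frames <- length(frames)
  log <- character(0)

  detections <- lapply(frames, function(f) detect_granules(f, config$detection))
  tracks <- track_granules(detections)
  tracks <- Filter(function(t) nrow(t) >= config$min_frames, tracks)
  log <- c(log, sprintf("%d tracks of >= %d frames", length(tracks),
                        config$min_frames))

  granules <- list(); stats_list <- list(); contour_list <- list()
  for (gi in seq_along(tracks)) {
    tr <- tracks[[gi]]
    res <- tryCatch({
      amps <- matrix(NA_complex_, n_frames, max(config$q_fit))
      radii_px <- rep(NA_real_, n_frames)
      contour_mat <- matrix(NA_real_, n_frames, config$n_rays)
      for (k in seq_len(nrow(tr))) {
        f <- tr$frame[k]
        ext <- estimate_extent(frames[[f]], tr[k, c("row", "col", "scale")],
                               min_area = config$min_area,
                               local = config$local_threshold)
        if (!ext$accepted) next
        ct <- extract_contour(frames[[f]], ext$centroid, tr$scale[k],
                              n_rays = config$n_rays, step_px = config$step_px,
                              window = config$window,
                              smooth_sigma = config$smooth_sigma,
                              noise_floor = config$noise_floor)
        if (!isTRUE(as.logical(validate_contour(ct, config$jump_threshold))))
          next
        amps[f, ] <- decompose_contour(ct, q_max = max(config$q_fit))
        radii_px[f] <- ct$mean_radius
        contour_mat[f, ] <- ct$radii
      }
      n_valid <- sum(is.finite(radii_px))
      pass_rate <- n_valid / n_frames
      radius_um <- mean(radii_px, na.rm = TRUE) * config$pixel_size
      if (n_valid < config$min_frames)
        stop(sprintf("only %d valid contours", n_valid))
      ms <- aggregate_modes(amps, min_frames = config$min_frames,
                            mean_radius = radius_um)
      fit <- helfrich_fit(ms, radius_um = radius_um,
                          temperature = config$temperature,
                          q_fit = config$q_fit, l_max = config$l_max)
      list(row = data.frame(
             granule_id = gi, radius_um = radius_um,
             circularity_C2sq = ms$circularity,
             sigma_uN_per_m = fit$sigma_physical * 1e6,
             kappa_kBT = coef(fit)[["kappa"]],
             sigma_bar = coef(fit)[["sigma_bar"]],
             error_full = fit$errors[["full"]],
             delta_error_bending = fit$delta_error_bending,
             pass_rate = pass_rate, n_valid_frames = n_valid,
             converged = fit$converged),
           ms = ms, contours = contour_mat, pass_rate = pass_rate)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      # salvage the pass rate so outline failures still enter the filter ledger
      log <- c(log, sprintf("granule %d skipped: %s", gi, conditionMessage(res)))
      granules[[gi]] <- data.frame(
        granule_id = gi, radius_um = NA, circularity_C2sq = NA,
        sigma_uN_per_m = NA, kappa_kBT = NA, sigma_bar = NA,
        error_full = NA, delta_error_bending = NA,
        pass_rate = 0, n_valid_frames = 0, converged = FALSE)
    } else {
      granules[[gi]] <- res$row
      stats_list[[gi]] <- res$ms
      contour_list[[gi]] <- res$contours
      log <- c(log, sprintf("granule %d: pass rate %.2f", gi, res$pass_rate))
    }
  }
  granules <- if (length(granules)) do.call(rbind, granules) else
    data.frame(granule_id = integer(0))

  filt <- if (nrow(granules) > 0)
    apply_filters(granules, config$min_pass_rate, config$min_delta_error,
                  config$max_error)
  else NULL
  pop <- if (!is.null(filt) && nrow(filt$kept) > 0)
    population_stats(filt$kept$sigma_uN_per_m, filt$kept$kappa_kBT)
  else NULL
  if (!is.null(filt)) granules$filter_stage_reached <- filt$stage_reached

  out <- structure(list(granules = granules, filter = filt, population = pop,
                        mode_stats = stats_list, contours = contour_list,
                        log = log, config = config),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(out, outdir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Flicker-spectroscopy pipeline result: %d granules analyzed\n",
              nrow(x$granules)))
  if (!is.null(x$filter)) print(x$filter)
  if (!is.null(x$population)) {
    cat("Population summary (geometric mean [67% band]):\n")
    print(x$population, row.names = FALSE)
  }
  invisible(x)
}

# Write the standard tabular outputs and a machine-readable run report.
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$granules, file.path(outdir, "granules.csv"),
                   row.names = FALSE)
  ms <- do.call(rbind, lapply(seq_along(result$mode_stats), function(i) {
    s <- result$mode_stats[[i]]
    if (is.null(s)) return(NULL)
    cbind(granule_id = i, as.data.frame(s))
  }))
  if (!is.null(ms))
    utils::write.csv(ms, file.path(outdir, "mode_stats.csv"), row.names = FALSE)
  cts <- do.call(rbind, lapply(seq_along(result$contours), function(i) {
    m <- result$contours[[i]]
    if (is.null(m)) return(NULL)
    fr <- which(apply(is.finite(m), 1, all))
    do.call(rbind, lapply(fr, function(f)
      data.frame(granule_id = i, frame = f,
                 angle_index = seq_len(ncol(m)) - 1L, radius_px = m[f, ])))
  }))
  if (!is.null(cts))
    utils::write.csv(cts, file.path(outdir, "contours.csv"), row.names = FALSE)
  if (!is.null(result$population))
    utils::write.csv(result$population, file.path(outdir, "population.csv"),
                     row.names = FALSE)
  cfg <- unclass(result$config)
  cfg$detection <- unclass(cfg$detection)
  report <- list(
    package_version = as.character(utils::packageVersion("flickerspec")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = cfg,
    filter_counts = as.list(result$filter$counts),
    log = result$log)
  yaml::write_yaml(report, file.path(outdir, "run_report.yaml"))
  invisible(outdir)
}
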