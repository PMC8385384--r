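#' Pipeline configuration
#'
#' Collects every tunable of the portrait pipeline with the standard
#' defaults: dF/F baseline window 40 s, blur sigma 1 px, Horn-Schunck
#' `alpha = 1` with 100 iterations, activity-scaling delay 1.5 s averaged
#' over 0.25 s, five-point temporal Gaussian with shape 1.25, integration
#' length 40 frames (2 s at 20 Hz), threshold percentile 93, wave thresholds
#' 50%/10%. Configurations round-trip losslessly through YAML.
#'
#' @param input path to the input movie (TIFF), or `NULL` when the stack is
#'   passed to [run_pipeline()] directly.
#' @param dt frame interval in seconds (mandatory metadata: every
#'   seconds-to-frames conversion uses it).
#' @param baseline_window_s,blur_sigma,bin_factor,ratio_threshold
#'   preprocessing parameters ([compute_dff()], [bin_pixels()],
#'   [compute_roi_mask()]).
#' @param alpha,max_iters Horn-Schunck parameters.
#' @param delay_s,avg_window_s,smooth_kernel_len,smooth_alpha scaling and
#'   smoothing parameters ([activity_scale()], [temporal_smooth()]).
#' @param scale_by_activity apply activity scaling (disable for noise-free
#'   synthetic movies).
#' @param T_frames FTLE integration length in frames.
#' @param base_time_step spacing between FTLE base times.
#' @param threshold_percentile ridge threshold percentile.
#' @param high,low,min_len_s wave segmentation thresholds and minimum event
#'   length in seconds.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest.
#' @param is_dff whether the input movie is already dF/F.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, dt = 0.05,
                            baseline_window_s = 40, blur_sigma = 1,
                            bin_factor = 1, ratio_threshold = 400,
                            alpha = 1, max_iters = 100,
                            delay_s = 1.5, avg_window_s = 0.25,
                            smooth_kernel_len = 5, smooth_alpha = 1.25,
                            scale_by_activity = TRUE,
                            T_frames = 40, base_time_step = 1,
                            threshold_percentile = 93,
                            high = 0.5, low = 0.1, min_len_s = 0,
                            out_dir = "flowportrait_out", seed = 1L,
                            is_dff = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Scale an arbitrary float array into [0, 1] for 32-bit TIFF storage and
# record the affine transform in a JSON sidecar.
write_field_tiff <- function(arr, path) {
  arr[!is.finite(arr)] <- 0
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(arr)[3]), function(k) (arr[, , k] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(offset = lo, scale = scale, dim = dim(arr)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_field_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  arr * meta$scale + meta$offset
}

#' Run the full FLOW-portrait pipeline
#'
#' Executes preprocessing (dF/F, binning, ROI mask), Horn-Schunck optical
#' flow with activity scaling and temporal smoothing, forward and backward
#' FTLE series, morphological ridge extraction, and the event/metric
#' computations, writing every intermediate artifact plus a JSON manifest
#' (configuration, seed, software version, input hash) to `out_dir`.
#' Recordings shorter than the integration length plus the scaling delay are
#' refused, because the FTLE and flow computations require longer bouts of
#' data.
#'
#' @param config a [pipeline_config()].
#' @param stack optionally, a [frame_stack()] to use instead of reading
#'   `config$input`.
#' @return Invisibly, a list with the portrait, traces, events, scores and
#'   the manifest.
#' @export
run_pipeline <- function(config, stack = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(stack)) {
    if (is.null(config$input)) stop("no input: set config$input or pass a stack")
    stack <- read_stack_tiff(config$input, dt = config$dt, is_dff = config$is_dff)
  }
  delay_frames <- if (config$scale_by_activity)
    seconds_to_frames(config$delay_s, config$dt) else 0L
  min_frames <- config$T_frames + delay_frames
  if (n_frames(stack) <= min_frames)
    stop("recording too short (", n_frames(stack), " frames) for integration length ",
         config$T_frames, " plus scaling delay ", delay_frames,
         " frames; longer bouts of data are required")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  raw <- if (config$bin_factor > 1) bin_pixels(stack, config$bin_factor) else stack
  if (raw$is_dff) {
    dff <- raw
    roi <- matrix(TRUE, dim(raw)[1], dim(raw)[2])
  } else {
    roi <- compute_roi_mask(raw, config$ratio_threshold)
    dff <- compute_dff(raw, config$baseline_window_s, config$blur_sigma)
  }
  write_field_tiff(dff$data, out("dff.tif"))
  png::writePNG(matrix(as.numeric(roi), nrow(roi), ncol(roi)), out("roi_mask.png"))

  flow <- compute_flow_series(dff, roi = roi,
                              params = hs_params(config$alpha, config$max_iters))
  if (config$scale_by_activity) {
    flow <- suppressWarnings(
      activity_scale(flow, raw,
                     scaling_params(config$delay_s, config$avg_window_s,
                                    config$smooth_kernel_len, config$smooth_alpha)))
  }
  flow <- temporal_smooth(flow, config$smooth_kernel_len, config$smooth_alpha)
  write_field_tiff(flow$u, out("flow_u.tif"))
  write_field_tiff(flow$v, out("flow_v.tif"))

  fwd <- ftle_series(flow, config$T_frames, "forward",
                     step = config$base_time_step, roi = roi)
  bwd <- ftle_series(flow, config$T_frames, "backward",
                     step = config$base_time_step, roi = roi)
  sig <- function(s) array(unlist(lapply(s$fields, `[[`, "sigma")),
                           dim = c(dim(roi), length(s$fields)))
  write_field_tiff(sig(fwd), out("ftle_forward.tif"))
  write_field_tiff(sig(bwd), out("ftle_backward.tif"))

  background <- apply(dff$data, c(1, 2), mean)
  portrait <- compose_portrait(fwd, bwd, background, config$threshold_percentile)
  png::writePNG(matrix(as.numeric(portrait$forward), nrow(roi)), out("ridges_forward.png"))
  png::writePNG(matrix(as.numeric(portrait$backward), nrow(roi)), out("ridges_backward.png"))
  render_portrait(portrait, out("portrait.png"))

  af <- active_fraction_trace(dff, roi)
  min_len <- seconds_to_frames(max(config$min_len_s, config$dt), config$dt)
  events <- segment_pan_cortical_waves(af, config$high, config$low, min_len)
  traces <- list(
    active_fraction = af,
    ftle_intensity_fwd = ftle_intensity_trace(fwd),
    ftle_intensity_bwd = ftle_intensity_trace(bwd)
  )
  write_trace_csv(af, out("active_fraction.csv"))
  write_trace_csv(traces$ftle_intensity_fwd, out("ftle_intensity_forward.csv"))
  write_trace_csv(traces$ftle_intensity_bwd, out("ftle_intensity_backward.csv"))
  write_events_tsv(events, out("events.tsv"))

  scores <- do.call(rbind, lapply(c("forward", "backward", "combined"), function(d) {
    s <- ridge_count_score(portrait, d)
    data.frame(direction = d, n_ridges = s$n_ridges,
               ridge_area = s$ridge_area, score = s$score)
  }))
  utils::write.csv(scores, out("ridge_scores.csv"), row.names = FALSE)

  manifest <- list(
    package = "flowportrait",
    version = as.character(utils::packageVersion("flowportrait")),
    config = unclass(config)[setdiff(names(config), "out_dir")],
    seed = config$seed,
    input_md5 = if (!is.null(config$input)) unname(tools::md5sum(config$input)) else NA,
    outputs = {
      fls <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
      stats::setNames(as.list(unname(tools::md5sum(file.path(config$out_dir, fls)))), fls)
    }
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(portrait = portrait, traces = traces, events = events,
                 scores = scores, manifest = manifest, flow = flow,
                 fwd = fwd, bwd = bwd, dff = dff, roi = roi))
}

#' Render a FLOW portrait to PNG
#'
#' Grayscale background with forward (repelling) ridges in orange and
#' backward (attracting) ridges in purple. Optionally overlays an anatomical
#' boundary polyline (CSV with columns `x`, `y` in pixel coordinates,
#' rasterized in white) and draws a scale bar when the pixel size is known.
#'
#' @param portrait a `flow_portrait`.
#' @param path output PNG path.
#' @param overlay_csv optional polyline CSV path.
#' @param px_size_um optional pixel size (micrometres) for a 1-mm scale bar.
#' @param fwd_col,bwd_col ridge colours as RGB triples in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
render_portrait <- function(portrait, path, overlay_csv = NULL, px_size_um = NULL,
                            fwd_col = c(1, 0.55, 0), bwd_col = c(0.63, 0.13, 0.94)) {
  stopifnot(inherits(portrait, "flow_portrait"))
  bg <- portrait$background
  bg[!is.finite(bg)] <- 0
  rng <- range(bg)
  if (rng[2] > rng[1]) bg <- (bg - rng[1]) / (rng[2] - rng[1])
  H <- nrow(bg); W <- ncol(bg)
  img <- array(rep(0.25 + 0.5 * bg, 3), dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[portrait$forward] <- fwd_col[ch]
    plane[portrait$backward] <- bwd_col[ch]
    img[, , ch] <- plane
  }
  if (!is.null(overlay_csv)) {
    poly <- utils::read.csv(overlay_csv)
    if (!all(c("x", "y") %in% names(poly))) stop("overlay CSV needs x and y columns")
    if (max(poly$x) > W || max(poly$y) > H) stop("overlay polygon exceeds the portrait")
    seg <- rasterize_polyline(poly$x, poly$y, H, W)
    for (ch in 1:3) { plane <- img[, , ch]; plane[seg] <- 1; img[, , ch] <- plane }
  }
  if (!is.null(px_size_um)) {
    bar_px <- max(1L, min(W - 4L, round(1000 / px_size_um)))
    rows <- (H - 3L):(H - 2L)
    cols <- (W - 2L - bar_px + 1L):(W - 2L)
    img[rows, cols, ] <- 1
  }
  png::writePNG(img, path)
  invisible(path)
}

# Bresenham rasterization of a polyline into a logical mask.
rasterize_polyline <- function(x, y, H, W) {
  mask <- matrix(FALSE, H, W)
  x <- round(x); y <- round(y)
  for (i in seq_len(length(x) - 1)) {
    n <- max(abs(x[i + 1] - x[i]), abs(y[i + 1] - y[i])) + 1
    xs <- clamp(round(seq(x[i], x[i + 1], length.out = n)), 1, W)
    ys <- clamp(round(seq(y[i], y[i + 1], length.out = n)), 1, H)
    mask[cbind(ys, xs)] <- TRUE
  }
  mask
}
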