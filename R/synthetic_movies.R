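#' Specify a synthetic activity movie
#'
#' Three archetypal widefield activity patterns are available, each with known
#' ground-truth geometry so every downstream stage can be validated without
#' recorded data:
#'
#' * `"plane_wave"`: a smooth wavefront (Gaussian-profile crest) that ignites
#'   at a column near the centre of the frame, travels in +x at constant
#'   speed, and extinguishes where it stops.
#' * `"circular_wave"`: a ring-shaped front that ignites at the centre and
#'   expands radially until a maximal radius, then extinguishes.
#' * `"translating_gaussian"`: a 2-D Gaussian blob that appears, grows,
#'   translates in +x, then shrinks away, in four equal phases.
#'
#' Waves that visibly *begin* and *end* inside the frame need brief ignition
#' and extinction phases during which the front holds position while its
#' amplitude ramps; their lengths are exposed as `ignition_frames` and
#' `fade_frames` (set to 0 for a front that moves from the first frame).
#' Fronts are rendered with a smooth profile (`front_width`) rather than a
#' binary step so that optical flow has gradients to track.
#'
#' @param kind one of `"plane_wave"`, `"circular_wave"`,
#'   `"translating_gaussian"`.
#' @param height,width frame size in pixels (>= 8).
#' @param n_frames number of frames (>= 8).
#' @param dt frame interval in seconds (default 0.05, i.e. 20 Hz).
#' @param noise_sd standard deviation of additive i.i.d. Gaussian pixel noise
#'   (intensity units; 0 disables noise).
#' @param seed integer seed making the rendered movie reproducible.
#' @param ... kind-specific geometry overrides: `x0` (initiation column),
#'   `speed` (px/frame), `front_width` (px), `ignition_frames`, `fade_frames`
#'   for the waves; `cx`, `cy`, `r_max` for the circular wave; `y0`, `x1`,
#'   `r0`, `r1` for the translating Gaussian.
#' @return A `synthetic_movie_spec` object.
#' @export
synthetic_movie_spec <- function(kind = c("plane_wave", "circular_wave", "translating_gaussian"),
                                 height = 64, width = 64, n_frames = 64,
                                 dt = 0.05, noise_sd = 0, seed = 1L, ...) {
  kind <- match.arg(kind)
  if (height < 8 || width < 8) stop("frame dimensions must be at least 8 px")
  if (n_frames < 8) stop("n_frames must be at least 8")
  if (dt <= 0) stop("dt must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  extra <- list(...)
  geom <- switch(kind,
    plane_wave = list(
      x0 = round(width / 2), speed = 1, front_width = 2, x_end = width - 12,
      ignition_frames = round(n_frames / 4), fade_frames = round(n_frames / 4)
    ),
    circular_wave = list(
      cx = (width + 1) / 2, cy = (height + 1) / 2, speed = 1, front_width = 2,
      r_max = floor(min(height, width) / 2) - 8,
      ignition_frames = round(n_frames / 4), fade_frames = round(n_frames / 4)
    ),
    translating_gaussian = list(
      x0 = round(width / 3), y0 = round(height / 2),
      x1 = round(2 * width / 3), r0 = 3, r1 = 6
    )
  )
  unknown <- setdiff(names(extra), names(geom))
  if (length(unknown)) stop("unknown geometry parameters: ", paste(unknown, collapse = ", "))
  geom[names(extra)] <- extra
  if (!is.null(geom$speed) && geom$speed <= 0) stop("speed must be positive")
  if (!is.null(geom$front_width) && geom$front_width <= 0) stop("front_width must be positive")
  structure(
    c(list(kind = kind, height = height, width = width, n_frames = n_frames,
           dt = dt, noise_sd = noise_sd, seed = as.integer(seed)), geom),
    class = "synthetic_movie_spec"
  )
}

# Per-frame (front position in px, amplitude in [0, 1]) schedule for the two
# wavefront kinds. Times are 0-based frame indices.
wave_schedule <- function(spec) {
  nf <- spec$n_frames
  ig <- spec$ignition_frames
  fd <- spec$fade_frames
  travel <- nf - ig - fd
  if (travel < 1) stop("ignition_frames + fade_frames leave no propagation phase")
  t <- seq_len(nf) - 1L
  start <- if (spec$kind == "plane_wave") spec$x0 else 0
  pos <- start + spec$speed * pmax(0, pmin(t - ig, travel - 1L))
  # the front stops at its termination site and holds there while it fades
  cap <- if (spec$kind == "plane_wave") spec$x_end else spec$r_max
  pos <- pmin(pos, cap)
  amp <- rep(1, nf)
  if (ig > 0) amp[t < ig] <- (t[t < ig] + 1) / ig
  if (fd > 0) {
    tail_idx <- t >= nf - fd
    amp[tail_idx] <- 1 - (t[tail_idx] - (nf - fd) + 1) / fd
  }
  list(pos = pos, amp = pmax(0, pmin(1, amp)))
}

#' Generate a synthetic movie with ground-truth geometry
#'
#' Renders the movie described by a [synthetic_movie_spec()]. Intensities lie
#' in `[0, 1]` before noise; identical spec and seed give a bit-identical
#' movie. The returned ground truth records a binary initiation mask, a binary
#' termination mask and the per-frame front position (the wavefront column,
#' ring radius or blob centre, depending on the kind), which tests use instead
#' of any visual judgement.
#'
#' @param spec a [synthetic_movie_spec()].
#' @return A list with elements `stack` (a [frame_stack()], flagged as dF/F),
#'   `truth` (initiation/termination masks and per-frame front position) and
#'   `spec`.
#' @export
generate_movie <- function(spec) {
  stopifnot(inherits(spec, "synthetic_movie_spec"))
  H <- spec$height; W <- spec$width; nf <- spec$n_frames
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  arr <- array(0, dim = c(H, W, nf))

  if (spec$kind == "plane_wave") {
    sched <- wave_schedule(spec)
    w2 <- 2 * spec$front_width^2
    for (k in seq_len(nf)) {
      arr[, , k] <- sched$amp[k] * exp(-(xs - sched$pos[k])^2 / w2)
    }
    x_end <- sched$pos[nf]
    truth <- list(
      initiation_mask = abs(xs - spec$x0) <= 1,
      termination_mask = abs(xs - min(x_end, W)) <= 1,
      front_position = sched$pos
    )
  } else if (spec$kind == "circular_wave") {
    sched <- wave_schedule(spec)
    w2 <- 2 * spec$front_width^2
    r <- sqrt((xs - spec$cx)^2 + (ys - spec$cy)^2)
    for (k in seq_len(nf)) {
      arr[, , k] <- sched$amp[k] * exp(-(r - sched$pos[k])^2 / w2)
    }
    truth <- list(
      initiation_mask = r <= 2,
      termination_mask = abs(r - sched$pos[nf]) <= 1,
      front_position = sched$pos
    )
  } else { # translating_gaussian
    q <- nf / 4
    t <- seq_len(nf) - 1L
    phase_frac <- function(t0, t1) pmax(0, pmin(1, (t - t0) / max(t1 - t0, 1)))
    amp <- phase_frac(0, q - 1) * (1 - phase_frac(3 * q, nf - 1))
    rad <- spec$r0 + (spec$r1 - spec$r0) *
      (phase_frac(q, 2 * q - 1) - phase_frac(3 * q, nf - 1))
    cx <- spec$x0 + (spec$x1 - spec$x0) * phase_frac(2 * q, 3 * q - 1)
    for (k in seq_len(nf)) {
      d2 <- (xs - cx[k])^2 + (ys - spec$y0)^2
      arr[, , k] <- amp[k] * exp(-d2 / (2 * rad[k]^2))
    }
    truth <- list(
      initiation_mask = sqrt((xs - spec$x0)^2 + (ys - spec$y0)^2) <= 2,
      termination_mask = sqrt((xs - spec$x1)^2 + (ys - spec$y0)^2) <= 2,
      front_position = cx
    )
  }

  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(spec$seed)
    arr <- arr + array(stats::rnorm(length(arr), sd = spec$noise_sd), dim = dim(arr))
  }
  list(
    stack = frame_stack(arr, dt = spec$dt, is_dff = TRUE),
    truth = structure(truth, class = "ground_truth_geometry"),
    spec = spec
  )
}

#' Save a synthetic movie and its ground truth to disk
#'
#' Writes the movie as a multi-page float TIFF and a YAML sidecar holding the
#' generating spec, the per-frame front position, and the initiation and
#' termination masks (as pixel index lists).
#'
#' @param movie result of [generate_movie()].
#' @param basename output path without extension; writes `<basename>.tif` and
#'   `<basename>.yaml`.
#' @return `basename`, invisibly.
#' @export
save_synthetic_movie <- function(movie, basename) {
  write_stack_tiff(movie$stack, paste0(basename, ".tif"))
  side <- list(
    spec = unclass(movie$spec),
    front_position = as.numeric(movie$truth$front_position),
    initiation_idx = which(movie$truth$initiation_mask),
    termination_idx = which(movie$truth$termination_mask),
    shape = dim(movie$truth$initiation_mask)
  )
  yaml::write_yaml(side, paste0(basename, ".yaml"))
  invisible(basename)
}
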