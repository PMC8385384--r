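#' Horn-Schunck parameters
#'
#' The two knobs of the Horn-Schunck variational problem: the smoothness
#' weight `alpha` (the regularizer is `alpha^2` times the flow-gradient
#' energy) and the iteration cap. Defaults are `alpha = 1` and
#' `max_iters = 100`, values that work well for widefield activity movies.
#'
#' @param alpha smoothness weight (> 0).
#' @param max_iters maximum Jacobi iterations (>= 1).
#' @param tol convergence tolerance on the mean-square velocity update.
#' @return An `hs_params` list.
#' @export
hs_params <- function(alpha = 1, max_iters = 100, tol = 1e-6) {
  if (alpha <= 0) stop("alpha must be positive")
  if (max_iters < 1) stop("max_iters must be at least 1")
  structure(list(alpha = alpha, max_iters = max_iters, tol = tol),
            class = "hs_params")
}

# Horn-Schunck 2x2x2 gradient stencil: derivatives are averaged over the
# eight pixels of the cube spanned by the two frames, with replicated edges.
hs_gradients <- function(a, b) {
  Ex <- ((shift_mat(a, 0, -1) - a) + (shift_mat(shift_mat(a, 0, -1) - a, -1, 0)) +
         (shift_mat(b, 0, -1) - b) + (shift_mat(shift_mat(b, 0, -1) - b, -1, 0))) / 4
  Ey <- ((shift_mat(a, -1, 0) - a) + (shift_mat(shift_mat(a, -1, 0) - a, 0, -1)) +
         (shift_mat(b, -1, 0) - b) + (shift_mat(shift_mat(b, -1, 0) - b, 0, -1))) / 4
  Et <- ((b - a) + shift_mat(b - a, -1, 0) + shift_mat(b - a, 0, -1) +
         shift_mat(shift_mat(b - a, -1, 0), 0, -1)) / 4
  list(Ex = Ex, Ey = Ey, Et = Et)
}

# Weighted 8-neighbour average (weights 1/6 edge, 1/12 corner) used by the
# classical Jacobi update.
hs_local_avg <- function(m) {
  (shift_mat(m, -1, 0) + shift_mat(m, 1, 0) +
   shift_mat(m, 0, -1) + shift_mat(m, 0, 1)) / 6 +
  (shift_mat(m, -1, -1) + shift_mat(m, -1, 1) +
   shift_mat(m, 1, -1) + shift_mat(m, 1, 1)) / 12
}

#' Horn-Schunck optical flow for one frame pair
#'
#' Solves the Horn-Schunck problem (brightness constancy plus `alpha^2`
#' smoothness) with the classical Jacobi-style iteration, run for at most
#' `max_iters` iterations or until the mean-square update falls below `tol`.
#' Like all variational flow estimates it under-estimates large displacements;
#' for the smooth, slowly moving structures typical of widefield activity the
#' direction is recovered accurately and the magnitude to within a factor of
#' order one.
#'
#' @param frame_a,frame_b numeric matrices of equal shape.
#' @param params an [hs_params()].
#' @return A list with velocity matrices `u` (x, px/frame) and `v` (y).
#' @export
horn_schunck_pair <- function(frame_a, frame_b, params = hs_params()) {
  if (!identical(dim(frame_a), dim(frame_b))) stop("frame shapes differ")
  stop_if_not_finite(frame_a, "frame_a"); stop_if_not_finite(frame_b, "frame_b")
  gr <- hs_gradients(frame_a, frame_b)
  denom <- params$alpha^2 + gr$Ex^2 + gr$Ey^2
  u <- matrix(0, nrow(frame_a), ncol(frame_a))
  v <- u
  for (it in seq_len(params$max_iters)) {
    ub <- hs_local_avg(u)
    vb <- hs_local_avg(v)
    s <- (gr$Ex * ub + gr$Ey * vb + gr$Et) / denom
    un <- ub - gr$Ex * s
    vn <- vb - gr$Ey * s
    delta <- mean((un - u)^2 + (vn - v)^2)
    u <- un; v <- vn
    if (delta < params$tol) break
  }
  list(u = u, v = v)
}

#' Optical flow for a whole movie
#'
#' Applies [horn_schunck_pair()] to each consecutive frame pair of a dF/F
#' movie. Pixels outside the ROI are set to `NA` in the output. `NA` pixels
#' inside the movie (e.g. a masked stack) are treated as 0 for the flow
#' computation itself.
#'
#' @param stack a dF/F [frame_stack()].
#' @param roi optional logical `H x W` ROI mask.
#' @param params an [hs_params()].
#' @return A [vector_field_series()] with `n_frames - 1` steps.
#' @export
compute_flow_series <- function(stack, roi = NULL, params = hs_params()) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!stack$is_dff) stop("optical flow expects a dF/F stack; run compute_dff() first")
  nf <- n_frames(stack)
  if (nf < 2) stop("need at least 2 frames")
  d <- dim(stack$data)
  u <- array(0, c(d[1], d[2], nf - 1L))
  v <- u
  dat <- stack$data
  dat[!is.finite(dat)] <- 0
  for (k in seq_len(nf - 1L)) {
    fl <- horn_schunck_pair(dat[, , k], dat[, , k + 1L], params)
    u[, , k] <- fl$u
    v[, , k] <- fl$v
  }
  if (!is.null(roi)) {
    u[rep(!roi, times = nf - 1L)] <- NA_real_
    v[rep(!roi, times = nf - 1L)] <- NA_real_
  }
  vector_field_series(u, v, dt = stack$dt)
}

#' Activity-scaling parameters
#'
#' Parameters of the activity-based magnitude scaling and temporal smoothing
#' applied to the raw optical flow: the intensity-change look-back `delay_s`
#' (1.5 s suits slow developmental waves, 0.5 s faster adult activity), the
#' sliding window `avg_window_s` over which weights are averaged (0.25 s),
#' and the five-point Gaussian smoothing kernel's length and shape parameter.
#'
#' @param delay_s look-back delay in seconds (> 0).
#' @param avg_window_s weight-averaging window in seconds.
#' @param smooth_kernel_len temporal kernel length in frames (odd, >= 3).
#' @param smooth_alpha kernel shape parameter (inverse-width; default 1.25).
#' @return A `scaling_params` list.
#' @export
scaling_params <- function(delay_s = 1.5, avg_window_s = 0.25,
                           smooth_kernel_len = 5, smooth_alpha = 1.25) {
  if (delay_s <= 0) stop("delay_s must be positive")
  if (smooth_kernel_len %% 2 == 0 || smooth_kernel_len < 3)
    stop("smooth_kernel_len must be odd and >= 3")
  structure(list(delay_s = delay_s, avg_window_s = avg_window_s,
                 smooth_kernel_len = smooth_kernel_len,
                 smooth_alpha = smooth_alpha),
            class = "scaling_params")
}

#' Activity-based scaling of flow magnitudes
#'
#' Attenuates flow vectors that do not correspond to real intensity changes.
#' For each pixel, a weight trace is built as the absolute intensity change
#' between the current frame and the frame `delay_s` earlier (frames earlier
#' than the delay use the first frame as reference), normalized by that
#' pixel's maximum observed change; weights are then averaged over a centred
#' sliding window of `avg_window_s` and multiplied onto the corresponding
#' velocity vectors. Weights lie in `[0, 1]`, so scaling never increases a
#' vector's magnitude. Normalization is per pixel by default; set
#' `global_norm = TRUE` to normalize by the maximum change over all pixels.
#'
#' @param fields a [vector_field_series()].
#' @param raw the raw intensity [frame_stack()] aligned with `fields` (if only
#'   dF/F is available it is used with a warning).
#' @param params a [scaling_params()].
#' @param global_norm normalize by the global maximum change instead of each
#'   pixel's own.
#' @return The scaled [vector_field_series()].
#' @export
activity_scale <- function(fields, raw, params = scaling_params(),
                           global_norm = FALSE) {
  stopifnot(inherits(fields, "vector_field_series"), inherits(raw, "frame_stack"))
  if (raw$is_dff) warning("activity scaling uses raw intensities; dF/F supplied, using it instead")
  d <- dim(raw$data)
  ns <- n_steps(fields)
  if (d[3] != ns + 1L) stop("raw stack and flow series are not aligned in time")
  delay <- seconds_to_frames(params$delay_s, raw$dt)
  if (delay >= d[3]) stop("delay longer than the recording")
  x <- matrix(raw$data, d[1] * d[2], d[3])
  ref <- pmax(seq_len(d[3]) - delay, 1L)
  w <- abs(x - x[, ref])
  mx <- if (global_norm) max(w, na.rm = TRUE) else apply(w, 1, max)
  mx[!is.finite(mx) | mx == 0] <- Inf   # constant pixels get weight 0
  w <- w / mx
  # centred sliding average over avg_window_s
  aw <- seconds_to_frames(params$avg_window_s, raw$dt)
  if (aw > 1L) {
    half <- (aw - 1L) %/% 2L
    acc <- matrix(0, nrow(w), d[3])
    cnt <- numeric(d[3])
    for (off in (-half):(aw - 1L - half)) {
      tt <- seq_len(d[3]) + off
      ok <- tt >= 1L & tt <= d[3]
      acc[, ok] <- acc[, ok] + w[, tt[ok]]
      cnt[ok] <- cnt[ok] + 1
    }
    w <- sweep(acc, 2, cnt, "/")
  }
  u <- fields$u; v <- fields$v
  # flow step k describes motion between frames k and k+1; weight it by the
  # intensity change measured at the arrival frame k+1
  for (k in seq_len(ns)) {
    wk <- matrix(w[, k + 1L], d[1], d[2])
    u[, , k] <- u[, , k] * wk
    v[, , k] <- v[, , k] * wk
  }
  vector_field_series(u, v, dt = fields$dt)
}

#' Gaussian temporal smoothing kernel
#'
#' Taps of the length-`L` Gaussian window
#' `w(k) = exp(-0.5 * (alpha * k / ((L - 1) / 2))^2)` for
#' `k = -(L-1)/2 ... (L-1)/2`, the classical `gausswin` parameterization in
#' which `alpha` is inversely proportional to the standard deviation.
#'
#' @param kernel_len odd window length.
#' @param smooth_alpha shape parameter (default 1.25).
#' @param normalize divide by the tap sum (default `TRUE`).
#' @return Numeric vector of taps.
#' @export
gaussian_window <- function(kernel_len = 5, smooth_alpha = 1.25, normalize = TRUE) {
  if (kernel_len %% 2 == 0) stop("kernel length must be odd")
  half <- (kernel_len - 1) / 2
  k <- seq(-half, half)
  w <- exp(-0.5 * (smooth_alpha * k / half)^2)
  if (normalize) w / sum(w) else w
}

#' Temporal Gaussian smoothing of a velocity-field series
#'
#' Convolves each velocity component in time with the unit-sum Gaussian
#' window of [gaussian_window()]; at the ends of the series the kernel is
#' renormalized over the taps that fall inside the recording. A
#' constant-in-time series is left unchanged, and smoothing commutes with
#' scalar multiplication of the series.
#'
#' @param fields a [vector_field_series()].
#' @param kernel_len odd kernel length in frames (default 5, must not exceed
#'   the number of steps).
#' @param smooth_alpha kernel shape parameter (default 1.25).
#' @return The smoothed [vector_field_series()].
#' @export
temporal_smooth <- function(fields, kernel_len = 5, smooth_alpha = 1.25) {
  stopifnot(inherits(fields, "vector_field_series"))
  ns <- n_steps(fields)
  if (kernel_len %% 2 == 0) stop("kernel length must be odd")
  if (kernel_len > ns) stop("kernel longer than the series")
  w <- gaussian_window(kernel_len, smooth_alpha, normalize = FALSE)
  half <- (kernel_len - 1L) / 2
  smooth_one <- function(a) {
    d <- dim(a)
    m <- matrix(a, d[1] * d[2], d[3])
    acc <- matrix(0, nrow(m), d[3])
    norm <- numeric(d[3])
    for (j in seq_along(w)) {
      off <- j - 1L - half
      tt <- seq_len(d[3]) + off
      ok <- tt >= 1L & tt <= d[3]
      acc[, ok] <- acc[, ok] + w[j] * m[, tt[ok]]
      norm[ok] <- norm[ok] + w[j]
    }
    array(sweep(acc, 2, norm, "/"), dim = d)
  }
  vector_field_series(smooth_one(fields$u), smooth_one(fields$v), dt = fields$dt)
}
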