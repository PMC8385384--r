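#' Compute dF/F with a moving-minimum baseline
#'
#' Raw fluorescence drifts slowly, so the baseline `F` of each pixel is taken
#' as the minimum of its trace over a centred moving window (default 40 s,
#' truncated at the recording ends). The relative change is then
#' `(raw - F) / max(F, eps)` where `eps` is a small floor
#' (`1e-6 * max(raw)`) guarding against division by near-zero baselines.
#' An optional small per-frame Gaussian blur attenuates speckled camera noise.
#'
#' @param raw a raw [frame_stack()] (`is_dff = FALSE`).
#' @param baseline_window_s moving-minimum window length in seconds
#'   (default 40).
#' @param blur_sigma Gaussian blur standard deviation in pixels applied to
#'   each dF/F frame (default 1); use `NULL` to skip blurring.
#' @return A [frame_stack()] with `is_dff = TRUE`.
#' @export
compute_dff <- function(raw, baseline_window_s = 40, blur_sigma = 1) {
  stopifnot(inherits(raw, "frame_stack"))
  if (raw$is_dff) stop("stack is already dF/F")
  nf <- n_frames(raw)
  w <- seconds_to_frames(baseline_window_s, raw$dt)
  if (w > nf) stop("baseline window is longer than the recording")
  if (!is.null(blur_sigma) && (!is.numeric(blur_sigma) || blur_sigma <= 0))
    stop("blur_sigma must be positive (or NULL to disable)")

  d <- dim(raw$data)
  x <- matrix(raw$data, nrow = d[1] * d[2], ncol = nf)  # pixels x frames
  half <- (w - 1L) %/% 2L
  # centred moving minimum, truncated at the ends; window covers
  # [t - half, t + half] (+1 on the right for even window lengths)
  baseline <- matrix(Inf, nrow(x), nf)
  for (off in (-half):(w - 1L - half)) {
    tt <- seq_len(nf) + off
    ok <- tt >= 1L & tt <= nf
    baseline[, ok] <- pmin(baseline[, ok], x[, tt[ok]])
  }
  eps_floor <- 1e-6 * max(raw$data)
  dff <- (x - baseline) / pmax(baseline, eps_floor)
  dff <- array(dff, dim = d)
  if (!is.null(blur_sigma)) {
    for (k in seq_len(nf)) dff[, , k] <- EBImage::gblur(dff[, , k], sigma = blur_sigma)
  }
  frame_stack(dff, dt = raw$dt, is_dff = TRUE)
}

#' Variance-based region-of-interest mask
#'
#' Pixels outside the imaged tissue barely fluctuate, so their temporal
#' mean-to-variance ratio is large. A pixel is excluded when
#' `mean / variance > ratio_threshold` (default 400); zero-variance pixels are
#' always excluded. The result is a logical `H x W` matrix, `TRUE` for pixels
#' kept in all downstream statistics.
#'
#' @param raw a [frame_stack()] with at least two frames.
#' @param ratio_threshold exclusion threshold on mean/variance (default 400).
#' @return Logical `H x W` matrix (the ROI mask).
#' @export
compute_roi_mask <- function(raw, ratio_threshold = 400) {
  stopifnot(inherits(raw, "frame_stack"))
  d <- dim(raw$data)
  x <- matrix(raw$data, nrow = d[1] * d[2], ncol = d[3])
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (d[3] - 1L)
  ratio <- ifelse(v > 0, mu / v, Inf)
  mask <- matrix(ratio <= ratio_threshold, d[1], d[2])
  if (!any(mask)) warning("ROI mask is empty: every pixel exceeded the ratio threshold")
  mask
}

#' Apply an ROI mask to a stack
#'
#' Pixels outside the mask are set to `NA` so that they are excluded from all
#' downstream statistics and percentiles.
#'
#' @param stack a [frame_stack()].
#' @param roi logical `H x W` mask.
#' @return A masked `frame_stack`.
#' @export
apply_roi_mask <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$data)
  if (!identical(dim(roi), d[1:2])) stop("ROI mask shape does not match the stack")
  x <- stack$data
  x[rep(!roi, times = d[3])] <- NA_real_
  frame_stack(x, dt = stack$dt, is_dff = stack$is_dff)
}
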