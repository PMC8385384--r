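#' Temporal mean of an FTLE series
#'
#' Pixelwise mean of the (non-negative) exponents over all base times. `NA`
#' pixels (outside the ROI) stay `NA`.
#'
#' @param series an `ftle_series` from [ftle_series()].
#' @return Numeric `H x W` matrix.
#' @export
mean_ftle <- function(series) {
  stopifnot(inherits(series, "ftle_series"))
  if (length(series$fields) == 0) stop("empty FTLE series")
  acc <- series$fields[[1]]$sigma
  for (f in series$fields[-1]) acc <- acc + f$sigma
  acc / length(series$fields)
}

#' Percentile threshold of a mean FTLE field
#'
#' Keeps the pixels at or above the given percentile of the field's values
#' over valid (non-`NA`) pixels, so that about `100 - percentile` percent of
#' the ROI survives. Percentiles use linear interpolation between order
#' statistics; ties are kept (threshold test is `>=`).
#'
#' @param mean_field numeric matrix (e.g. from [mean_ftle()]).
#' @param threshold_percentile percentile in (0, 100); typical portraits use
#'   85-93.
#' @return Logical ridge candidate mask (`NA` pixels are `FALSE`).
#' @export
threshold_binarize <- function(mean_field, threshold_percentile = 93) {
  if (threshold_percentile <= 0 || threshold_percentile >= 100)
    stop("threshold_percentile must be in (0, 100)")
  vals <- mean_field[is.finite(mean_field)]
  if (length(vals) == 0) stop("no valid pixels to threshold")
  if (max(vals) == min(vals)) {
    warning("degenerate field (all values equal); returning an empty mask")
    return(matrix(FALSE, nrow(mean_field), ncol(mean_field)))
  }
  thr <- stats::quantile(vals, threshold_percentile / 100, type = 7, names = FALSE)
  out <- mean_field >= thr
  out[!is.finite(mean_field)] <- FALSE
  out
}

#' Morphological ridge clean-up
#'
#' Turns a thresholded mean-FTLE mask into thin connected ridge
#' approximations by the fixed operator sequence: close (bridge 1-px gaps),
#' thin (to convergence), skeletonize (4 iterations), diagonal fill (to
#' convergence), spur removal (default 1 pass; see [bw_spur()] for why it is
#' not iterated), and a final close. Every output pixel lies within the
#' 1-px dilation of the input mask.
#'
#' @param binary logical ridge-candidate mask.
#' @param skel_iters skeletonization passes (default 4).
#' @param spur_iters spur-removal passes (default 1).
#' @return Logical ridge mask (thin, 8-connected structures).
#' @export
extract_ridges <- function(binary, skel_iters = 4L, spur_iters = 1L) {
  stopifnot(is.logical(binary), is.matrix(binary))
  if (!any(binary)) return(binary)
  m <- bw_close(binary)
  m <- bw_thin(m, n_iter = Inf)
  m <- bw_skel(m, n_iter = skel_iters)
  m <- bw_diag(m, n_iter = Inf)
  m <- bw_spur(m, n_iter = spur_iters)
  bw_close(m)
}

#' Compose a FLOW portrait
#'
#' Processes the forward and backward FTLE series independently (temporal
#' mean, percentile threshold, morphological ridge clean-up) and pairs the
#' resulting masks with a background image (typically the mean dF/F frame).
#' By convention forward-time ridges are repelling structures where activity
#' originates (rendered orange) and backward-time ridges are attracting
#' structures where activity terminates (rendered purple).
#'
#' @param fwd,bwd forward and backward `ftle_series`.
#' @param background numeric `H x W` image for display underneath the masks.
#' @param threshold_percentile percentile for [threshold_binarize()].
#' @param spur_iters spur-removal passes passed to [extract_ridges()].
#' @return A `flow_portrait`: logical masks `forward` and `backward`, the
#'   `background` image and the parameters used.
#' @export
compose_portrait <- function(fwd, bwd, background, threshold_percentile = 93,
                             spur_iters = 1L) {
  stopifnot(inherits(fwd, "ftle_series"), inherits(bwd, "ftle_series"))
  mf <- mean_ftle(fwd)
  mb <- mean_ftle(bwd)
  if (!identical(dim(mf), dim(mb)) || !identical(dim(mf), dim(background)))
    stop("forward, backward and background shapes differ")
  fwd_mask <- extract_ridges(threshold_binarize(mf, threshold_percentile),
                             spur_iters = spur_iters)
  bwd_mask <- extract_ridges(threshold_binarize(mb, threshold_percentile),
                             spur_iters = spur_iters)
  structure(
    list(forward = fwd_mask, backward = bwd_mask, background = background,
         params = list(T_frames = fwd$T_frames,
                       threshold_percentile = threshold_percentile)),
    class = "flow_portrait"
  )
}

#' @export
print.flow_portrait <- function(x, ...) {
  cat(sprintf(
    "<flow_portrait> %d x %d px; forward ridges: %d px, backward ridges: %d px (T = %d, percentile = %g)\n",
    nrow(x$background), ncol(x$background), sum(x$forward), sum(x$backward),
    x$params$T_frames, x$params$threshold_percentile))
  invisible(x)
}
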