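#' Frame stacks
#'
#' A `frame_stack` holds a movie as an `H x W x n_frames` numeric array plus
#' the frame interval `dt` (seconds/frame) and a flag recording whether the
#' intensities are raw fluorescence or relative change (dF/F). It is the input
#' and output container of the preprocessing stage and the input to optical
#' flow.
#'
#' @param data numeric array `H x W x n_frames` (rows = y, columns = x).
#' @param dt frame interval in seconds (> 0).
#' @param is_dff logical; `TRUE` when `data` already holds dF/F values.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(data, dt, is_dff = FALSE) {
  if (length(dim(data)) != 3) stop("data must be an H x W x n_frames array")
  if (dim(data)[3] < 2) stop("a frame stack needs at least 2 frames")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be a positive scalar")
  structure(
    list(data = data, dt = dt, is_dff = isTRUE(is_dff)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<frame_stack> %d x %d px, %d frames, dt = %g s (%s)\n",
    d[1], d[2], d[3], x$dt, if (x$is_dff) "dF/F" else "raw"
  ))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3]

#' Spatially bin a frame stack
#'
#' Each output pixel is the mean of a `factor x factor` block of input pixels,
#' the on- or off-camera binning routinely used to trade spatial resolution for
#' signal-to-noise in widefield imaging (e.g. 960 x 720 to 480 x 360 at
#' `factor = 2`). Trailing rows/columns that do not fill a whole block are
#' cropped. The frame interval is unchanged. When `factor` divides both
#' dimensions the global mean is conserved exactly.
#'
#' @param stack a [frame_stack()].
#' @param factor integer binning factor (>= 1).
#' @return A binned `frame_stack`.
#' @export
bin_pixels <- function(stack, factor) {
  stopifnot(inherits(stack, "frame_stack"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(stack)
  d <- dim(stack$data)
  H <- (d[1] %/% factor) * factor
  W <- (d[2] %/% factor) * factor
  if (H < factor || W < factor) stop("stack smaller than one bin")
  x <- stack$data[seq_len(H), seq_len(W), , drop = FALSE]
  nf <- d[3]
  # mean over factor x factor blocks via two reshapes
  dim(x) <- c(factor, H %/% factor, W, nf)
  x <- colMeans(x)                      # (H/f) x W x nf
  x <- aperm(x, c(2, 1, 3))             # W x (H/f) x nf
  dim(x) <- c(factor, W %/% factor, H %/% factor, nf)
  x <- colMeans(x)                      # (W/f) x (H/f) x nf
  x <- aperm(x, c(2, 1, 3))
  frame_stack(x, dt = stack$dt, is_dff = stack$is_dff)
}

#' Read a movie from a multi-page TIFF file
#'
#' @param path TIFF file with one page per frame.
#' @param dt frame interval in seconds.
#' @param is_dff whether the file stores dF/F values.
#' @return A [frame_stack()].
#' @export
read_stack_tiff <- function(path, dt, is_dff = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  frame_stack(arr, dt = dt, is_dff = is_dff)
}

#' Write a movie to a multi-page float TIFF file
#'
#' @param stack a [frame_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  x <- stack$data
  x[!is.finite(x)] <- 0
  frames <- lapply(seq_len(dim(x)[3]), function(k) x[, , k])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
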