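# Internal numeric helpers shared across the pipeline.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a matrix by (dr, dc) with replicated ("replicate") or zero ("zero")
# padding; used for finite-difference stencils and 3x3 morphology.
shift_mat <- function(m, dr, dc, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  H <- nrow(m); W <- ncol(m)
  ri <- seq_len(H) - dr
  ci <- seq_len(W) - dc
  if (pad == "replicate") {
    ri <- clamp(ri, 1L, H)
    ci <- clamp(ci, 1L, W)
    m[ri, ci, drop = FALSE]
  } else {
    out <- matrix(if (is.logical(m)) FALSE else 0, H, W)
    rok <- ri >= 1L & ri <= H
    cok <- ci >= 1L & ci <= W
    out[rok, cok] <- m[ri[rok], ci[cok], drop = FALSE]
    out
  }
}

# Bilinear interpolation of a H x W field at continuous positions
# (x = column coordinate, y = row coordinate), clamped to the domain.
interp_bilinear <- function(field, x, y) {
  H <- nrow(field); W <- ncol(field)
  x <- clamp(x, 1, W)
  y <- clamp(y, 1, H)
  x0 <- clamp(floor(x), 1, W - 1L)
  y0 <- clamp(floor(y), 1, H - 1L)
  fx <- x - x0
  fy <- y - y0
  i00 <- y0 + (x0 - 1) * H
  f00 <- field[i00]
  f10 <- field[i00 + H]       # (y0, x0 + 1)
  f01 <- field[i00 + 1]       # (y0 + 1, x0)
  f11 <- field[i00 + H + 1]
  (1 - fy) * ((1 - fx) * f00 + fx * f10) + fy * ((1 - fx) * f01 + fx * f11)
}

# Seconds -> frames conversion used everywhere the configuration mixes units.
seconds_to_frames <- function(seconds, dt) {
  stopifnot(is.numeric(seconds), is.numeric(dt), dt > 0)
  max(1L, as.integer(round(seconds / dt)))
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}
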