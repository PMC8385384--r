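#' Time-varying 2-D velocity fields
#'
#' A `vector_field_series` holds per-frame-pair velocity components `u` (along
#' x, i.e. columns) and `v` (along y, i.e. rows) as `H x W x n_steps` arrays in
#' pixels/frame, on a unit-spaced pixel grid. It is the object every
#' Lagrangian computation (flow maps, FTLE) consumes. Velocity samples are
#' indexed by step `k = 1..n_steps`; when derived from a movie, step `k`
#' describes the motion between frames `k` and `k + 1`.
#'
#' @param u,v numeric arrays `H x W x n_steps` (px/frame).
#' @param dt frame interval in seconds.
#' @return A `vector_field_series`.
#' @export
vector_field_series <- function(u, v, dt = 1) {
  if (!identical(dim(u), dim(v))) stop("u and v must have identical dimensions")
  if (length(dim(u)) != 3) stop("u and v must be H x W x n_steps arrays")
  if (dt <= 0) stop("dt must be positive")
  structure(list(u = u, v = v, dt = dt), class = "vector_field_series")
}

#' @export
print.vector_field_series <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("<vector_field_series> %d x %d px, %d steps, dt = %g s\n",
              d[1], d[2], d[3], x$dt))
  invisible(x)
}

n_steps <- function(fields) dim(fields$u)[3]

#' Reverse a velocity-field series in time
#'
#' Reverses the step order and negates both components. Integrating the
#' reversed series forward is arithmetically identical to integrating the
#' original backward, which is how backward-time FTLE is defined.
#'
#' @param fields a [vector_field_series()].
#' @return The time-reversed series.
#' @export
reverse_series <- function(fields) {
  stopifnot(inherits(fields, "vector_field_series"))
  idx <- rev(seq_len(n_steps(fields)))
  vector_field_series(-fields$u[, , idx, drop = FALSE],
                      -fields$v[, , idx, drop = FALSE], dt = fields$dt)
}

#' Specify an analytic benchmark vector field
#'
#' Closed-form fields used to validate the Lagrangian machinery:
#'
#' * `"zero"`: no motion anywhere (identity flow map).
#' * `"uniform_translation"`: constant `(u0, v0)` everywhere (rigid motion,
#'   zero stretching).
#' * `"linear_saddle"`: `v(x, y) = (a (x - cx), -a (y - cy))`; its flow map is
#'   `diag(exp(aT), exp(-aT))`, so the forward FTLE equals `a` exactly.
#' * `"double_gyre"`: the standard time-periodic two-gyre benchmark on the
#'   domain `[0, 2] x [0, 1]`, mapped onto the pixel grid; its boundary-normal
#'   velocity is identically zero, so particles never leave the frame.
#'
#' Velocities are returned in px/frame. The double-gyre amplitude default
#' (`A = 0.005`) gives peak speeds of about 1 px/frame on the default
#' 65 x 129 grid (spacing 1/64 of the domain height), comparable to the
#' optical-flow magnitudes of propagating activity, and the spacing resolves
#' the FTLE ridges so that sub-pixel perturbations of particle seeds stay in
#' the flow map's locally linear regime.
#'
#' @param kind field kind (see above).
#' @param height,width grid size in pixels.
#' @param ... parameter overrides: `u0`, `v0` (uniform translation, px/frame);
#'   `a`, `cx`, `cy` (saddle rate per frame and centre); `A`, `eps`, `period`
#'   (double-gyre amplitude, gyre asymmetry and oscillation period in frames).
#' @return An `analytic_field_spec`.
#' @export
analytic_field_spec <- function(kind = c("zero", "uniform_translation",
                                         "linear_saddle", "double_gyre"),
                                height = 65, width = 65, ...) {
  kind <- match.arg(kind)
  if (kind == "double_gyre" && missing(width)) width <- 129
  if (height < 4 || width < 4) stop("grid too small")
  pars <- switch(kind,
    zero = list(),
    uniform_translation = list(u0 = 1, v0 = 0),
    linear_saddle = list(a = 0.05, cx = (width + 1) / 2, cy = (height + 1) / 2),
    double_gyre = list(A = 0.005, eps = 0.25, period = 10)
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(pars))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  pars[names(extra)] <- extra
  if (kind == "linear_saddle" && pars$a <= 0) stop("saddle rate a must be positive")
  structure(c(list(kind = kind, height = height, width = width), pars),
            class = "analytic_field_spec")
}

#' Sample an analytic field as a velocity-field series
#'
#' Evaluates the field on the pixel grid at step times `1..n_steps`. Steady
#' kinds repeat the same field every step; the double gyre is sampled at each
#' integer frame of its oscillation.
#'
#' @param spec an [analytic_field_spec()].
#' @param n_steps number of velocity samples to generate.
#' @param dt frame interval in seconds (metadata only; default 1).
#' @return A [vector_field_series()].
#' @export
generate_analytic_field <- function(spec, n_steps, dt = 1) {
  stopifnot(inherits(spec, "analytic_field_spec"))
  if (n_steps < 1) stop("n_steps must be at least 1")
  H <- spec$height; W <- spec$width
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  u <- array(0, c(H, W, n_steps))
  v <- array(0, c(H, W, n_steps))

  if (spec$kind == "uniform_translation") {
    u[] <- spec$u0
    v[] <- spec$v0
  } else if (spec$kind == "linear_saddle") {
    uk <- spec$a * (xs - spec$cx)
    vk <- -spec$a * (ys - spec$cy)
    for (k in seq_len(n_steps)) { u[, , k] <- uk; v[, , k] <- vk }
  } else if (spec$kind == "double_gyre") {
    # domain [0, 2] x [0, 1] mapped to the pixel grid; px/frame velocities
    sx <- 2 / (W - 1)
    sy <- 1 / (H - 1)
    xd <- (xs - 1) * sx
    yd <- (ys - 1) * sy
    om <- 2 * pi / spec$period
    for (k in seq_len(n_steps)) {
      s <- spec$eps * sin(om * k)
      f <- s * xd^2 + (1 - 2 * s) * xd
      dfdx <- 2 * s * xd + (1 - 2 * s)
      u[, , k] <- -pi * spec$A * sin(pi * f) * cos(pi * yd) / sx
      v[, , k] <- pi * spec$A * cos(pi * f) * sin(pi * yd) * dfdx / sy
    }
  }
  vector_field_series(u, v, dt = dt)
}
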