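# Velocity sampler: bilinear in space, linear in time between step samples.
# Step k of the series is taken as the velocity sample at time t = k; the
# admissible integration span is [1, n_steps].
velocity_at <- function(fields, px, py, t) {
  ns <- n_steps(fields)
  if (ns == 1L) {
    return(list(u = interp_bilinear(fields$u[, , 1], px, py),
                v = interp_bilinear(fields$v[, , 1], px, py)))
  }
  k <- clamp(floor(t), 1, ns - 1L)
  w <- t - k
  u0 <- interp_bilinear(fields$u[, , k], px, py)
  v0 <- interp_bilinear(fields$v[, , k], px, py)
  if (w == 0) return(list(u = u0, v = v0))
  u1 <- interp_bilinear(fields$u[, , k + 1L], px, py)
  v1 <- interp_bilinear(fields$v[, , k + 1L], px, py)
  list(u = (1 - w) * u0 + w * u1, v = (1 - w) * v0 + w * v1)
}

#' Advect particles through a velocity-field series
#'
#' Integrates particles from arbitrary starting positions at base time `t0`
#' over a signed horizon of `T` frames, using 4th-order Runge-Kutta with
#' `substeps` steps per frame (or first-order Euler with `method = "euler"`,
#' which serves as an independent brute-force oracle for the integrator).
#' Velocities are sampled bilinearly in space and linearly in time; positions
#' are clamped to the pixel domain after every step.
#'
#' @param fields a [vector_field_series()].
#' @param x,y starting coordinates (columns and rows, px).
#' @param t0 base time (step index, 1-based).
#' @param T_frames signed integration horizon in frames (positive = forward).
#' @param substeps integration steps per frame (>= 1).
#' @param method `"rk4"` (default) or `"euler"`.
#' @return List of final coordinates `x`, `y`.
#' @export
advect_particles <- function(fields, x, y, t0, T_frames, substeps = 2L,
                             method = c("rk4", "euler")) {
  stopifnot(inherits(fields, "vector_field_series"))
  method <- match.arg(method)
  ns <- n_steps(fields)
  if (abs(T_frames) < 1) stop("|T| must be at least 1 frame")
  if (substeps < 1) stop("substeps must be >= 1")
  t_end <- t0 + T_frames
  if (min(t0, t_end) < 1 || max(t0, t_end) > ns)
    stop("integration horizon [", min(t0, t_end), ", ", max(t0, t_end),
         "] exceeds the available steps [1, ", ns, "]")
  H <- dim(fields$u)[1]; W <- dim(fields$u)[2]
  u <- fields$u; v <- fields$v
  u[!is.finite(u)] <- 0; v[!is.finite(v)] <- 0
  flds <- list(u = u, v = v)
  class(flds) <- "vector_field_series"

  h <- sign(T_frames) / substeps
  nstep <- abs(T_frames) * substeps
  px <- as.numeric(x); py <- as.numeric(y)
  t <- t0
  for (i in seq_len(nstep)) {
    if (method == "rk4") {
      k1 <- velocity_at(flds, px, py, t)
      k2 <- velocity_at(flds, clamp(px + h / 2 * k1$u, 1, W),
                        clamp(py + h / 2 * k1$v, 1, H), t + h / 2)
      k3 <- velocity_at(flds, clamp(px + h / 2 * k2$u, 1, W),
                        clamp(py + h / 2 * k2$v, 1, H), t + h / 2)
      k4 <- velocity_at(flds, clamp(px + h * k3$u, 1, W),
                        clamp(py + h * k3$v, 1, H), t + h)
      px <- px + h / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
      py <- py + h / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
    } else {
      k1 <- velocity_at(flds, px, py, t)
      px <- px + h * k1$u
      py <- py + h * k1$v
    }
    px <- clamp(px, 1, W)
    py <- clamp(py, 1, H)
    t <- t0 + i * h
  }
  list(x = px, y = py)
}

#' Integrate the flow map on the pixel grid
#'
#' Places one virtual particle at every pixel and advects it with
#' [advect_particles()] from base time `t0` over the signed horizon
#' `T_frames`. Negative horizons integrate backward in time (arithmetically
#' identical to integrating the time-reversed, negated series forward).
#' Particles are clamped at the domain boundary, which flattens stretching
#' there; the returned object flags boundary pixels.
#'
#' @param fields a [vector_field_series()].
#' @param t0 base time (step index).
#' @param T_frames signed horizon in frames.
#' @param substeps RK4 substeps per frame (default 2).
#' @return A `flow_map`: matrices `final_x`, `final_y`, plus `t0`, `T_frames`
#'   and a logical `boundary` matrix.
#' @export
integrate_flow_map <- function(fields, t0, T_frames, substeps = 2L) {
  H <- dim(fields$u)[1]; W <- dim(fields$u)[2]
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  fin <- advect_particles(fields, xs, ys, t0, T_frames, substeps)
  fx <- matrix(fin$x, H, W)
  fy <- matrix(fin$y, H, W)
  boundary <- fx <= 1 | fx >= W | fy <= 1 | fy >= H
  structure(list(final_x = fx, final_y = fy, t0 = t0, T_frames = T_frames,
                 boundary = boundary),
            class = "flow_map")
}

#' Finite-difference Jacobian of a flow map
#'
#' Central differences over immediate grid neighbours (spacing 2 px) at
#' interior pixels, one-sided differences at image boundaries. Returns the
#' four per-pixel entries `d(final_x)/dx`, `d(final_x)/dy`, `d(final_y)/dx`,
#' `d(final_y)/dy` as `H x W` matrices.
#'
#' @param map a `flow_map` from [integrate_flow_map()].
#' @return List of matrices `dxdx`, `dxdy`, `dydx`, `dydy`.
#' @export
flow_map_jacobian <- function(map) {
  stopifnot(inherits(map, "flow_map"))
  grad <- function(m, axis) {
    H <- nrow(m); W <- ncol(m)
    if (axis == "x") {
      fwd <- shift_mat(m, 0, -1); bwd <- shift_mat(m, 0, 1)
      den <- matrix(2, H, W); den[, c(1, W)] <- 1
    } else {
      fwd <- shift_mat(m, -1, 0); bwd <- shift_mat(m, 1, 0)
      den <- matrix(2, H, W); den[c(1, H), ] <- 1
    }
    (fwd - bwd) / den
  }
  list(
    dxdx = grad(map$final_x, "x"), dxdy = grad(map$final_x, "y"),
    dydx = grad(map$final_y, "x"), dydy = grad(map$final_y, "y")
  )
}

# Largest singular value of the per-pixel 2x2 Jacobian, computed in closed
# form: smax^2 = (q + sqrt(q^2 - 4 det^2)) / 2 with q the squared Frobenius
# norm. Equals sqrt of the largest eigenvalue of the Cauchy-Green tensor.
jacobian_smax <- function(J) {
  q <- J$dxdx^2 + J$dxdy^2 + J$dydx^2 + J$dydy^2
  det <- J$dxdx * J$dydy - J$dxdy * J$dydx
  disc <- pmax(q^2 - 4 * det^2, 0)
  sqrt((q + sqrt(disc)) / 2)
}

#' Finite-time Lyapunov exponent field for one base time
#'
#' Integrates the flow map over horizon `T_frames` (forward or backward),
#' differentiates it with [flow_map_jacobian()], and sets
#' `sigma = log(lambda_max) / |T|` per pixel. Under the default
#' singular-value convention `lambda_max` is the maximum singular value of
#' the flow-map Jacobian, which makes the perturbation bound
#' `||DPhi e|| <= exp(sigma |T|) ||e||` tight; `convention = "eigenvalue"`
#' instead uses the largest eigenvalue of the Cauchy-Green tensor (the square
#' of the former). Because activity flow is compressible, exponents can be
#' negative everywhere locally; only non-negative exponents are kept
#' (negative values are set to 0).
#'
#' @param fields a [vector_field_series()].
#' @param t0 base time (step index).
#' @param T_frames positive horizon length in frames.
#' @param direction `"forward"` or `"backward"`.
#' @param substeps RK4 substeps per frame.
#' @param convention `"singular_value"` (default) or `"eigenvalue"`.
#' @param roi optional logical mask; pixels outside become `NA`.
#' @return An `ftle_field`: matrix `sigma` (1/frames, >= 0), plus `t0`,
#'   `T_frames`, `direction` and the boundary flag matrix.
#' @export
ftle_field <- function(fields, t0, T_frames, direction = c("forward", "backward"),
                       substeps = 2L, convention = c("singular_value", "eigenvalue"),
                       roi = NULL) {
  direction <- match.arg(direction)
  convention <- match.arg(convention)
  if (T_frames < 1) stop("T_frames must be a positive horizon length")
  signed_T <- if (direction == "forward") T_frames else -T_frames
  map <- integrate_flow_map(fields, t0, signed_T, substeps)
  smax <- jacobian_smax(flow_map_jacobian(map))
  lam <- if (convention == "singular_value") smax else smax^2
  sigma <- log(pmax(lam, .Machine$double.xmin)) / T_frames
  sigma <- pmax(sigma, 0)
  if (!is.null(roi)) sigma[!roi] <- NA_real_
  structure(list(sigma = sigma, t0 = t0, T_frames = T_frames,
                 direction = direction, boundary = map$boundary),
            class = "ftle_field")
}

#' FTLE fields over a sweep of base times
#'
#' Evaluates [ftle_field()] at every admissible base time with spacing
#' `step`: forward base times satisfy `t0 + T <= n_steps`, backward base
#' times `t0 - T >= 1`; base times whose horizon would leave the recording
#' are omitted, mirroring the exclusion of bouts shorter than the
#' integration length.
#'
#' @param fields a [vector_field_series()].
#' @param T_frames positive horizon length in frames.
#' @param direction `"forward"` or `"backward"`.
#' @param step spacing between base times (default 1).
#' @param substeps RK4 substeps per frame.
#' @param convention FTLE convention, see [ftle_field()].
#' @param roi optional logical ROI mask.
#' @return An `ftle_series`: list of `ftle_field`s sharing `T_frames` and
#'   `direction`, with base times stored in `t0s`.
#' @export
ftle_series <- function(fields, T_frames, direction = c("forward", "backward"),
                        step = 1L, substeps = 2L,
                        convention = c("singular_value", "eigenvalue"),
                        roi = NULL) {
  direction <- match.arg(direction)
  convention <- match.arg(convention)
  ns <- n_steps(fields)
  if (ns <= T_frames)
    stop("series too short for integration length T = ", T_frames,
         " (", ns, " steps); longer bouts of data are required")
  t0s <- if (direction == "forward") {
    seq(1L, ns - T_frames, by = step)
  } else {
    seq(1L + T_frames, ns, by = step)
  }
  flds <- lapply(t0s, function(t0)
    ftle_field(fields, t0, T_frames, direction, substeps, convention, roi))
  structure(list(fields = flds, t0s = t0s, T_frames = T_frames,
                 direction = direction, dt = fields$dt),
            class = "ftle_series")
}

#' @export
print.ftle_series <- function(x, ...) {
  cat(sprintf("<ftle_series> %s, T = %d frames, %d base times (t0 = %d..%d)\n",
              x$direction, x$T_frames, length(x$t0s), min(x$t0s), max(x$t0s)))
  invisible(x)
}
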