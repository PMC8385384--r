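# Shared fixtures: everything is generated in code at test time.

# Chebyshev dilation by k px (3x3 square element applied k times).
dilate_k <- function(mask, k) {
  for (i in seq_len(k)) mask <- bw_dilate(mask)
  mask
}

# A smooth bright blob on a camera-scale intensity background, centred at
# (cy, cx); amplitude ~8-bit so the Horn-Schunck data term dominates alpha.
blob_frame <- function(H, W, cx, cy, sigma = 5, amplitude = 255) {
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  amplitude * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
}

# Build a frame_stack where every pixel follows the same temporal trace.
trace_stack <- function(trace, H = 2, W = 2, dt = 1, is_dff = FALSE) {
  arr <- array(rep(trace, each = H * W), dim = c(H, W, length(trace)))
  frame_stack(arr, dt = dt, is_dff = is_dff)
}

# Lightweight ftle_series stand-in from a list of sigma matrices (only the
# fields/t0s/T_frames/direction/dt slots that consumers read).
fake_ftle_series <- function(sigmas, direction = "forward", T_frames = 10, dt = 1) {
  structure(
    list(fields = lapply(sigmas, function(s)
           structure(list(sigma = s), class = "ftle_field")),
         t0s = seq_along(sigmas), T_frames = T_frames,
         direction = direction, dt = dt),
    class = "ftle_series"
  )
}

# Full portrait pipeline on a synthetic movie (no activity scaling: the
# movies are noise-free, so the denoising weights are unnecessary).
portrait_from_movie <- function(movie, T_frames, percentile) {
  flow <- compute_flow_series(movie$stack)
  flow <- temporal_smooth(flow)
  fwd <- ftle_series(flow, T_frames, "forward")
  bwd <- ftle_series(flow, T_frames, "backward")
  background <- apply(movie$stack$data, c(1, 2), mean)
  compose_portrait(fwd, bwd, background, percentile)
}
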