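# Horn-Schunck flow, activity scaling and temporal smoothing.

test_that("identical frames give zero flow", {
  a <- blob_frame(32, 32, 16, 16)
  fl <- horn_schunck_pair(a, a)
  expect_true(all(fl$u == 0) && all(fl$v == 0))
})

test_that("a blob translated by (1,0) is recovered in direction and rough magnitude", {
  a <- blob_frame(64, 64, 28, 32)
  b <- blob_frame(64, 64, 29, 32)
  fl <- horn_schunck_pair(a, b, hs_params(alpha = 1, max_iters = 100))
  support <- a > 0.1 * max(a)
  angle <- atan2(mean(fl$v[support]), mean(fl$u[support])) * 180 / pi
  mag <- mean(sqrt(fl$u[support]^2 + fl$v[support]^2))
  expect_lt(abs(angle), 10)
  expect_gt(mag, 0.5)
  expect_lt(mag, 1.5)
})

test_that("flow is equivariant to translating both frames together", {
  a <- blob_frame(48, 48, 20, 22)
  b <- blob_frame(48, 48, 21, 22)
  a2 <- shift_mat(a, 3, 5)
  b2 <- shift_mat(b, 3, 5)
  f1 <- horn_schunck_pair(a, b)
  f2 <- horn_schunck_pair(a2, b2)
  core <- 15:35
  expect_lt(max(abs(f1$u[core - 3, core - 5] - f2$u[core, core])), 0.02)
  expect_lt(max(abs(f1$v[core - 3, core - 5] - f2$v[core, core])), 0.02)
})

test_that("compute_flow_series obeys its count and sign contracts", {
  still <- frame_stack(array(blob_frame(16, 16, 8, 8), c(16, 16, 3)),
                       dt = 1, is_dff = TRUE)
  fl <- compute_flow_series(still)
  expect_equal(dim(fl$u)[3], 2L)
  expect_true(all(fl$u == 0) && all(fl$v == 0))

  many <- frame_stack(array(1, c(8, 8, 41)) + array(rnorm(8 * 8 * 41, sd = 1e-9), c(8, 8, 41)),
                      dt = 1, is_dff = TRUE)
  expect_equal(dim(compute_flow_series(many)$u)[3], 40L)

  # plane wave: spatially averaged flow near the front points in +x each step
  mv <- generate_movie(synthetic_movie_spec("plane_wave", height = 32, width = 32,
                                            n_frames = 20, x0 = 8, speed = 1,
                                            x_end = 28, ignition_frames = 0,
                                            fade_frames = 0))
  fl <- compute_flow_series(mv$stack)
  for (k in seq_len(dim(fl$u)[3])) {
    front <- mv$stack$data[, , k] > 0.2
    expect_gt(mean(fl$u[, , k][front]), 0)
  }

  expect_error(compute_flow_series(frame_stack(array(1, c(8, 8, 2)), dt = 1)),
               "dF/F")
})

test_that("activity scaling zeroes quiet pixels and never amplifies", {
  H <- 4; W <- 4; nf <- 6
  arr <- array(1, c(H, W, nf))
  arr[1, 1, ] <- c(0, 0, 1, 1, 1, 1)  # one step change at frame 3
  raw <- frame_stack(arr, dt = 1)
  u <- array(1, c(H, W, nf - 1)); v <- array(-2, c(H, W, nf - 1))
  flds <- vector_field_series(u, v, dt = 1)
  # delay of one frame, no window averaging (0.25 s rounds to 1 frame at dt=1)
  sc <- activity_scale(flds, raw, scaling_params(delay_s = 1, avg_window_s = 0.25))
  expect_true(all(sc$u[2, 2, ] == 0))             # constant pixel: weight 0
  expect_equal(sc$u[1, 1, 2], 1)                  # step into frame 3: max change
  expect_equal(sc$u[1, 1, 1], 0)                  # step into frame 2: no change
  expect_equal(sc$u[1, 1, 3], 0)                  # step into frame 4: no change
  expect_true(all(abs(sc$u) <= abs(u) + 1e-12))
  expect_true(all(abs(sc$v) <= abs(v) + 1e-12))

  # global normalization divides by the maximum change over all pixels
  arr2 <- arr
  arr2[3, 3, ] <- c(0, 0, 0.5, 0.5, 0.5, 0.5)   # half the global max change
  raw2 <- frame_stack(arr2, dt = 1)
  g <- activity_scale(flds, raw2, scaling_params(delay_s = 1, avg_window_s = 0.25),
                      global_norm = TRUE)
  expect_equal(g$u[3, 3, 2], 0.5)
  expect_equal(g$u[1, 1, 2], 1)

  expect_error(activity_scale(flds, raw, scaling_params(delay_s = 100)),
               "delay longer")
})

test_that("smoothing kernel matches the closed form and an independent oracle", {
  taps <- gaussian_window(5, 1.25, normalize = FALSE)
  expect_equal(taps,
               c(exp(-0.78125), exp(-0.1953125), 1, exp(-0.1953125), exp(-0.78125)),
               tolerance = 1e-15)
  # independent oracle: signal::gausswin divides by n where the classical
  # window divides by n - 1, so shape a maps to w = a * n / (n - 1)
  skip_if_not_installed("signal")
  expect_equal(taps, as.numeric(signal::gausswin(5, w = 1.25 * 5 / 4)),
               tolerance = 1e-12)
})

test_that("temporal smoothing preserves constants and commutes with scaling", {
  set.seed(5)
  u <- array(rnorm(6 * 6 * 9), c(6, 6, 9))
  v <- array(rnorm(6 * 6 * 9), c(6, 6, 9))
  flds <- vector_field_series(u, v, dt = 1)

  const <- vector_field_series(array(2, c(4, 4, 7)), array(-1, c(4, 4, 7)), dt = 1)
  sm <- temporal_smooth(const)
  expect_equal(sm$u, const$u)
  expect_equal(sm$v, const$v)

  s1 <- temporal_smooth(flds)
  scaled <- vector_field_series(3 * u, 3 * v, dt = 1)
  s2 <- temporal_smooth(scaled)
  expect_equal(s2$u, 3 * s1$u)
  expect_equal(s2$v, 3 * s1$v)

  expect_error(temporal_smooth(flds, kernel_len = 4), "odd")
  expect_error(temporal_smooth(flds, kernel_len = 11), "longer")
})
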