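# Event segmentation and summary metrics.

test_that("active fraction is zero for constants and matches constructed traces", {
  const <- trace_stack(rep(1, 10), H = 4, W = 4, is_dff = TRUE)
  tr <- active_fraction_trace(const)
  expect_true(all(tr$value == 0))

  # half the ROI pixels spike far above mean + sd at frame 10 (trace 0...0,10:
  # mean 1, sd sqrt(10), and 10 > 1 + sqrt(10)); the rest stay constant
  n <- 10
  arr <- array(0, c(2, 4, n))
  for (j in 1:2) arr[1, j, ] <- c(rep(0, n - 1), 10)        # spike at frame 10
  for (j in 3:4) arr[1, j, ] <- 5                           # flat: never active
  for (j in 1:4) arr[2, j, ] <- c(rep(0, n - 1), 10)
  stk <- frame_stack(arr, dt = 1, is_dff = TRUE)
  roi <- matrix(c(TRUE, FALSE), 2, 4)                        # keep row 1 only
  tr2 <- active_fraction_trace(stk, roi)
  # spiking pixels: mean 1, sd ~3.16, value 10 > 4.16 -> active at frame 10
  expect_equal(tr2$value[n], 0.5)
  expect_true(all(tr2$value >= 0 & tr2$value <= 1))
})

test_that("wave segmentation reproduces hand-traced crossings", {
  # run of trace >= 0.1 spans frames 11..31 and contains a 50% crossing:
  # the event is the half-open interval [11, 32)
  v <- rep(0.05, 40)
  v[11:31] <- c(seq(0.1, 0.6, length.out = 11), seq(0.55, 0.1, length.out = 10))
  ev <- segment_pan_cortical_waves(v, high = 0.5, low = 0.1, min_len = 5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 11L)
  expect_equal(ev$end, 32L)
  expect_true(all(v[ev$start:(ev$end - 1)] >= 0.1))

  # two 50% excursions inside one low envelope merge into a single wave
  v2 <- rep(0.02, 50)
  v2[11:40] <- 0.2
  v2[15:18] <- 0.7
  v2[30:33] <- 0.8
  ev2 <- segment_pan_cortical_waves(v2, 0.5, 0.1, 1)
  expect_equal(nrow(ev2), 1L)
  expect_equal(c(ev2$start, ev2$end), c(11L, 41L))

  # events shorter than min_len are discarded
  v3 <- rep(0.02, 20); v3[10:12] <- 0.9
  expect_equal(nrow(segment_pan_cortical_waves(v3, 0.5, 0.1, min_len = 5)), 0L)
  expect_equal(nrow(segment_pan_cortical_waves(v3, 0.5, 0.1, min_len = 3)), 1L)

  # a flat zero trace has no events; a trace that never falls back warns
  expect_equal(nrow(segment_pan_cortical_waves(rep(0, 10), 0.5, 0.1, 1)), 0L)
  v4 <- c(rep(0.02, 5), seq(0.2, 0.9, length.out = 10))
  expect_warning(ev4 <- segment_pan_cortical_waves(v4, 0.5, 0.1, 1), "recording end")
  expect_equal(ev4$end, 16L)
  expect_error(segment_pan_cortical_waves(v, high = 0.1, low = 0.5), "low < high")
})

test_that("segmented intervals are disjoint, sorted and low-bounded", {
  set.seed(42)
  for (rep in 1:10) {
    v <- pmax(0, pmin(1, stats::filter(runif(200), rep(1 / 15, 15), circular = TRUE)))
    v <- as.numeric(v) * 1.4
    ev <- suppressWarnings(segment_pan_cortical_waves(v, 0.5, 0.1, 1))
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$start) > 0))
      expect_true(all(ev$start[-1] >= ev$end[-nrow(ev)]))
    }
    for (i in seq_len(nrow(ev))) {
      seg <- v[ev$start[i]:(ev$end[i] - 1)]
      expect_gte(max(seg), 0.5)
      expect_true(all(seg >= 0.1))
      if (ev$start[i] > 1) expect_lt(v[ev$start[i] - 1], 0.1)
      if (ev$end[i] <= length(v)) expect_lt(v[ev$end[i]], 0.1)
    }
  }
})

test_that("movement score normalizes absolute frame differences", {
  static <- trace_stack(rep(2, 5), H = 3, W = 3)
  expect_true(all(movement_score_trace(static)$value == 0))

  arr <- array(0, c(5, 4, 3))
  arr[1:2, 1, 2] <- 1                    # 2 pixels change by 1 into frame 2
  arr[1:4, 1, 3] <- arr[1:4, 1, 2] + 1   # 4 pixels change by 1 into frame 3
  stk <- frame_stack(arr, dt = 1)
  tr <- movement_score_trace(stk)
  expect_equal(tr$value, c(0, 0.5, 1))   # sums 0, 2, 4, max-normalized

  # invariance to adding a constant to every frame
  stk2 <- frame_stack(arr + 7, dt = 1)
  expect_equal(movement_score_trace(stk2)$value, tr$value)

  # forward difference shifts the scores one frame earlier
  trf <- movement_score_trace(stk, difference = "forward")
  expect_equal(trf$value[length(trf$value)], 0)
  expect_equal(trf$value[-length(trf$value)], tr$value[-1])
})

test_that("FTLE intensity trace is max-normalized and scale invariant", {
  s <- fake_ftle_series(list(matrix(0.02, 10, 10), matrix(0.04, 10, 10)))
  tr <- ftle_intensity_trace(s)
  expect_equal(tr$value, c(0.5, 1))

  one <- fake_ftle_series(list(matrix(0.3, 5, 5)))
  expect_equal(ftle_intensity_trace(one)$value, 1)

  dbl <- fake_ftle_series(list(matrix(0.04, 10, 10), matrix(0.08, 10, 10)))
  expect_equal(ftle_intensity_trace(dbl)$value, tr$value)

  zero <- fake_ftle_series(list(matrix(0, 4, 4), matrix(0, 4, 4)))
  expect_equal(ftle_intensity_trace(zero)$value, c(0, 0))
})

test_that("ridge count score is components over area, exactly", {
  m <- matrix(FALSE, 20, 40)
  # five disjoint 10-px horizontal ridges
  for (i in 0:4) m[2 + 3 * i, 2:11] <- TRUE
  expect_equal(ridge_count_score(m)$score, 5 / 50)
  expect_equal(ridge_count_score(m)$n_ridges, 5L)

  one <- matrix(FALSE, 10, 10); one[3, 3:7] <- TRUE; one[4, 8] <- TRUE
  # translation invariance
  shifted <- shift_mat(one, 3, 2, pad = "zero")
  expect_equal(ridge_count_score(one)$score, ridge_count_score(shifted)$score)

  single <- matrix(FALSE, 5, 5); single[2, 2] <- TRUE
  expect_equal(ridge_count_score(single)$score, 1)
  expect_equal(ridge_count_score(matrix(FALSE, 5, 5))$score, 0)

  # a portrait object dispatches on direction
  p <- structure(list(forward = one, backward = shifted,
                      background = matrix(0, 10, 10),
                      params = list(T_frames = 1, threshold_percentile = 93)),
                 class = "flow_portrait")
  cmb <- ridge_count_score(p, "combined")
  expect_equal(cmb$ridge_area, sum(one | shifted))
})

test_that("paired comparison matches t.test and handles degenerate groups", {
  a <- c(0.0038, 0.0027, 0.0022, 0.0031)
  b <- c(0.0019, 0.0015, 0.0010, 0.0021)
  res <- compare_ridge_scores(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_false(res$degenerate)

  same <- compare_ridge_scores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  shiftd <- compare_ridge_scores(c(1, 2, 3), c(0, 1, 2))
  expect_equal(shiftd$p_value, 0)
  expect_true(is.infinite(shiftd$t) && shiftd$t > 0)
  expect_true(shiftd$degenerate)

  expect_error(compare_ridge_scores(1:3, 1:4), "equal-length")
  expect_error(compare_ridge_scores(1, 2), "2 pairs")
})

test_that("traces and events export to delimited text", {
  dir <- withr::local_tempdir()
  tr <- data.frame(frame = 1:3, time_s = 0:2, value = c(0, 0.5, 1))
  p1 <- file.path(dir, "trace.csv")
  write_trace_csv(tr, p1)
  expect_equal(utils::read.csv(p1)$value, tr$value)
  ev <- data.frame(start = 2L, end = 5L, kind = "pan_cortical_wave")
  p2 <- file.path(dir, "events.tsv")
  write_events_tsv(ev, p2)
  back <- utils::read.delim(p2)
  expect_equal(back$start, 2L)
  expect_equal(back$kind, "pan_cortical_wave")
})
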