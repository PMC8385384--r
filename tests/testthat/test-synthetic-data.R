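# Synthetic movies and analytic benchmark fields.

test_that("plane-wave front is where the generating formula puts it", {
  # no ignition/extinction: the crest moves from the first frame, so at
  # 0-based frame 10 the crest sits at column 32 + 10 = 42; evaluating the
  # generating Gaussian profile on integer columns puts the argmax there
  spec <- synthetic_movie_spec("plane_wave", n_frames = 32,
                               x0 = 32, speed = 1, x_end = 60,
                               ignition_frames = 0, fade_frames = 0)
  mv <- generate_movie(spec)
  profile <- colMeans(mv$stack$data[, , 11])  # frame index 11 = 0-based frame 10
  expect_identical(which.max(profile), 42L)
  expect_equal(mv$truth$front_position[11], 42)
})

test_that("movies are deterministic and bounded", {
  spec <- synthetic_movie_spec("plane_wave", noise_sd = 0.05, seed = 7L)
  m1 <- generate_movie(spec)
  m2 <- generate_movie(spec)
  expect_identical(m1$stack$data, m2$stack$data)

  clean <- generate_movie(synthetic_movie_spec("plane_wave"))
  expect_true(all(clean$stack$data >= 0 & clean$stack$data <= 1))
  noisier <- generate_movie(synthetic_movie_spec("plane_wave", noise_sd = 0.05, seed = 8L))
  expect_false(identical(clean$stack$data, noisier$stack$data))
})

test_that("front position advances by speed per frame during propagation", {
  spec <- synthetic_movie_spec("plane_wave", n_frames = 40, speed = 1.5,
                               ignition_frames = 8, fade_frames = 8, x_end = 1e6)
  mv <- generate_movie(spec)
  travel <- 10:31  # strictly inside the propagation phase (1-based frames)
  expect_equal(diff(mv$truth$front_position[travel]), rep(1.5, length(travel) - 1))
})

test_that("total intensity is non-decreasing while the front crosses, constant after exit", {
  spec <- synthetic_movie_spec("plane_wave", n_frames = 60, x0 = 32, speed = 2,
                               ignition_frames = 0, fade_frames = 0, x_end = 1e6)
  mv <- generate_movie(spec)
  totals <- apply(mv$stack$data, 3, sum)
  crossing <- totals[1:10]           # crest fully inside the frame
  expect_true(all(diff(crossing) >= -1e-9))
  exited <- totals[25:60]            # front beyond column 64 + several widths
  expect_true(all(abs(diff(exited)) < 1e-6))
})

test_that("translating gaussian starts at the appearance site and dies at the shrink site", {
  spec <- synthetic_movie_spec("translating_gaussian", n_frames = 40)
  mv <- generate_movie(spec)
  first <- mv$stack$data[, , 2]
  peak <- which(first == max(first), arr.ind = TRUE)[1, ]
  expect_true(mv$truth$initiation_mask[peak["row"], peak["col"]])
  late <- mv$stack$data[, , 38]
  peak_late <- which(late == max(late), arr.ind = TRUE)[1, ]
  expect_true(mv$truth$termination_mask[peak_late["row"], peak_late["col"]])
  # masks sit at distinct sites separated by the translation
  expect_false(any(mv$truth$initiation_mask & mv$truth$termination_mask))
})

test_that("movie specs validate their inputs", {
  expect_error(synthetic_movie_spec("vortex"), "arg")
  expect_error(synthetic_movie_spec("plane_wave", height = 4), "at least 8")
  expect_error(synthetic_movie_spec("plane_wave", speed = 0), "speed")
  expect_error(synthetic_movie_spec("plane_wave", noise_sd = -1), "noise_sd")
  expect_error(synthetic_movie_spec("plane_wave", bogus = 1), "unknown")
})

test_that("analytic fields match their closed forms", {
  z <- generate_analytic_field(analytic_field_spec("zero", 16, 16), 3)
  expect_true(all(z$u == 0) && all(z$v == 0))

  tr <- generate_analytic_field(analytic_field_spec("uniform_translation", 16, 16,
                                                    u0 = 1, v0 = 0), 3)
  expect_true(all(tr$u == 1) && all(tr$v == 0))

  sd65 <- analytic_field_spec("linear_saddle", 65, 65, a = 0.05)
  fl <- generate_analytic_field(sd65, 2)
  expect_equal(fl$u[33, 33, 1], 0)
  expect_equal(fl$v[33, 33, 1], 0)
  expect_equal(fl$u[33, 43, 1], 0.5)   # v = (a x, -a y) at x = centre + 10
  expect_equal(fl$v[33, 43, 1], 0)
  # steady kinds repeat the same field every step
  expect_identical(fl$u[, , 1], fl$u[, , 2])
})

test_that("double gyre has zero boundary-normal velocity", {
  dg <- generate_analytic_field(analytic_field_spec("double_gyre"), 10)
  H <- dim(dg$u)[1]; W <- dim(dg$u)[2]
  expect_true(all(abs(dg$u[, c(1, W), ]) < 1e-12))  # u = 0 on left/right edges
  expect_true(all(abs(dg$v[c(1, H), , ]) < 1e-12))  # v = 0 on top/bottom edges
  # unsteady: successive samples differ
  expect_false(identical(dg$u[, , 1], dg$u[, , 2]))
})

test_that("movies and ground truth round-trip to disk", {
  dir <- withr::local_tempdir()
  mv <- generate_movie(synthetic_movie_spec("circular_wave", n_frames = 12,
                                            ignition_frames = 2, fade_frames = 2))
  base <- file.path(dir, "circ")
  save_synthetic_movie(mv, base)
  expect_true(file.exists(paste0(base, ".tif")))
  side <- yaml::read_yaml(paste0(base, ".yaml"))
  expect_equal(side$front_position, as.numeric(mv$truth$front_position))
  back <- read_stack_tiff(paste0(base, ".tif"), dt = mv$spec$dt, is_dff = TRUE)
  expect_equal(dim(back$data), dim(mv$stack$data))
  expect_lt(max(abs(back$data - mv$stack$data)), 1e-6)
})
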