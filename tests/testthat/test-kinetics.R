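# shared fixture: a clean dried field for compositing time-lapses
tl_field <- function(canvas = c(200, 120), scale = 1, seed = 9) {
  generate_pore_field(microstructure_spec(
    canvas = canvas, pixel_scale = scale, n_pores = 25, seed = seed))
}

test_that("front positions are pixel-accurate for a straight front", {
  f <- tl_field(c(200, 256))
  kin <- front_kinetics_spec("+x", base_velocity = 10, frame_interval = 60,
                             n_frames = 12, seed = 4)
  tl <- generate_timelapse(f, kin)
  ref <- estimate_frozen_ref(tl$frames$frames[[1]], "+x")
  # frame 11: truth 100 um; every column within one pixel quantum
  p <- front_profile(tl$frames$frames[[11]], "+x", 1, frozen_ref = ref)
  expect_true(all(abs(p$positions_um - 100) <= 1))
  expect_false(p$complete)
})

test_that("block-fissured fronts resolve per column and average correctly", {
  f <- tl_field(c(200, 256))
  mult <- rep(c(1.0, 1.2), each = 100)
  kin <- front_kinetics_spec("+x", base_velocity = 10, n_frames = 12,
                             velocity_multipliers = mult, seed = 4)
  tl <- generate_timelapse(f, kin)
  ref <- estimate_frozen_ref(tl$frames$frames[[1]], "+x")
  # frame 11: truth alternates 100 / 120 um in 100-row blocks
  p <- front_profile(tl$frames$frames[[11]], "+x", 1,
                     cfg = detect_config(perp_window = 1), frozen_ref = ref)
  expect_equal(mean(p$positions_um), 110, tolerance = 0.02)
  expect_true(all(abs(p$positions_um[10:90] - 100) <= 1))
  expect_true(all(abs(p$positions_um[110:190] - 120) <= 1))
})

test_that("uniform frames classify as frozen or dried against the reference", {
  f <- tl_field(c(200, 120))
  kin <- front_kinetics_spec("+x", base_velocity = 15, n_frames = 12,
                             seed = 2)
  tl <- generate_timelapse(f, kin)
  ref <- estimate_frozen_ref(tl$frames$frames[[1]], "+x")
  p0 <- front_profile(tl$frames$frames[[1]], "+x", 1, frozen_ref = ref)
  expect_true(all(p0$positions_um == 0))
  expect_false(p0$complete)
  # front exits the 120 um extent after 8 min; frame 12 is fully dried
  p12 <- front_profile(tl$frames$frames[[12]], "+x", 1, frozen_ref = ref)
  expect_true(p12$complete)
  expect_true(all(p12$positions_um == 120))
  # a uniform frame without any reference cannot be interpreted
  expect_error(front_profile(tl$frames$frames[[1]], "+x", 1),
               "front not found")
})

test_that("noiseless constant-velocity recovery is exact", {
  f <- generate_pore_field(microstructure_spec(
    canvas = c(256, 256), pixel_scale = 1, n_pores = 40, noise_sigma = 0,
    seed = 2))
  kin <- front_kinetics_spec("+x", base_velocity = 15, frame_interval = 60,
                             n_frames = 9, frozen_noise = 0,
                             frame_noise = 0, seed = 5)
  tl <- generate_timelapse(f, kin)
  vt <- velocity_trace(tl$frames, "+x")
  expect_true(all(abs(vt$interval_velocities - 15) <= 1))  # 1 px / interval
  expect_equal(vt$mean_velocity, 15, tolerance = 1 / 15)
})

test_that("noisy front velocity is recovered within 5%", {
  f <- generate_pore_field(microstructure_spec(
    canvas = c(384, 384), pixel_scale = 0.5, n_pores = 60, seed = 12))
  kin <- front_kinetics_spec("+x", base_velocity = 10, frame_interval = 60,
                             n_frames = 10, seed = 11)
  tl <- generate_timelapse(f, kin)
  vt <- velocity_trace(tl$frames, "+x")
  expect_lt(abs(vt$mean_velocity - 10) / 10, 0.05)
})

test_that("velocity respects the time axis: origin shift and interval scaling", {
  f <- tl_field(c(128, 128), seed = 3)
  kin <- front_kinetics_spec("+x", base_velocity = 12, n_frames = 6,
                             seed = 8)
  tl <- generate_timelapse(f, kin)
  vt <- velocity_trace(tl$frames, "+x")
  shifted <- frame_sequence(tl$frames$frames, tl$frames$times_s + 3600,
                            tl$frames$pixel_scale)
  vs <- velocity_trace(shifted, "+x")
  expect_equal(vs$interval_velocities, vt$interval_velocities)
  # same displacements stamped at twice the interval: velocities halve
  stretched <- frame_sequence(tl$frames$frames, tl$frames$times_s * 2,
                              tl$frames$pixel_scale)
  v2 <- velocity_trace(stretched, "+x")
  expect_equal(v2$interval_velocities, vt$interval_velocities / 2)
  # column-mean displacement equals displacement of column means
  d1 <- diff(rowMeans(vt$positions_um))
  d2 <- rowMeans(apply(vt$positions_um, 2, diff))
  expect_equal(d1, d2)
})

test_that("degenerate sequences are rejected", {
  f <- tl_field(c(128, 128), seed = 3)
  kin <- front_kinetics_spec("+x", base_velocity = 12, n_frames = 6,
                             seed = 8)
  tl <- generate_timelapse(f, kin)
  one <- frame_sequence(tl$frames$frames[1], tl$frames$times_s[1], 1)
  expect_error(velocity_trace(one, "+x"), "at least 2 frames")
  uneven <- frame_sequence(tl$frames$frames[1:3], c(0, 60, 180), 1)
  expect_error(velocity_trace(uneven, "+x"), "constant within 1%")
})

test_that("ROI velocities reflect per-column multipliers and exit handling", {
  f <- generate_pore_field(microstructure_spec(
    canvas = c(256, 256), pixel_scale = 1, n_pores = 40, noise_sigma = 0,
    seed = 2))
  mult <- c(rep(1.0, 128), rep(1.2, 128))
  kin <- front_kinetics_spec("+x", base_velocity = 10, n_frames = 10,
                             velocity_multipliers = mult, seed = 6)
  tl <- generate_timelapse(f, kin)
  v1 <- velocity_trace(tl$frames, "+x", roi = roi("a", c(10, 110), c(1, 256)))
  v2 <- velocity_trace(tl$frames, "+x", roi = roi("b", c(146, 246), c(1, 256)))
  expect_lt(abs(v2$mean_velocity / v1$mean_velocity - 1.2) / 1.2, 0.1)
  # an ROI covering only the first 40 columns is exited quickly: fewer
  # usable intervals than the full field of view
  vs <- velocity_trace(tl$frames, "+x", roi = roi("c", c(10, 110), c(1, 40)))
  expect_lt(vs$n_intervals, v1$n_intervals)
  expect_lt(abs(vs$mean_velocity - 10) / 10, 0.1)
})

test_that("primary drying time uses the slowest column or extrapolates", {
  # front exits a 120 um extent at 15 um/min: completion at 8 min
  f <- tl_field(c(200, 120))
  kin <- front_kinetics_spec("+x", base_velocity = 15, n_frames = 12,
                             seed = 2)
  tl <- generate_timelapse(f, kin)
  vt <- velocity_trace(tl$frames, "+x")
  d <- primary_drying_time(vt)
  expect_equal(d$minutes, 8)
  expect_false(d$extrapolated)
  # extrapolation to the full sample extent: 3000 um / 15 um/min = 200 min
  d2 <- primary_drying_time(vt, extent_um = 3000)
  expect_equal(d2$minutes, 200, tolerance = 0.01)
  expect_true(d2$extrapolated)
  # block-fissured front: completion waits for the slowest block
  mult <- rep(c(1.25, 1.0), each = 100)
  kinf <- front_kinetics_spec("+x", base_velocity = 12, n_frames = 12,
                              velocity_multipliers = mult, seed = 2)
  tlf <- generate_timelapse(f, kinf)
  vtf <- velocity_trace(tlf$frames, "+x")
  df <- primary_drying_time(vtf)
  expect_equal(df$minutes, 10)  # slow block: 120 um at 12 um/min
})

test_that("a stationary front yields zero velocity and no drying time", {
  f <- tl_field(c(128, 128), seed = 3)
  kin <- front_kinetics_spec("+x", base_velocity = 10, n_frames = 5,
                             seed = 8)
  tl <- generate_timelapse(f, kin)
  frozen_frame <- tl$frames$frames[[3]]
  static <- frame_sequence(rep(list(frozen_frame), 4), (0:3) * 60, 1)
  vt <- velocity_trace(static, "+x")
  expect_equal(vt$mean_velocity, 0)
  expect_error(primary_drying_time(vt), "zero mean velocity")
})
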