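clean_scene <- function(...) {
  scene_config(width = 240L, height = 200L, frames = 1L, a_px = 50, b_px = 25,
               n_particles = 0L, blur_sd = 0, noise_sd = 0,
               body_texture_sd = 0, angle_step_sd = 0, swim_speed_px = 0,
               heading_sd = 0, drift_sd = 0, seed = 5, ...)
}

measure_frame <- function(frame) {
  mask <- ifelse(frame > 80, 255, 0)
  measure_object(select_largest(find_contours(mask)), frame,
                 c(0, 0, ncol(frame), nrow(frame)))
}

test_that("in-plane and end-on orientations bracket the silhouette", {
  v0 <- render_video(clean_scene(initial_axis = c(1, 0, 0)))
  m0 <- measure_frame(v0$frames[[1]])
  expect_equal(m0$major_axis_px, 100, tolerance = 0.015)  # 2a, theta = 0
  expect_equal(v0$truth$projected_major_px, 100)
  v90 <- render_video(clean_scene(initial_axis = c(0, 0, 1)))
  m90 <- measure_frame(v90$frames[[1]])
  expect_equal(m90$major_axis_px, 50, tolerance = 0.02)   # 2b, sphere-like
  expect_equal(m90$minor_axis_px, 50, tolerance = 0.02)
})

test_that("silhouette axes follow the spheroid projection law", {
  for (deg in seq(0, 90, by = 15)) {
    th <- deg * pi / 180
    v <- render_video(clean_scene(initial_axis = c(cos(th), 0, sin(th))))
    m <- measure_frame(v$frames[[1]])
    expected <- 2 * sqrt(50^2 * cos(th)^2 + 25^2 * sin(th)^2)
    expect_equal(m$major_axis_px, expected, tolerance = 0.02)
    expect_equal(v$truth$projected_major_px, expected, tolerance = 1e-9)
  }
})

test_that("projection never exceeds the true length", {
  cfg <- quick_scene(seed = 83)
  v <- render_video(cfg)
  expect_true(all(v$truth$projected_major_px <= 2 * cfg$a_px + 1e-9))
  expect_true(all(v$truth$projected_minor_px == 2 * cfg$b_px))
})

test_that("rendering is bit-reproducible under a fixed seed", {
  cfg <- quick_scene(frames = 10L, seed = 91)
  v1 <- render_video(cfg)
  v2 <- render_video(cfg)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$truth, v2$truth)
  v3 <- render_video(quick_scene(frames = 10L, seed = 92))
  expect_false(identical(v1$frames, v3$frames))
})

test_that("rendered videos round-trip to disk with their truth table", {
  dir <- withr::local_tempdir()
  cfg <- quick_scene(frames = 6L)
  v <- render_video(cfg, dir = dir, video_name = "fix01")
  expect_true(file.exists(v$video_path))
  expect_true(file.exists(v$truth_path))
  back <- read_video(v$video_path)
  expect_identical(back, lapply(v$frames, function(f) {
    storage.mode(f) <- "integer"; f
  }))
  tt <- utils::read.csv(v$truth_path)
  expect_equal(nrow(tt), 6)
  expect_equal(tt$true_length_mm, v$truth$true_length_mm)
})

test_that("invalid scene configurations are rejected before rendering", {
  expect_error(scene_config(a_px = 10, b_px = 20), "a >= b")
  expect_error(scene_config(body_intensity = 5, background_intensity = 8),
               "exceed")
  expect_error(scene_config(width = 100L, height = 100L,
                            crop_box = c(0, 0, 200, 100)), "within")
})

test_that("calibration cohorts are deterministic with truthful manual values", {
  tpl <- quick_scene(frames = 5L)
  c1 <- make_calibration_cohort(39, c(0.8, 4), template = tpl, seed = 7)
  expect_length(c1$configs, 39)
  expect_equal(nrow(c1$manual), 39)
  expect_true(all(c1$manual$manual_mm > 0))
  c2 <- make_calibration_cohort(39, c(0.8, 4), template = tpl, seed = 7)
  expect_identical(c1$manual, c2$manual)
  # noise-free manual measurements equal the truth exactly
  c0 <- make_calibration_cohort(5, c(1, 3), template = tpl,
                                manual_sd_mm = 0, seed = 11)
  expect_equal(c0$manual$manual_mm, c0$truth$true_length_mm)
  # aspect ratio of the template is preserved
  for (cfg in c0$configs) {
    expect_equal(cfg$a_px / cfg$b_px, tpl$a_px / tpl$b_px)
    expect_equal(2 * cfg$a_px * cfg$mm_per_px,
                 c0$truth$true_length_mm[which(vapply(
                   c0$configs, identical, logical(1), cfg))])
  }
})

test_that("the appendage is eroded away by the default morphology", {
  # both scenes share appendage_length_px (it enters the swim margin), so
  # the trajectories are identical and only the appendage pixels differ
  base <- scene_config(width = 260L, height = 220L, frames = 70L,
                       a_px = 30, b_px = 21, n_particles = 3L, seed = 17,
                       appendage_length_px = 18)
  withapp <- base
  withapp$appendage <- TRUE
  withapp$appendage_width_px <- 2
  prof <- sim_profile(95)
  rc <- run_config(profile = prof, mm_per_px = 0.02, seed = 3)
  est <- function(cfg) {
    process_video(render_video(cfg)$frames, rc, "app")$summary$length_mm
  }
  e_off <- est(base); e_on <- est(withapp)
  expect_lt(abs(e_on - e_off) / e_off, 0.03)
})
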