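test_that("detected events match generator ground truth within 2 frames", {
  for (spec in list(healthy_cohort_spec(), stroke_cohort_spec())) {
    tr <- quick_trial(spec, seed = 101)
    ev <- detect_gait_events(tr$recording)
    for (side in c("left", "right")) {
      dhs <- match_events(tr$events_true$heel_strikes[[side]],
                          ev$heel_strikes[[side]])
      expect_true(all(is.finite(dhs)))
      expect_lt(max(dhs), 0.02 + 1e-9)
      dto <- match_events(tr$events_true$toe_offs[[side]],
                          ev$toe_offs[[side]])
      expect_true(all(is.finite(dto)))
      expect_lt(max(dto), 0.02 + 1e-9)
    }
  }
})

test_that("standing still and too-short trials are rejected", {
  rec <- straight_walk_recording(speed = 0)   # no anterior progression
  expect_error(detect_gait_events(rec), "progression")
  tr <- quick_trial(healthy_cohort_spec(n_steps = 6), seed = 3)
  expect_error(detect_gait_events(tr$recording,
                                  gait_config(min_steps_per_trial = 50L)),
               "rejected")
})

test_that("event detection is equivariant to walking direction", {
  tr <- quick_trial(healthy_cohort_spec(marker_noise_sd = 0), seed = 5)
  rec <- tr$recording
  rev_rec <- rec
  for (cc in grep("_x$", names(rev_rec$data), value = TRUE)) {
    rev_rec$data[[cc]] <- -rev_rec$data[[cc]]
  }
  ev <- detect_gait_events(rec)
  ev_rev <- detect_gait_events(rev_rec)
  expect_equal(ev_rev$heel_strikes, ev$heel_strikes, tolerance = 1e-9)
  expect_equal(ev_rev$toe_offs, ev$toe_offs, tolerance = 1e-9)
})

test_that("spatio-temporal arithmetic matches the definitions", {
  rec <- straight_walk_recording(speed = 1.4, duration = 2)
  ev <- gait_events(
    heel_strikes = list(left = c(0, 1), right = c(0.5, 1.5)),
    toe_offs = list(left = 0.6, right = 1.1))
  st <- compute_spatiotemporal(ev, rec)
  val <- function(pp, side = NULL) {
    sel <- st$parameter == pp
    if (!is.null(side)) sel <- sel & st$side == side
    st$value[sel]
  }
  expect_equal(val("stride_time", "left"), 1.0)
  expect_equal(val("stride_time", "right"), 1.0)
  expect_equal(val("step_time", "left"), 0.5)
  expect_equal(val("step_time", "right"), 0.5)
  expect_equal(val("cadence"), 120)
  expect_equal(val("stride_length", "left"), 1.4, tolerance = 1e-9)
  expect_equal(val("step_length", "right"), 0.7, tolerance = 1e-9)
  expect_equal(val("ssws"), 1.4, tolerance = 1e-9)
  # toe offs at 60% of each cycle
  expect_equal(val("foot_off", "left"), 60, tolerance = 1e-9)
  expect_equal(val("foot_off", "right"), 60, tolerance = 1e-9)
  # two double-contact intervals of 0.1 s per 1 s cycle
  expect_equal(val("double_support"), 0.2, tolerance = 1e-9)
  # consistency: cadence * mean step time = 60
  expect_equal(val("cadence") * mean(c(val("step_time", "left"),
                                       val("step_time", "right"))), 60,
               tolerance = 1e-6)
})

test_that("parameters are recovered within 5% across speed/cadence grid", {
  for (speed in c(0.4, 0.9, 1.5)) {
    for (cadence in c(70, 120)) {
      stride <- speed * 120 / cadence
      if (stride < 0.45 || stride > 1.9) next
      spec <- cohort_spec(speed_mean = speed, speed_sd = 0,
                          stride_length_mean = stride, stride_length_sd = 0,
                          w_p_mean = max(0.1, 0.3 * speed), w_p_sd = 0,
                          w_k_mean = max(0.1, 0.35 * speed), w_k_sd = 0,
                          eri_sd = 0, marker_noise_sd = 0.0005,
                          n_steps = 8)
      tr <- quick_trial(spec, seed = round(1000 * speed + cadence))
      ev <- detect_gait_events(tr$recording)
      st <- compute_spatiotemporal(ev, tr$recording)
      val <- function(pp) mean(st$value[st$parameter == pp])
      expect_lt(abs(val("ssws") - tr$truth$ssws) / tr$truth$ssws, 0.05)
      expect_lt(abs(val("stride_length") - tr$truth$stride_length) /
                  tr$truth$stride_length, 0.05)
      expect_lt(abs(val("cadence") - tr$truth$cadence) / tr$truth$cadence, 0.05)
      expect_lt(abs(val("double_support") - tr$truth$double_support) /
                  tr$truth$double_support, 0.05)
    }
  }
})

test_that("stroke-like trial recovers SSWS as stride length over stride time", {
  # stride time 1.52 s with stride length 0.78 m implies SSWS ~ 0.513 m/s
  spec <- stroke_cohort_spec(speed_mean = 0.78 / 1.52, speed_sd = 0,
                             stride_length_sd = 0)
  tr <- quick_trial(spec, seed = 9)
  expect_equal(tr$truth$stride_time, 1.52, tolerance = 1e-9)
  ev <- detect_gait_events(tr$recording)
  st <- compute_spatiotemporal(ev, tr$recording)
  ssws <- st$value[st$parameter == "ssws"]
  expect_lt(abs(ssws - 0.78 / 1.52) / (0.78 / 1.52), 0.05)
})

test_that("double support grows with stance fraction", {
  ds <- vapply(c(0.60, 0.66, 0.72), function(fo) {
    spec <- cohort_spec(speed_mean = 1.0, speed_sd = 0,
                        stride_length_mean = 1.1, stride_length_sd = 0,
                        foot_off_first_mean = fo, foot_off_first_sd = 0,
                        foot_off_second_mean = fo, foot_off_second_sd = 0,
                        eri_sd = 0, marker_noise_sd = 0, n_steps = 8)
    tr <- quick_trial(spec, seed = 77)
    ev <- detect_gait_events(tr$recording)
    st <- compute_spatiotemporal(ev, tr$recording)
    st$value[st$parameter == "double_support"]
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
  expect_true(all(ds >= 0))
})

test_that("segment_steps produces contiguous alternating intervals", {
  ev <- gait_events(heel_strikes = list(left = c(0, 1), right = 0.5))
  steps <- segment_steps(ev)
  expect_equal(steps$t_start, c(0, 0.5))
  expect_equal(steps$t_end, c(0.5, 1))
  expect_equal(steps$side, c("left", "right"))
  # single heel strike: no steps
  ev1 <- gait_events(heel_strikes = list(left = 0.5, right = numeric(0)))
  expect_equal(nrow(segment_steps(ev1)), 0L)
  # non-alternating strikes are inconsistent
  expect_error(
    gait_events(heel_strikes = list(left = c(0, 0.4), right = 0.9)),
    "alternate")
  # asymmetric stroke-like timing gives alternating unequal intervals
  ev2 <- gait_events(heel_strikes = list(left = c(0, 1.53, 3.06),
                                         right = c(0.68, 2.21)))
  steps2 <- segment_steps(ev2)
  expect_equal(steps2$duration, c(0.68, 0.85, 0.68, 0.85), tolerance = 1e-9)
})

test_that("limb pooling follows the paired-test rule strictly", {
  params <- tibble::tibble(
    subject_id = "s1",
    parameter = rep(c("step_time", "foot_off"), each = 2),
    side = rep(c("left", "right"), 2),
    value = c(0.5, 0.5, 61.3, 71.05),
    n_cycles = 5L)
  tests <- tibble::tibble(parameter = c("step_time", "foot_off"),
                          p_value = c(0.8, 0.001))
  pooled <- pool_limbs(params, tests)
  # identical sides pool to the common value
  expect_equal(pooled$value[pooled$parameter == "step_time"], 0.5)
  expect_equal(pooled$side[pooled$parameter == "step_time"], "pooled")
  # significant side difference keeps sides separate
  expect_setequal(pooled$side[pooled$parameter == "foot_off"],
                  c("left", "right"))
  # p exactly at the threshold keeps sides separate
  tests_border <- tibble::tibble(parameter = "step_time", p_value = 0.05)
  pooled2 <- pool_limbs(params[params$parameter == "step_time", ], tests_border)
  expect_setequal(pooled2$side, c("left", "right"))
})
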