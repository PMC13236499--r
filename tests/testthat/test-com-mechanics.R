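test_that("CoM estimate is the pelvic-marker centroid and is translation-equivariant", {
  rec <- straight_walk_recording()
  com <- estimate_com(rec)
  # centroid of the four pelvic offsets used by the fixture:
  # ap offsets +-0.11/-0.12 average to -0.005 relative to the common path
  mid <- (marker_xyz(rec, "LASI") + marker_xyz(rec, "RASI") +
            marker_xyz(rec, "LPSI") + marker_xyz(rec, "RPSI")) / 4
  expect_equal(com$ap, mid[, "x"], tolerance = 1e-9)
  expect_equal(com$v, mid[, "z"] - 0.02, tolerance = 1e-9)  # floor at heel height
  # translating every marker shifts the CoM identically
  shifted <- rec
  for (cc in grep("_x$", names(shifted$data), value = TRUE)) {
    shifted$data[[cc]] <- shifted$data[[cc]] + 3.2
  }
  com2 <- estimate_com(shifted)
  expect_equal(com2$ap - com$ap, rep(3.2, nrow(com)), tolerance = 1e-9)
  expect_equal(com2$v, com$v, tolerance = 1e-9)
})

test_that("zero-phase low-pass filter has unit DC gain and expected roll-off", {
  cfg <- gait_config()
  sr <- 100
  t <- seq(0, 5, by = 1 / sr)
  expect_lt(max(abs(lowpass_filter(rep(2.5, length(t)), sr, cfg) - 2.5)), 1e-5)
  # 1 Hz passband tone: amplitude preserved within 1%, no phase shift
  x1 <- sin(2 * pi * 1 * t)
  y1 <- lowpass_filter(x1, sr, cfg)
  interior <- 100:400
  expect_lt(max(abs(y1[interior] - x1[interior])), 0.01)
  # 30 Hz stopband tone: attenuated below 10%
  x30 <- sin(2 * pi * 30 * t)
  y30 <- lowpass_filter(x30, sr, cfg)
  expect_lt(max(abs(y30[interior])), 0.1)
  expect_error(lowpass_filter(1:5, sr, cfg), "short")
  expect_error(lowpass_filter(sin(t), 15, cfg), "Nyquist")
})

test_that("finite-difference velocity matches analytic derivatives", {
  sr <- 100
  t <- seq(0, 2, by = 1 / sr)
  # linear ramp at a typical self-selected walking speed
  v <- finite_velocity(1.42 * t, sr)
  expect_equal(v, rep(1.42, length(t)), tolerance = 1e-9)
  expect_equal(finite_velocity(rep(5, 20), sr), rep(0, 20))
  expect_length(v, length(t))
  # slow sinusoid: derivative within 1% of 2 pi f cos (small f dt)
  srf <- 1000
  tf <- seq(0, 1, by = 1 / srf)
  f <- 1
  vf <- finite_velocity(sin(2 * pi * f * tf), srf)
  ref <- 2 * pi * f * cos(2 * pi * f * (tf + 0.5 / srf))  # forward-diff midpoint
  interior <- 10:(length(tf) - 10)
  expect_lt(max(abs(vf[interior] - ref[interior])) / (2 * pi * f), 0.01)
  expect_error(finite_velocity(1, 100), "two samples")
})

test_that("energies follow E_P = mgh and E_K = mv^2/2 and sum pointwise", {
  cfg <- gait_config()
  com <- tibble::tibble(time = c(0, 0.01), v = c(1, 1),
                        v_ap = c(0, 1), v_ml = 0, v_v = 0)
  en <- com_energies(com, mass = 70, cfg)
  expect_equal(en$e_p, c(686.7, 686.7))
  expect_equal(en$e_k, c(0, 35))
  expect_equal(en$e_tot, en$e_p + en$e_k)
  en2 <- com_energies(com, mass = 140, cfg)
  expect_equal(en2$e_p, 2 * en$e_p)
  expect_equal(en2$e_k, 2 * en$e_k)
  expect_error(com_energies(com, mass = 0, cfg), "positive")
})

test_that("positive work sums positive increments only", {
  expect_equal(positive_work(c(0, 1, 0, 1)), 2)
  expect_equal(positive_work(seq(10, 0, by = -1)), 0)
  # sinusoid of amplitude A over an integer cycle has positive variation 2A
  t <- seq(0, 1, length.out = 1001)
  expect_equal(positive_work(3.7 * sin(2 * pi * t)), 2 * 3.7,
               tolerance = 1e-4)
  expect_error(positive_work(1), "2 samples")
})

test_that("recovery and congruity match sinusoid closed forms", {
  eri_of <- function(phase, ...) {
    ec <- make_energy_curves(phase, ...)
    energy_recovery(positive_work(ec$e_p), positive_work(ec$e_k),
                    positive_work(ec$e_tot))
  }
  cong_of <- function(phase) {
    ec <- make_energy_curves(phase)
    as.numeric(congruity(ec$e_p, ec$e_k, attr(ec, "sample_rate")))
  }
  expect_equal(eri_of(pi), 100, tolerance = 0.5)
  expect_equal(eri_of(0), 0, tolerance = 0.5)
  expect_equal(eri_of(pi / 2), 100 * (1 - cos(pi / 4)), tolerance = 0.5)
  expect_equal(cong_of(0), 100, tolerance = 1)
  expect_equal(cong_of(pi), 0, tolerance = 1)
  expect_equal(cong_of(pi / 2), 50, tolerance = 1)
  # full sweep: recovery falls and congruity rises as curves come into phase
  phis <- seq(0, pi, by = pi / 8)
  eris <- vapply(phis, eri_of, numeric(1))
  congs <- vapply(phis, cong_of, numeric(1))
  expect_lt(max(abs(eris - 100 * (1 - abs(cos(phis / 2))))), 0.5)
  expect_lt(max(abs(congs - 100 * (1 - phis / pi))), 1)
  expect_true(all(diff(eris) > -1e-9))
  expect_true(all(diff(congs) < 1e-9))
})

test_that("recovery is bounded and works subadditive on random curves", {
  set.seed(99)
  for (i in 1:40) {
    n <- 200
    e_p <- cumsum(rnorm(n)); e_k <- cumsum(rnorm(n))
    w_p <- positive_work(e_p); w_k <- positive_work(e_k)
    w_tot <- positive_work(e_p + e_k)
    expect_lte(w_tot, w_p + w_k + 1e-12)
    if (w_p + w_k > 0) {
      eri <- energy_recovery(w_p, w_k, w_tot)
      expect_gte(eri, 0); expect_lte(eri, 100)
    }
  }
  expect_error(energy_recovery(0, 0, 0), "Undefined")
  expect_error(congruity(rep(1, 10), sin(1:10), 100), "constant")
})

test_that("time normalization is exact on linear curves and preserves works", {
  cfg <- gait_config()
  t <- seq(0, 1, by = 0.01)
  tn <- time_normalize(t, 2 * t + 1, 0.2, 0.8, cfg)
  expect_equal(nrow(tn), 101L)
  expect_equal(tn$value[1], 1.4, tolerance = 1e-12)
  expect_equal(tn$value[101], 2.6, tolerance = 1e-12)
  expect_equal(tn$value, 2 * seq(0.2, 0.8, length.out = 101) + 1,
               tolerance = 1e-12)
  expect_error(time_normalize(t, t, -0.5, 0.8, cfg), "support")
  # positive works on raw vs normalized band-limited curves agree within 2%
  ec <- make_energy_curves(2.2, samples_per_cycle = 100, n_cycles = 2)
  raw_w <- positive_work(ec$e_tot)
  norm <- time_normalize(ec$time, ec$e_tot, 0, 2, gait_config(
    normalized_samples_per_step = 201L))
  expect_lt(abs(positive_work(norm$value) - raw_w) / raw_w, 0.02)
})

test_that("per-step mechanics are mass-invariant in J/kg and average correctly", {
  tr <- quick_trial(healthy_cohort_spec(marker_noise_sd = 0), seed = 21)
  rec <- tr$recording
  ev <- detect_gait_events(rec)
  sm1 <- step_mechanics(rec, ev)
  rec2 <- rec
  rec2$anthropometrics <- anthropometrics(
    mass = 2 * rec$anthropometrics$mass,
    leg_length = rec$anthropometrics$leg_length)
  sm2 <- step_mechanics(rec2, ev)
  expect_equal(sm2$w_p, sm1$w_p, tolerance = 1e-9)
  expect_equal(sm2$w_k, sm1$w_k, tolerance = 1e-9)
  expect_equal(sm2$eri_pct, sm1$eri_pct, tolerance = 1e-9)
  # the summary of identical steps equals the single-step value
  one <- sm1[1, ]
  rep3 <- dplyr::bind_rows(one, one, one)
  expect_equal(summarize_mechanics(rep3)$eri_pct, one$eri_pct)
  expect_equal(summarize_mechanics(rep3)$n_steps, 3L)
})

test_that("a healthy-like subject lands in the normative recovery band", {
  tr <- quick_trial(healthy_cohort_spec(), seed = 42)
  ev <- detect_gait_events(tr$recording)
  sm <- summarize_mechanics(step_mechanics(tr$recording, ev))
  expect_gt(sm$eri_pct, 55)
  expect_lt(sm$eri_pct, 80)
  # and tracks the generator's own ground truth closely
  expect_lt(abs(sm$eri_pct - tr$truth$eri), 4)
  expect_lt(abs(sm$congruity_pct - tr$truth$congruity), 6)
})
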