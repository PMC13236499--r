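test_that("marker table round trip preserves coordinates and metadata", {
  set.seed(11)
  tr <- make_walking_trial(healthy_cohort_spec(n_steps = 4), 1)
  rec <- tr$recording
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_table(rec, path)
  back <- read_marker_table(path)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_identical(back$subject_id, rec$subject_id)
  expect_identical(back$group, rec$group)
  expect_identical(sort(marker_labels(back)), sort(marker_labels(rec)))
  for (lab in marker_labels(rec)) {
    expect_lt(max(abs(marker_xyz(back, lab) - marker_xyz(rec, lab))), 1e-9)
  }
  expect_equal(back$anthropometrics$mass, rec$anthropometrics$mass)
})

test_that("millimetre coordinates are converted to metres", {
  # explicit units header
  lines <- c("# sample_rate: 100", "# units: mm",
             "frame,LASI_x,LASI_y,LASI_z",
             "0,100,0,1000", "1,110,0,1005")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path)
  rec <- read_marker_table(path)
  expect_equal(marker_xyz(rec, "LASI")[, "z"], c(1.000, 1.005))
  # auto-detection from magnitudes > 50
  lines2 <- c("# sample_rate: 100",
              "frame,LASI_x,LASI_y,LASI_z",
              "0,100,0,950", "1,110,0,955")
  writeLines(lines2, path)
  rec2 <- read_marker_table(path)
  z <- marker_xyz(rec2, "LASI")[, "z"]
  expect_true(all(z > 0.5 & z < 1.5))
})

test_that("malformed tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# sample_rate: 100", "frame,LASI_x,LASI_y,LASI_w",
               "0,1,2,3"), path)
  expect_error(read_marker_table(path), "LASI_w")
  writeLines(c("# sample_rate: 100", "frame,LASI_x,LASI_y,LASI_z",
               "0,1,2,3", "1,1,2"), path)
  expect_error(read_marker_table(path), "[Rr]agged")
  writeLines(c("# sample_rate: 100", "frame,LASI_x,LASI_y,LASI_z",
               "0,1,two,3"), path)
  expect_error(read_marker_table(path), "Non-numeric")
  writeLines(c("frame,LASI_x,LASI_y,LASI_z", "0,1,2,3"), path)
  expect_error(read_marker_table(path), "[Ss]ample rate")
})

test_that("missing required markers are reported by name", {
  rec <- straight_walk_recording()
  rec$data$RPSI_x <- rec$data$RPSI_y <- rec$data$RPSI_z <- NULL
  expect_error(require_markers(rec), "RPSI")
  expect_error(detect_gait_events(rec), "RPSI")
})

test_that("marker label dialects resolve to canonical names", {
  lines <- c("# sample_rate: 100",
             "frame,L_ASIS_x,L_ASIS_y,L_ASIS_z",
             "0,0.1,0,0.95")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, path)
  rec <- read_marker_table(path)
  expect_true("LASI" %in% marker_labels(rec))
})

test_that("single-frame recordings survive the round trip", {
  rec <- gait_recording(tibble::tibble(LASI_x = 0.1, LASI_y = 0, LASI_z = 1),
                        sample_rate = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_table(rec, path)
  back <- read_marker_table(path)
  expect_equal(nrow(back$data), 1L)
  expect_equal(marker_xyz(back, "LASI"), marker_xyz(rec, "LASI"),
               tolerance = 1e-12)
})

test_that("recordings without marker columns are refused", {
  expect_error(gait_recording(tibble::tibble(a = 1:3), sample_rate = 100),
               "marker")
})

test_that("C3D round trips in metre and millimetre units", {
  set.seed(12)
  tr <- make_walking_trial(healthy_cohort_spec(n_steps = 4), 1)
  rec <- tr$recording
  for (units in c("m", "mm")) {
    path <- withr::local_tempfile(fileext = ".c3d")
    write_c3d(rec, path, units = units)
    back <- read_c3d(path)
    expect_equal(back$sample_rate, rec$sample_rate)
    expect_identical(sort(marker_labels(back)), sort(marker_labels(rec)))
    for (lab in c("LASI", "RHEE")) {
      # float32 storage limits round-trip precision
      expect_lt(max(abs(marker_xyz(back, lab) - marker_xyz(rec, lab))), 1e-4)
    }
  }
})

test_that("constant-position C3D content is preserved exactly enough", {
  rec <- gait_recording(
    tibble::tibble(LASI_x = rep(0.1, 10), LASI_y = rep(0, 10),
                   LASI_z = rep(1.0, 10)),
    sample_rate = 100)
  path <- withr::local_tempfile(fileext = ".c3d")
  write_c3d(rec, path)
  back <- read_c3d(path)
  expect_equal(unname(marker_xyz(back, "LASI")[1, ]), c(0.1, 0, 1.0),
               tolerance = 1e-6)
})

test_that("short marker gaps are interpolated, long gaps invalidated", {
  rec <- straight_walk_recording()
  truth <- rec$data$LASI_x
  rec$data$LASI_x[20:25] <- NA          # 6-frame gap: fillable
  rec$data$LASI_x[100:120] <- NA        # 21-frame gap: too long
  filled <- fill_marker_gaps(rec, max_gap_frames = 10)
  expect_lt(max(abs(filled$data$LASI_x[20:25] - truth[20:25])), 1e-6)
  expect_true(all(100:120 %in% attr(filled, "invalid_frames")))
  expect_true(all(is.na(filled$data$LASI_x[100:120])))
})
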