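make_torque_recording <- function(torque, fs = 1024, target_level = 0.10,
                                  task = "flexion", rest_s = 0,
                                  phase = "submaximal") {
  n <- length(torque)
  emg_recording(matrix(0, 16, n), fs, tiny_geometry(4, 4), torque,
                task, if (phase == "endurance") NA_real_ else target_level,
                phase = phase, rest_s = rest_s)
}

test_that("submaximal selection takes the windows closest to the target force", {
  fs <- 1024
  # 3 s rest at ~0 torque, 10 s exactly at target: contraction windows tie,
  # earliest 20 win
  torque <- c(numeric(3 * fs), rep(10, 10 * fs))
  rec <- make_torque_recording(torque, fs, 0.10, rest_s = 3)
  ep <- select_submax_epochs(rec)
  expect_identical(nrow(ep$epochs), 20L)
  expect_identical(ep$epochs$window, 13:32)
  # graded deviations: ranking follows |mean torque - target|
  dev <- rep(seq(0, 4.8, length.out = 40), each = fs / 4)
  rec2 <- make_torque_recording(c(numeric(3 * fs), 10 + dev), fs, 0.10, rest_s = 3)
  ep2 <- select_submax_epochs(rec2)
  expect_identical(ep2$epochs$window, 13:32)   # smallest deviations are earliest
  # a torque that never enters the band fails with a shortfall message
  saw <- 20 + 10 * abs(seq(-1, 1, length.out = 13 * fs))
  expect_error(select_submax_epochs(make_torque_recording(saw, fs, 0.10, rest_s = 3)),
               "only 0 windows")
  # exactly 20 qualifying windows are all returned
  torque3 <- c(numeric(3 * fs), rep(10, 5 * fs), rep(40, 5 * fs))
  ep3 <- select_submax_epochs(make_torque_recording(torque3, fs, 0.10, rest_s = 3))
  expect_identical(ep3$epochs$window, 13:32)
})

test_that("the torque band is level-specific (5 at 10 %MVC, 10 at 30/50 %MVC)", {
  fs <- 1024
  t30 <- c(rep(38, 6 * fs))   # 8 off target: inside the 30 % band of 10
  ep <- select_submax_epochs(make_torque_recording(t30, fs, 0.30), n = 20)
  expect_identical(nrow(ep$epochs), 20L)
  t10 <- rep(16, 6 * fs)      # 6 off target: outside the 10 % band of 5
  expect_error(select_submax_epochs(make_torque_recording(t10, fs, 0.10), n = 20),
               "only 0")
})

test_that("rest epochs come from the 3 s prefixes, lowest torque first", {
  fs <- 1024
  recs <- lapply(1:12, function(i) {
    tq <- c(abs(numeric(3 * fs) + 0.01 * i), rep(10, 7 * fs))
    make_torque_recording(tq, fs, 0.10, rest_s = 3)
  })
  ep <- select_rest_epochs(recs)                 # 144 candidates -> 60
  expect_identical(nrow(ep$epochs), 60L)
  expect_identical(unique(ep$epochs$class), "NoAct")
  # lowest-torque recordings contribute first: recordings 1-5 fully used
  expect_true(all(1:5 %in% ep$epochs$recording))
  expect_false(any(ep$epochs$recording > 5))
  expect_true(all(ep$epochs$window <= 12))
  # a recording without rest prefix is skipped with a warning
  recs2 <- c(recs[1:4], list(make_torque_recording(rep(10, 5 * fs), fs, 0.10)))
  expect_warning(e2 <- select_rest_epochs(recs2, n_total = 48), "skipped")
  expect_false(any(e2$epochs$recording == 5))
  # all-zero torque everywhere: earliest windows win by tie-break
  recs3 <- lapply(1:6, function(i)
    make_torque_recording(numeric(6 * fs), fs, 0.10, rest_s = 3))
  e3 <- select_rest_epochs(recs3, n_total = 60)
  expect_identical(nrow(e3$epochs), 60L)
  expect_identical(e3$epochs$window[1:12], 1:12)
  expect_error(select_rest_epochs(recs3[1:2], n_total = 60), "available")
})

test_that("TDC segmentation partitions the contraction into equal quintiles", {
  fs <- 1024
  # 3 s rest + 25 s contraction = 100 contraction windows
  rec <- make_torque_recording(c(numeric(3 * fs), rep(50, 25 * fs)), fs,
                               phase = "endurance", rest_s = 3)
  seg <- tdc_segments(rec)
  expect_identical(lengths(seg), rep(20L, 5))
  expect_identical(seg[[1]][1], 13L)
  expect_identical(unlist(seg), 13:112)
  # remainder windows go to the last segment
  rec2 <- make_torque_recording(c(numeric(3 * fs), rep(50, 25.75 * fs)), fs,
                                phase = "endurance", rest_s = 3)
  seg2 <- tdc_segments(rec2)
  expect_identical(lengths(seg2), c(20L, 20L, 20L, 20L, 23L))
  expect_identical(unlist(seg2), 13:115)
  expect_error(tdc_segments(make_torque_recording(
    c(numeric(3 * fs), rep(50, fs)), fs, phase = "endurance", rest_s = 3)),
    "segments")
  expect_error(tdc_segments(make_torque_recording(rep(10, 5 * fs), fs, 0.10)),
               "endurance")
})

test_that("TDC segmentation is a partition for arbitrary lengths", {
  fs <- 1024
  set.seed(15)
  for (rep_i in 1:8) {
    n_con <- sample(6:40, 1)
    rec <- make_torque_recording(c(numeric(3 * fs), rep(50, n_con * fs)), fs,
                                 phase = "endurance", rest_s = 3)
    seg <- tdc_segments(rec)
    all_w <- unlist(seg)
    expect_identical(all_w, 13:(12 + 4 * n_con))
    expect_identical(anyDuplicated(all_w), 0L)
  }
})

test_that("the time-effect subset is the first TDC quintile", {
  fs <- 1024
  rec <- make_torque_recording(c(numeric(3 * fs), rep(50, 25 * fs)), fs,
                               phase = "endurance", rest_s = 3, task = "pronation")
  te <- time_effect_subset(rec)
  expect_identical(te$epochs$window, tdc_segments(rec)[[1]])
  expect_identical(unique(te$epochs$class), "pronation")
  # 10 contraction windows -> first quintile has 2
  rec2 <- make_torque_recording(c(numeric(3 * fs), rep(50, 2.5 * fs)), fs,
                                phase = "endurance", rest_s = 3)
  expect_identical(length(time_effect_subset(rec2)$epochs$window), 2L)
})

test_that("selected submaximal epochs never overlap and satisfy the band", {
  sess <- cached_fixture("separable")
  sub <- Filter(function(r) r$phase == "submaximal", sess$session$recordings)
  for (rec in sub[1:4]) {
    ep <- select_submax_epochs(rec)
    expect_identical(anyDuplicated(ep$epochs$window), 0L)
    win <- round(0.25 * rec$fs)
    target <- 100 * rec$target_level
    half <- if (rec$target_level == 0.10) 5 else 10
    for (w in ep$epochs$window) {
      mt <- mean(rec$torque[((w - 1) * win + 1):(w * win)])
      expect_lte(abs(mt - target), half)
    }
  }
})
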