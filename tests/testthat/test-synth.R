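test_that("the generator is deterministic: same config, identical output", {
  cfg <- fixture_config("separable", seed = 31)
  r1 <- simulate_recording(cfg, "flexion", 0.30, "submaximal", seed = 4)
  r2 <- simulate_recording(cfg, "flexion", 0.30, "submaximal", seed = 4)
  expect_identical(r1$recording$signals, r2$recording$signals)
  expect_identical(r1$recording$torque, r2$recording$torque)
})

test_that("silent muscles leave clean noise at the configured floor", {
  cfg <- fixture_config("separable", seed = 32)
  cfg$gains <- lapply(cfg$gains, function(g) lapply(g, function(x) 0))
  cfg$line_amp <- numeric(0)
  r <- simulate_recording(cfg, "flexion", 0.30, "submaximal", seed = 5)
  expect_identical(length(screen_channels(r$recording)$bad), 0L)
  maps <- compute_maps(r$recording)
  # intensity of pure noise ~ log10(noise RMS)
  expect_equal(intensity(maps[[1]][[20]]), log10(cfg$noise_mv),
               tolerance = 0.05)
})

test_that("the map CG of a simulated source sits at the configured center", {
  cfg <- fixture_config("separable", seed = 33)
  cfg$noise_mv <- 0.002                      # high SNR
  ctr <- c(3, 8)
  cfg$centers$biceps_brachii <- lapply(cfg$centers$biceps_brachii,
                                       function(z) ctr)
  # widen A2 for an interior center
  cfg$geometries <- small_geometries()
  cfg$geometries[[2]] <- array_geometry("A2", 6, 12,
    muscle_regions = list(biceps_brachii = c(1, 12)))
  r <- simulate_recording(cfg, "flexion", 0.50, "submaximal", seed = 6)
  maps <- compute_maps(r$recording)$biceps_brachii
  mean_map <- Reduce(`+`, maps[13:40]) / 28
  cg <- center_of_gravity(mean_map)
  expect_lt(abs(cg["row"] - ctr[1]), 0.5)
  expect_lt(abs(cg["col"] - ctr[2]), 0.5)
})

test_that("doubling the gains raises intensity by log10(2) and leaves CG alone", {
  cfg <- fixture_config("separable", seed = 34)
  cfg$line_amp <- numeric(0); cfg$noise_mv <- 0.002
  r1 <- simulate_recording(cfg, "extension", 0.50, "submaximal", seed = 7)
  cfg2 <- cfg
  cfg2$gains <- lapply(cfg$gains, function(g) lapply(g, function(x) 2 * x))
  r2 <- simulate_recording(cfg2, "extension", 0.50, "submaximal", seed = 7)
  m1 <- compute_maps(r1$recording)$triceps_brachii[[30]]
  m2 <- compute_maps(r2$recording)$triceps_brachii[[30]]
  expect_equal(intensity(m2) - intensity(m1), log10(2), tolerance = 0.05)
  expect_equal(center_of_gravity(m2), center_of_gravity(m1), tolerance = 0.1)
})

test_that("a default session has the documented composition", {
  cfg <- fixture_config("separable", seed = 35)
  sess <- simulate_session(cfg)
  phases <- vapply(sess$session$recordings, `[[`, character(1), "phase")
  expect_identical(sum(phases == "submaximal"), 12L)
  expect_identical(sum(phases == "endurance"), 4L)
  tl <- vapply(sess$session$recordings[phases == "submaximal"],
               `[[`, numeric(1), "target_level")
  expect_identical(sort(unique(tl)), c(0.10, 0.30, 0.50))
  # torque satisfies the epoching band for at least 20 windows by construction
  for (rec in sess$session$recordings[phases == "submaximal"])
    expect_silent(select_submax_epochs(rec))
})

test_that("configured artifact channels are exactly the screened ones", {
  cfg <- fixture_config("artifact_channels", seed = 36)
  r <- simulate_recording(cfg, "flexion", 0.30, "submaximal", seed = 8)
  expect_identical(screen_channels(r$recording)$bad, cfg$bad_channels)
})

test_that("fatigue drift compresses the source spectrum monotonically", {
  cfg <- fixture_config("fatigue_drift", seed = 37)
  r <- simulate_recording(cfg, "flexion", 0.50, "endurance", seed = 9)
  rec <- r$recording
  seg <- tdc_segments(rec)
  # strongest channel of biceps region
  tbl <- hdemgid:::muscle_channel_table(rec$geometries)
  ch <- tbl$biceps_brachii$channels[which.max(
    rowMeans(rec$signals[tbl$biceps_brachii$channels, ]^2))]
  win <- round(0.25 * rec$fs)
  mdf <- vapply(seg, function(ws) {
    idx <- ((min(ws) - 1) * win + 1):(max(ws) * win)
    median_freq(rec$signals[ch, idx], rec$fs)
  }, numeric(1))
  expect_true(all(diff(mdf) < 0))
})

test_that("chance preset signals carry no class information", {
  cfg <- fixture_config("chance", seed = 38)
  # identical seeds give identical signals for different task labels
  r1 <- simulate_recording(cfg, "flexion", 0.30, "submaximal", seed = 10)
  r2 <- simulate_recording(cfg, "pronation", 0.30, "submaximal", seed = 10)
  expect_identical(r1$recording$signals, r2$recording$signals)
})
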