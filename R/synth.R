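#' Configuration of the synthetic HD-EMG session generator
#'
#' The generator emulates the phenomenology the pipeline assumes: each
#' muscle is driven by one band-limited (15-350 Hz) Gaussian source
#' process, projected onto its electrode region through a 2-D Gaussian
#' spatial profile whose center and gain depend on the (muscle, task) pair;
#' effort scales gains through a concave power law (`gain proportional to
#' level^level_exponent`, reflecting the nonlinear EMG-amplitude/force
#' relation); independent channel noise, common power-line interference,
#' a 3 s rest prefix, and — for endurance recordings — fatigue drift
#' (gain growth and spectral compression toward low frequencies as the
#' total duration of contraction advances) and an optional per-channel
#' multiplicative gel-drying gain walk.
#'
#' @param seed Master seed; all generator randomness derives from it.
#' @param fs Sampling rate, Hz.
#' @param geometries Electrode montage (list of [array_geometry()]).
#' @param tasks Task labels.
#' @param levels Submaximal target levels (fractions of MVC).
#' @param gains Named list per muscle of named per-task base gains (mV at
#'   50 %MVC); `NULL` uses a physiologically plausible default.
#' @param centers Named list per muscle of per-task `(row, col)` source
#'   centers in region coordinates; `NULL` places task-specific centers
#'   around the region center.
#' @param sigma Spatial spread of the source profile, electrode pitches.
#' @param level_exponent Exponent of the level-to-gain law.
#' @param noise_mv Channel noise RMS, mV.
#' @param line_amp Amplitudes (mV) of the power-line fundamental and
#'   harmonics added to every channel.
#' @param line_freq Line fundamental, Hz.
#' @param rest_gain_frac Source gain during the rest prefix relative to the
#'   contraction gain.
#' @param rest_s,submax_s,endurance_s Durations (s) of the rest prefix, of
#'   a submaximal contraction and of an endurance contraction.
#' @param torque_noise_sd Fast torque noise, %MVC.
#' @param torque_wander Amplitude of the slow torque wander, %MVC.
#' @param fatigue_gain_slope Fractional gain increase over the full TDC:
#'   a scalar, or a named per-muscle list for differential fatigue
#'   (0 disables).
#' @param fatigue_spectral_compression Final upper band edge as a fraction
#'   of the initial 350 Hz (1 disables).
#' @param gel_drift_sd Standard deviation of the per-channel log-gain
#'   random walk at the end of an endurance recording (0 disables).
#' @param bad_channels Integer global channel indices given an artifact.
#' @param artifact_type `"lowfreq"`, `"line"` or `"dead"`.
#' @param normalize_regional_intensity If `TRUE`, spatial profiles are
#'   rescaled so every task yields exactly the same regional mean absolute
#'   weight (classes then differ only in source position, not intensity).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, fs = 2048, geometries = default_geometries(),
                       tasks = c("flexion", "extension", "supination", "pronation"),
                       levels = c(0.10, 0.30, 0.50),
                       gains = NULL, centers = NULL, sigma = 1.0,
                       level_exponent = 0.7, noise_mv = 0.02,
                       line_amp = c(0.010, 0.005, 0.003, 0.002, 0.001, 0.001),
                       line_freq = 50, rest_gain_frac = 0.02,
                       rest_s = 3, submax_s = 10, endurance_s = 60,
                       torque_noise_sd = 0.5, torque_wander = 1.5,
                       fatigue_gain_slope = 0, fatigue_spectral_compression = 1,
                       gel_drift_sd = 0, bad_channels = integer(0),
                       artifact_type = "lowfreq",
                       normalize_regional_intensity = FALSE) {
  stopifnot(sigma > 0, level_exponent > 0, noise_mv >= 0,
            all(levels > 0), rest_s >= 0, submax_s > 0, endurance_s > 0)
  tbl <- muscle_channel_table(geometries)
  muscles <- names(tbl)
  if (is.null(gains)) gains <- default_gains(muscles, tasks)
  if (is.null(centers)) centers <- default_centers(tbl, tasks)
  for (m in muscles) {
    info <- tbl[[m]]
    for (tk in tasks) {
      ctr <- centers[[m]][[tk]]
      if (ctr[1] < 1 || ctr[1] > info$rows || ctr[2] < 1 || ctr[2] > info$cols)
        stop(sprintf("sim_config: source center of %s/%s outside its region",
                     m, tk), call. = FALSE)
      if (gains[[m]][[tk]] < 0)
        stop("sim_config: gains must be non-negative", call. = FALSE)
    }
  }
  structure(list(seed = seed, fs = fs, geometries = geometries, tasks = tasks,
                 levels = levels, gains = gains, centers = centers,
                 sigma = sigma, level_exponent = level_exponent,
                 noise_mv = noise_mv, line_amp = line_amp,
                 line_freq = line_freq, rest_gain_frac = rest_gain_frac,
                 rest_s = rest_s, submax_s = submax_s,
                 endurance_s = endurance_s,
                 torque_noise_sd = torque_noise_sd,
                 torque_wander = torque_wander,
                 fatigue_gain_slope = fatigue_gain_slope,
                 fatigue_spectral_compression = fatigue_spectral_compression,
                 gel_drift_sd = gel_drift_sd, bad_channels = bad_channels,
                 artifact_type = artifact_type,
                 normalize_regional_intensity = normalize_regional_intensity),
            class = "sim_config")
}

# Plausible relative involvement of the five muscles in the four tasks
# (mV source gain at 50 %MVC at the profile center).
default_gains <- function(muscles, tasks) {
  base <- list(
    biceps_brachii  = c(flexion = 0.80, extension = 0.06, supination = 0.50, pronation = 0.10),
    triceps_brachii = c(flexion = 0.06, extension = 0.80, supination = 0.10, pronation = 0.10),
    anconeus        = c(flexion = 0.06, extension = 0.50, supination = 0.10, pronation = 0.20),
    brachioradialis = c(flexion = 0.60, extension = 0.10, supination = 0.30, pronation = 0.30),
    pronator_teres  = c(flexion = 0.10, extension = 0.10, supination = 0.15, pronation = 0.70))
  out <- list()
  for (m in muscles) {
    g <- if (m %in% names(base)) base[[m]] else
      stats::setNames(rep(0.4, length(tasks)), tasks)
    out[[m]] <- as.list(g[tasks])
  }
  out
}

# Task-specific source centers spread around each region's center.
default_centers <- function(tbl, tasks) {
  shifts <- list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  out <- list()
  for (m in names(tbl)) {
    info <- tbl[[m]]
    c0 <- c((info$rows + 1) / 2, (info$cols + 1) / 2)
    sc <- c(max(0.5, (info$rows - 2) / 4), max(0.5, (info$cols - 2) / 4))
    out[[m]] <- stats::setNames(lapply(seq_along(tasks), function(i) {
      s <- shifts[[(i - 1) %% 4 + 1]]
      pmin(pmax(c0 + s * sc, 1), c(info$rows, info$cols))
    }), tasks)
  }
  out
}

# Theoretical output RMS of a forward-backward Butterworth band-pass driven
# by unit-variance white noise: mean of |H|^4 over frequency.
fb_butter_gain <- function(band, fs, order = 4, n_grid = 4096L) {
  bf <- signal::butter(order, band * 2 / fs, type = "pass")
  H <- signal::freqz(bf$b, bf$a, n = n_grid)$h
  sqrt(mean(Mod(H)^4))
}

# Band-limited unit-RMS source; for fatiguing contractions the upper band
# edge shrinks with TDC by crossfading progressively low-passed versions.
# Normalization uses the filter's theoretical white-noise gain, not the
# realized sample SD: per-realization normalization would pin the total
# windowed power of a recording and anti-correlate its analysis windows.
make_source <- function(n, fs, tau, compression) {
  w <- stats::rnorm(n)
  hi0 <- min(350, 0.45 * fs)
  if (compression < 1) {
    L <- 5L
    fracs <- seq(1, compression, length.out = L)
    vers <- vapply(fracs, function(f) {
      bf <- signal::butter(4, c(15, hi0 * f) * 2 / fs, type = "pass")
      signal::filtfilt(bf, w) / fb_butter_gain(c(15, hi0 * f), fs)
    }, numeric(n))
    p <- tau * (L - 1L)
    l <- pmin(floor(p), L - 2L)
    a <- p - l
    (1 - a) * vers[cbind(seq_len(n), l + 1L)] +
      a * vers[cbind(seq_len(n), l + 2L)]
  } else {
    bf <- signal::butter(4, c(15, hi0) * 2 / fs, type = "pass")
    signal::filtfilt(bf, w) / fb_butter_gain(c(15, hi0), fs)
  }
}

#' Simulate one HD-EMG recording with ground truth
#'
#' @param cfg A [sim_config()].
#' @param task Task label.
#' @param level Target level (fraction of MVC); endurance recordings are
#'   always performed at 0.50.
#' @param phase `"submaximal"` or `"endurance"`.
#' @param seed Seed for this recording (defaults to `cfg$seed`).
#' @return List with `recording` (an [emg_recording()]) and `truth`
#'   (per-muscle gains, centers, drift trajectories, bad channels).
#' @export
simulate_recording <- function(cfg, task, level = 0.50,
                               phase = c("submaximal", "endurance"),
                               seed = cfg$seed) {
  phase <- match.arg(phase)
  set.seed(seed)
  fs <- cfg$fs
  contr_s <- if (phase == "endurance") cfg$endurance_s else cfg$submax_s
  n_rest <- as.integer(round(cfg$rest_s * fs))
  n_con <- as.integer(round(contr_s * fs))
  n <- n_rest + n_con
  tbl <- muscle_channel_table(cfg$geometries)
  n_ch <- sum(vapply(cfg$geometries, n_channels, integer(1)))
  sig <- matrix(0, n_ch, n)
  tau <- c(rep(0, n_rest), seq(0, 1, length.out = n_con))
  active <- c(rep(0, n_rest), rep(1, n_con))
  lvl_gain <- if (phase == "endurance") 0.50 else level
  compression <- if (phase == "endurance") cfg$fatigue_spectral_compression else 1
  truth_gain <- list(); truth_ctr <- list()
  for (m in names(tbl)) {
    info <- tbl[[m]]
    src <- make_source(n, fs, tau, compression)
    g <- cfg$gains[[m]][[task]] * (lvl_gain / 0.5)^cfg$level_exponent
    ctr <- cfg$centers[[m]][[task]]
    rows <- rep(seq_len(info$rows), each = info$cols)
    cols <- rep(seq_len(info$cols), times = info$rows)
    w <- exp(-((rows - ctr[1])^2 + (cols - ctr[2])^2) / (2 * cfg$sigma^2))
    if (cfg$normalize_regional_intensity) w <- 0.25 * w / mean(w)
    gain_t <- g * (cfg$rest_gain_frac + (1 - cfg$rest_gain_frac) * active)
    slope_m <- if (length(cfg$fatigue_gain_slope) > 1L)
      cfg$fatigue_gain_slope[[m]] else cfg$fatigue_gain_slope
    if (phase == "endurance" && slope_m != 0)
      gain_t <- gain_t * (1 + slope_m * tau)
    sig[info$channels, ] <- sig[info$channels, ] +
      outer(w, src * gain_t)
    truth_gain[[m]] <- g; truth_ctr[[m]] <- ctr
  }
  sig <- sig + matrix(stats::rnorm(n_ch * n, sd = cfg$noise_mv), n_ch, n)
  if (any(cfg$line_amp > 0)) {
    tt <- seq_len(n) - 1L
    line <- numeric(n)
    for (h in seq_along(cfg$line_amp))
      if (cfg$line_amp[h] > 0)
        line <- line + cfg$line_amp[h] *
          sin(2 * pi * cfg$line_freq * h * tt / fs + stats::runif(1, 0, 2 * pi))
    coupling <- stats::runif(n_ch, 0.5, 1.5)
    sig <- sig + outer(coupling, line)
  }
  gel <- NULL
  if (cfg$gel_drift_sd > 0 && phase == "endurance") {
    win <- as.integer(round(0.25 * fs))
    n_seg <- ceiling(n / win)
    gel <- matrix(NA_real_, n_ch, n_seg)
    for (ch in seq_len(n_ch)) {
      walk <- cumsum(stats::rnorm(n_seg)) / sqrt(n_seg) * cfg$gel_drift_sd
      gel[ch, ] <- exp(walk)
      sig[ch, ] <- sig[ch, ] * rep(gel[ch, ], each = win)[seq_len(n)]
    }
  }
  if (length(cfg$bad_channels)) {
    tt <- seq_len(n) - 1L
    for (ch in cfg$bad_channels) {
      sig[ch, ] <- switch(cfg$artifact_type,
        lowfreq = sig[ch, ] + 0.8 * sin(2 * pi * 5 * tt / fs),
        line = sig[ch, ] + 1.0 * sin(2 * pi * cfg$line_freq * tt / fs),
        dead = stats::rnorm(n, sd = 1e-4),
        stop("simulate_recording: unknown artifact_type", call. = FALSE))
    }
  }
  target_pct <- if (phase == "endurance") 50 else 100 * level
  wander <- cfg$torque_wander *
    sin(2 * pi * 0.2 * (seq_len(n_con) / fs) + stats::runif(1, 0, 2 * pi))
  torque <- c(stats::rnorm(n_rest, 0, 0.2),
              target_pct + wander + stats::rnorm(n_con, 0, cfg$torque_noise_sd))
  rec <- emg_recording(sig, fs = fs, geometries = cfg$geometries,
                       torque = torque, task = task,
                       target_level = if (phase == "endurance") NA_real_ else level,
                       phase = phase, rest_s = cfg$rest_s)
  list(recording = rec,
       truth = list(task = task, level = level, phase = phase,
                    gains = truth_gain, centers = truth_ctr,
                    bad_channels = cfg$bad_channels, gel = gel, seed = seed))
}

#' Simulate a full two-part measurement session
#'
#' Part 1: one submaximal recording per task x level, in seeded random
#' order. Part 2: one endurance contraction at 50 %MVC per task, with the
#' configured fatigue and gel drift.
#'
#' @param cfg A [sim_config()].
#' @param subject_id Subject label for the session.
#' @return List with `session` (an [emg_session()]) and `truth` (list of
#'   per-recording ground truth, in session order).
#' @export
simulate_session <- function(cfg, subject_id = "synthetic") {
  grid <- expand.grid(task = cfg$tasks, level = cfg$levels,
                      stringsAsFactors = FALSE)
  set.seed(cfg$seed)
  grid <- grid[sample(nrow(grid)), ]
  recs <- list(); truth <- list()
  rec_seed <- function(i) (abs(cfg$seed) %% 100000L) * 10007L + i * 127L
  for (i in seq_len(nrow(grid))) {
    r <- simulate_recording(cfg, grid$task[i], grid$level[i], "submaximal",
                            seed = rec_seed(i))
    recs[[length(recs) + 1L]] <- r$recording
    truth[[length(truth) + 1L]] <- r$truth
  }
  for (j in seq_along(cfg$tasks)) {
    r <- simulate_recording(cfg, cfg$tasks[j], 0.50, "endurance",
                            seed = rec_seed(nrow(grid) + j))
    recs[[length(recs) + 1L]] <- r$recording
    truth[[length(truth) + 1L]] <- r$truth
  }
  list(session = emg_session(recs, subject_id = subject_id), truth = truth)
}

#' Small deterministic fixture sessions
#'
#' Fast presets on the reduced 84-channel montage at 1024 Hz, used by the
#' test-suite and the validation properties:
#' \describe{
#'   \item{separable}{Distinct per-task gains and source centers; the
#'     pipeline should identify tasks nearly perfectly.}
#'   \item{spatial_only}{All tasks share identical regional intensity by
#'     construction and differ only in source centers: intensity features
#'     carry no class information, spatial features carry it all. One
#'     effort level (30 %MVC), longer contractions for a larger epoch pool.}
#'   \item{chance}{Task labels independent of the signals (identical
#'     sources for every task, rest gain equal to contraction gain):
#'     classification must perform at chance.}
#'   \item{fatigue_drift}{Separable classes plus strong fatigue drift on
#'     the endurance recordings: gain grows by 80 % over the TDC and the
#'     source band compresses to 40 % of its initial upper edge.}
#'   \item{gel_drift}{Separable classes plus a per-channel multiplicative
#'     gel-drying gain walk (log-gain sd 0.5 at end) on part-2 recordings.}
#'   \item{artifact_channels}{Separable classes with a configured set of
#'     artifact channels.}
#' }
#'
#' @param name Preset label.
#' @param seed Seed.
#' @return The [sim_config()] of the preset (pass to [simulate_session()]),
#'   so callers can inspect or tweak the conditions.
#' @export
fixture_config <- function(name = c("separable", "spatial_only", "chance",
                                    "fatigue_drift", "gel_drift",
                                    "artifact_channels"),
                           seed = 1) {
  name <- match.arg(name)
  base <- list(seed = seed, fs = 1024, geometries = small_geometries(),
               sigma = 0.8, noise_mv = 0.02, line_amp = numeric(0),
               submax_s = 7, endurance_s = 25)
  args <- switch(name,
    separable = base,
    spatial_only = utils::modifyList(base, list(
      levels = 0.30, submax_s = 12,
      gains = uniform_gains(), normalize_regional_intensity = TRUE)),
    chance = utils::modifyList(base, list(
      gains = uniform_gains(), centers = shared_centers(),
      rest_gain_frac = 1)),
    fatigue_drift = utils::modifyList(base, list(
      gains = moderate_gains(),
      fatigue_gain_slope = list(biceps_brachii = 1.0, triceps_brachii = 0.25,
                                anconeus = 0.7, brachioradialis = 0.45,
                                pronator_teres = 0.15),
      fatigue_spectral_compression = 0.4)),
    gel_drift = utils::modifyList(base, list(
      gains = moderate_gains(), gel_drift_sd = 0.5)),
    artifact_channels = utils::modifyList(base, list(
      bad_channels = c(2L, 40L, 70L), artifact_type = "lowfreq")))
  do.call(sim_config, args)
}

# Moderate task contrast in gains: classes overlap enough in intensity for
# amplitude drift to matter, while source centers stay fully informative.
moderate_gains <- function() {
  base <- list(
    biceps_brachii  = c(flexion = 0.60, extension = 0.30, supination = 0.45, pronation = 0.35),
    triceps_brachii = c(flexion = 0.30, extension = 0.60, supination = 0.35, pronation = 0.45),
    anconeus        = c(flexion = 0.35, extension = 0.50, supination = 0.40, pronation = 0.45),
    brachioradialis = c(flexion = 0.55, extension = 0.35, supination = 0.50, pronation = 0.40),
    pronator_teres  = c(flexion = 0.35, extension = 0.40, supination = 0.45, pronation = 0.60))
  lapply(base, as.list)
}

# Equal gain for every task (per muscle): removes intensity information.
uniform_gains <- function() {
  tasks <- c("flexion", "extension", "supination", "pronation")
  ms <- muscle_order()
  stats::setNames(lapply(ms, function(m)
    stats::setNames(as.list(rep(0.5, 4)), tasks)), ms)
}

# Identical source center for every task: removes spatial information too.
shared_centers <- function() {
  tbl <- muscle_channel_table(small_geometries())
  tasks <- c("flexion", "extension", "supination", "pronation")
  stats::setNames(lapply(names(tbl), function(m) {
    info <- tbl[[m]]
    c0 <- c((info$rows + 1) / 2, (info$cols + 1) / 2)
    stats::setNames(lapply(tasks, function(t) c0), tasks)
  }), names(tbl))
}

#' @rdname fixture_config
#' @export
make_fixture <- function(name, seed = 1) {
  simulate_session(fixture_config(name, seed), subject_id = paste0("fix_", name))
}
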