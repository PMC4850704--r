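# Shared helpers: brute-force oracles and lazily cached fixture sessions.

.fixture_cache <- new.env(parent = emptyenv())

# Fixture sessions are expensive; build each (name, seed) once per run.
cached_fixture <- function(name, seed = 5) {
  key <- paste0(name, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_fixture(name, seed = seed)
  .fixture_cache[[key]]
}

# A tiny one-muscle recording for unit tests.
tiny_geometry <- function(rows = 4, cols = 4, muscle = "m")
  list(array_geometry("G", rows, cols,
                      muscle_regions = stats::setNames(list(c(1, cols)), muscle)))

tiny_recording <- function(signals, fs = 1024, torque = NULL,
                           task = "flexion", target_level = 0.10,
                           rest_s = 0, geometries = NULL) {
  if (is.null(geometries)) {
    side <- sqrt(nrow(signals))
    geometries <- tiny_geometry(side, side)
  }
  if (is.null(torque)) torque <- numeric(ncol(signals))
  emg_recording(signals, fs = fs, geometries = geometries, torque = torque,
                task = task, target_level = target_level, rest_s = rest_s)
}

# ---- independent brute-force oracles -----------------------------------

oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}

oracle_intensity <- function(map, eps = 1e-6) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(map))) for (j in seq_len(ncol(map))) {
    s <- s + map[i, j]; n <- n + 1
  }
  log10(max(s / n, eps))
}

oracle_cg <- function(map) {
  si <- 0; sj <- 0; s <- 0
  for (i in seq_len(nrow(map))) for (j in seq_len(ncol(map))) {
    si <- si + map[i, j] * i; sj <- sj + map[i, j] * j; s <- s + map[i, j]
  }
  c(si / s, sj / s)
}

oracle_indices <- function(M) {
  k <- nrow(M); total <- sum(M)
  out <- matrix(NA_real_, k, 4)
  for (c in seq_len(k)) {
    tp <- M[c, c]
    fn <- sum(M[c, ]) - tp
    fp <- sum(M[, c]) - tp
    tn <- total - tp - fn - fp
    out[c, ] <- c((tp + tn) / total,
                  tp / (tp + fn),
                  if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                  tn / (tn + fp))
  }
  colnames(out) <- c("Acc", "S", "P", "SP")
  out
}

# Single-bin periodogram power with a coherent window (for line-filter
# measurements; assumes f0 falls on an exact bin of a 1024-sample grid).
one_bin_power <- function(s, fs, f0) {
  m <- length(s) - length(s) %% 1024L
  s <- s[seq_len(m)]
  Mod(stats::fft(s)[round(f0 * m / fs) + 1L])^2 / m
}

# Windowed median frequency of a signal segment.
median_freq <- function(x, fs) {
  p <- Mod(stats::fft(x))^2
  n <- length(x)
  half <- seq_len(n %/% 2)
  p <- p[half]
  fr <- (half - 1) * fs / n
  cum <- cumsum(p) / sum(p)
  fr[which(cum >= 0.5)[1]]
}
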