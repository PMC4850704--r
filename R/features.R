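#' Map intensity feature
#'
#' The intensity of an activation map is the common logarithm of its mean
#' cell value, `I = log10(mean(HM))`. EMG amplitude grows nonlinearly with
#' force, and the logarithmic intensity has proven better behaved for
#' classification than the linear mean. Means below the floor `eps` are
#' clamped before taking the log (near-silent rest windows).
#'
#' @param map An `activation_map` or non-negative numeric matrix.
#' @param eps Clamping floor in mV (default 1e-6).
#' @return Scalar intensity, log10 mV.
#' @export
intensity <- function(map, eps = 1e-6) {
  v <- as.numeric(map)
  if (any(v < 0)) stop("intensity: map cells must be non-negative", call. = FALSE)
  log10(max(mean(v), eps))
}

#' Center of gravity of an activation map
#'
#' Intensity-weighted mean electrode coordinate,
#' `CG = sum(HM[i,j] * (i, j)) / sum(HM)`, with 1-based grid coordinates in
#' electrode-pitch units. The CG summarizes where on the muscle the
#' activity sits; unlike the intensity it is invariant to a global gain.
#'
#' @param map An `activation_map` or non-negative numeric matrix.
#' @return Numeric `c(row, col)`.
#' @export
center_of_gravity <- function(map) {
  v <- unclass(map)
  tot <- sum(v)
  if (tot <= 0)
    stop("center_of_gravity: undefined for an all-zero map", call. = FALSE)
  rows <- row(v); cols <- col(v)
  c(row = sum(v * rows) / tot, col = sum(v * cols) / tot)
}

#' Single-differential (bipolar) intensity
#'
#' The conventional bipolar-montage feature: the common logarithm of the
#' RMS of the difference between two consecutive channels along the muscle
#' fiber direction (rows of the grid), computed over the same window span
#' as the activation maps.
#'
#' @param recording A preprocessed [emg_recording()].
#' @param muscle Muscle label (must exist in the montage).
#' @param window_span Half-open 0-based sample span `c(start, end)`.
#' @param site 1-based `(row, col)` within the muscle region; default is the
#'   middle row / central column. The neighbour is `(row + 1, col)`.
#' @param eps Clamping floor in mV for the log (default 1e-6).
#' @return Scalar, log10 mV.
#' @export
single_differential <- function(recording, muscle, window_span,
                                site = NULL, eps = 1e-6) {
  tbl <- muscle_channel_table(recording$geometries)
  if (!muscle %in% names(tbl))
    stop(sprintf("single_differential: unknown muscle '%s'", muscle), call. = FALSE)
  info <- tbl[[muscle]]
  if (is.null(site))
    site <- c(max(1L, info$rows %/% 2L), (info$cols + 1L) %/% 2L)
  if (site[1] >= info$rows)
    stop("single_differential: site on the last row has no fiber-direction neighbour",
         call. = FALSE)
  local_a <- (site[1] - 1L) * info$cols + site[2]
  local_b <- site[1] * info$cols + site[2]
  ch_a <- info$channels[local_a]; ch_b <- info$channels[local_b]
  idx <- (window_span[1] + 1L):window_span[2]
  d <- recording$signals[ch_a, idx] - recording$signals[ch_b, idx]
  log10(max(sqrt(mean(d^2)), eps))
}

#' Assemble a classifier feature vector
#'
#' Concatenates per-muscle features in the canonical [muscle_order()] under
#' one of the three feature-set definitions: `"I"` (5 intensities), `"I+CG"`
#' (per muscle `I`, `CG_row`, `CG_col`; 15 values) or `"Diff"` (5
#' single-differential intensities).
#'
#' @param maps Named list of one `activation_map` per muscle (a common
#'   window index), as one element of [compute_maps()] output transposed;
#'   required for `"I"` and `"I+CG"`.
#' @param feature_set `"I"`, `"I+CG"` or `"Diff"`.
#' @param recording,window_span,sites Needed for `"Diff"`: the recording,
#'   the window span and optional named list of per-muscle sites.
#' @param eps Log clamping floor.
#' @return Named numeric vector.
#' @export
build_vector <- function(maps = NULL, feature_set = c("I", "I+CG", "Diff"),
                         recording = NULL, window_span = NULL,
                         sites = NULL, eps = 1e-6) {
  feature_set <- match.arg(feature_set)
  ord <- muscle_order()
  if (feature_set %in% c("I", "I+CG")) {
    ord <- ord[ord %in% names(maps)]
    if (!length(ord)) stop("build_vector: no known muscles in maps", call. = FALSE)
    out <- numeric(0)
    for (m in ord) {
      I <- intensity(maps[[m]], eps = eps)
      if (feature_set == "I") {
        out <- c(out, stats::setNames(I, paste0("I_", m)))
      } else {
        cg <- tryCatch(center_of_gravity(maps[[m]]), error = function(e) {
          g <- dim(maps[[m]])
          warning(sprintf("all-zero map for %s; substituting grid centroid", m))
          c(row = (g[1] + 1) / 2, col = (g[2] + 1) / 2)
        })
        out <- c(out, stats::setNames(c(I, cg[1], cg[2]),
                                      paste0(c("I_", "CGr_", "CGc_"), m)))
      }
    }
    return(out)
  }
  # Diff
  stopifnot(!is.null(recording), !is.null(window_span))
  tbl <- muscle_channel_table(recording$geometries)
  ord <- ord[ord %in% names(tbl)]
  vapply(ord, function(m)
    single_differential(recording, m, window_span,
                        site = sites[[m]], eps = eps),
    numeric(1)) -> v
  stats::setNames(v, paste0("Diff_", ord))
}

#' Feature table for a set of epochs
#'
#' Runs map computation once per recording and assembles one feature vector
#' per epoch. The returned data frame carries the epoch bookkeeping
#' (recording id, task, level, window) followed by the feature columns.
#'
#' @param recordings List of preprocessed [emg_recording()] objects.
#' @param epochs An `epoch_set` (see [select_submax_epochs()]) whose
#'   `recording` column indexes into `recordings`.
#' @param feature_set `"I"`, `"I+CG"` or `"Diff"`.
#' @param window_s Analysis window (must match the epoching window).
#' @param bad_channels Optional list (per recording) of artifact channel
#'   indices to interpolate.
#' @param eps Log clamping floor.
#' @return Data frame: `class`, `recording`, `task`, `level`, `window`,
#'   then feature columns.
#' @export
build_feature_table <- function(recordings, epochs,
                                feature_set = c("I", "I+CG", "Diff"),
                                window_s = 0.250, bad_channels = NULL,
                                eps = 1e-6) {
  feature_set <- match.arg(feature_set)
  ep <- epochs$epochs
  need <- sort(unique(ep$recording))
  rows <- vector("list", nrow(ep))
  for (ri in need) {
    rec <- recordings[[ri]]
    bad <- if (is.null(bad_channels)) integer(0) else bad_channels[[ri]]
    win <- as.integer(round(window_s * rec$fs))
    if (feature_set %in% c("I", "I+CG"))
      maps <- compute_maps(rec, window_s = window_s, bad = bad)
    sel <- which(ep$recording == ri)
    for (k in sel) {
      w <- ep$window[k]
      span <- c((w - 1L) * win, w * win)
      fv <- if (feature_set == "Diff")
        build_vector(feature_set = "Diff", recording = rec,
                     window_span = span, eps = eps)
      else
        build_vector(lapply(maps, `[[`, w), feature_set = feature_set,
                     eps = eps)
      rows[[k]] <- fv
    }
  }
  feat <- do.call(rbind, rows)
  data.frame(class = ep$class, recording = ep$recording,
             task = ep$task, level = ep$level, window = ep$window,
             feat, check.names = FALSE)
}
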