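#' Torque-guided selection of submaximal epochs
#'
#' Candidate analysis windows are the non-overlapping 250 ms windows
#' (aligned to sample 0) whose mean torque stays inside the level-specific
#' band: within 5 %MVC of the 10 %MVC target, within 10 %MVC of the
#' 30 %MVC and 50 %MVC targets. The `n` candidates closest to the target
#' (smallest absolute deviation of the window-mean torque, ties broken by
#' earlier start) are returned.
#'
#' @param recording An [emg_recording()] with `target_level` set.
#' @param n Number of epochs to select (default 20).
#' @param window_s Window length in seconds.
#' @param recording_index Index stored in the output (for multi-recording
#'   bookkeeping).
#' @return An object of class `epoch_set`: list with `epochs` (data frame
#'   `recording`, `window`, `class`, `task`, `level`) and `scheme`.
#' @export
select_submax_epochs <- function(recording, n = 20, window_s = 0.250,
                                 recording_index = 1L) {
  stopifnot(inherits(recording, "emg_recording"))
  lvl <- recording$target_level
  if (is.na(lvl) || !lvl %in% c(0.10, 0.30, 0.50))
    stop("select_submax_epochs: recording has no submaximal target level",
         call. = FALSE)
  target <- 100 * lvl
  half_band <- if (lvl == 0.10) 5 else 10
  win <- as.integer(round(window_s * recording$fs))
  n_win <- length(recording$torque) %/% win
  if (n_win < 1L)
    stop("select_submax_epochs: recording shorter than one window", call. = FALSE)
  mt <- vapply(seq_len(n_win), function(w)
    mean(recording$torque[((w - 1L) * win + 1L):(w * win)]), numeric(1))
  cand <- which(abs(mt - target) <= half_band)
  if (length(cand) < n)
    stop(sprintf(
      "select_submax_epochs: only %d windows inside the +/-%g %%MVC band (need %d)",
      length(cand), half_band, n), call. = FALSE)
  o <- cand[order(abs(mt[cand] - target), cand)]
  sel <- sort(o[seq_len(n)])
  structure(list(
    epochs = data.frame(recording = recording_index, window = sel,
                        class = paste0(recording$task, "_",
                                       sprintf("%02d", round(target))),
                        task = recording$task, level = lvl),
    scheme = "task_level"), class = "epoch_set")
}

#' Rest (no-activity) epochs from the rest prefixes
#'
#' Candidate windows lie entirely inside the first `rest_s` seconds of each
#' recording; the `n_total` windows with the lowest mean absolute torque
#' across all recordings are labelled `NoAct` (ties broken by recording
#' order, then time).
#'
#' @param recordings List of [emg_recording()] objects.
#' @param n_total Total number of rest epochs (default 60).
#' @param window_s Window length in seconds.
#' @return An `epoch_set` with class label `"NoAct"`.
#' @export
select_rest_epochs <- function(recordings, n_total = 60, window_s = 0.250) {
  cand <- list()
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    win <- as.integer(round(window_s * rec$fs))
    n_rest <- as.integer(rec$rest_s * rec$fs) %/% win
    if (n_rest < 1L) {
      warning(sprintf("recording %d has no usable rest prefix; skipped", ri))
      next
    }
    mt <- vapply(seq_len(n_rest), function(w)
      mean(abs(rec$torque[((w - 1L) * win + 1L):(w * win)])), numeric(1))
    cand[[length(cand) + 1L]] <-
      data.frame(recording = ri, window = seq_len(n_rest), dev = mt)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) < n_total)
    stop(sprintf("select_rest_epochs: only %d rest windows available (need %d)",
                 if (is.null(cand)) 0L else nrow(cand), n_total), call. = FALSE)
  o <- order(cand$dev, cand$recording, cand$window)
  sel <- cand[o[seq_len(n_total)], ]
  sel <- sel[order(sel$recording, sel$window), ]
  structure(list(
    epochs = data.frame(recording = sel$recording, window = sel$window,
                        class = "NoAct", task = "rest", level = NA_real_),
    scheme = "rest"), class = "epoch_set")
}

#' Split an endurance contraction into TDC segments
#'
#' The contraction portion (after the rest prefix, until the end of the
#' recording = task failure) is split into `k` contiguous segments of equal
#' window counts — quintiles of the total duration of contraction (TDC) by
#' default — with remainder windows assigned to the last segment.
#'
#' @param recording An endurance [emg_recording()].
#' @param k Number of segments (default 5).
#' @param window_s Window length in seconds.
#' @return List of `k` integer vectors of window indices (1-based, indexing
#'   the recording's non-overlapping windows).
#' @export
tdc_segments <- function(recording, k = 5, window_s = 0.250) {
  stopifnot(inherits(recording, "emg_recording"))
  if (recording$phase != "endurance")
    stop("tdc_segments: recording is not an endurance contraction", call. = FALSE)
  win <- as.integer(round(window_s * recording$fs))
  n_win <- ncol(recording$signals) %/% win
  first <- as.integer(recording$rest_s * recording$fs) %/% win + 1L
  contraction <- seq(first, n_win)
  if (length(contraction) < k)
    stop(sprintf("tdc_segments: only %d contraction windows for %d segments",
                 length(contraction), k), call. = FALSE)
  per <- length(contraction) %/% k
  out <- vector("list", k)
  for (s in seq_len(k)) {
    from <- (s - 1L) * per + 1L
    to <- if (s == k) length(contraction) else s * per
    out[[s]] <- contraction[from:to]
  }
  out
}

#' Time-effect epochs (first TDC quintile)
#'
#' Returns the windows of the first 0-20 % TDC segment of an endurance
#' recording as epochs labelled by the recording's task — the validation
#' material for the time-effect analysis.
#'
#' @inheritParams tdc_segments
#' @param recording_index Index stored in the output.
#' @return An `epoch_set`.
#' @export
time_effect_subset <- function(recording, window_s = 0.250,
                               recording_index = 1L) {
  seg <- tdc_segments(recording, k = 5, window_s = window_s)[[1]]
  structure(list(
    epochs = data.frame(recording = recording_index, window = seg,
                        class = recording$task, task = recording$task,
                        level = NA_real_),
    scheme = "time_effect"), class = "epoch_set")
}

#' Combine epoch sets
#' @param ... `epoch_set` objects.
#' @param scheme Label for the combined set.
#' @return An `epoch_set`.
#' @export
combine_epochs <- function(..., scheme = "combined") {
  sets <- list(...)
  structure(list(epochs = do.call(rbind, lapply(sets, `[[`, "epochs")),
                 scheme = scheme), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set (%s): %d epochs, %d classes\n", x$scheme,
              nrow(x$epochs), length(unique(x$epochs$class))))
  print(table(x$epochs$class))
  invisible(x)
}
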