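#' HD-EMG recording bundle
#'
#' Container for one multichannel monopolar HD-EMG recording with its
#' synchronized torque trace and metadata. Signals are a channels x samples
#' matrix in mV; torque shares the signal time base and is expressed in
#' %MVC. Tasks follow the four isometric forearm tasks plus rest.
#'
#' @param signals Numeric matrix, channels x samples, mV.
#' @param fs Sampling rate in Hz.
#' @param geometries List of [array_geometry()] objects; their total channel
#'   count must equal `nrow(signals)`.
#' @param torque Numeric vector of `ncol(signals)` samples, %MVC.
#' @param task One of `"flexion"`, `"extension"`, `"supination"`,
#'   `"pronation"`, `"rest"`.
#' @param target_level Target effort as a fraction of MVC (0.10, 0.30 or
#'   0.50) or `NA` for rest/endurance-to-failure recordings.
#' @param phase One of `"submaximal"`, `"time_effect_source"`, `"endurance"`.
#' @param rest_s Duration of the rest prefix in seconds (default 3).
#' @param mvc Optional named numeric vector of per-task maximal torques.
#' @param id Optional recording identifier.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signals, fs, geometries, torque, task,
                          target_level = NA_real_, phase = "submaximal",
                          rest_s = 3, mvc = NULL, id = NULL) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("emg_recording: signals must be a numeric matrix", call. = FALSE)
  if (ncol(signals) < 1L)
    stop("emg_recording: recording has no samples", call. = FALSE)
  n_ch <- sum(vapply(geometries, n_channels, integer(1)))
  if (nrow(signals) != n_ch)
    stop(sprintf("emg_recording: %d signal rows but geometries define %d channels",
                 nrow(signals), n_ch), call. = FALSE)
  if (length(torque) != ncol(signals))
    stop("emg_recording: torque and signals must share the time base", call. = FALSE)
  task <- match.arg(task, c("flexion", "extension", "supination", "pronation", "rest"))
  phase <- match.arg(phase, c("submaximal", "time_effect_source", "endurance"))
  if (!is.na(target_level) && !isTRUE(all.equal(target_level, 0.10)) &&
      !isTRUE(all.equal(target_level, 0.30)) && !isTRUE(all.equal(target_level, 0.50)))
    stop("emg_recording: target_level must be 0.10, 0.30, 0.50 or NA", call. = FALSE)
  structure(list(signals = signals, fs = fs, geometries = geometries,
                 torque = as.numeric(torque), task = task,
                 target_level = target_level, phase = phase,
                 rest_s = rest_s, mvc = mvc,
                 id = if (is.null(id)) sprintf("%s_%s", task,
                        ifelse(is.na(target_level), phase,
                               sprintf("%02d", round(100 * target_level)))) else id),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("HD-EMG recording '%s': %d channels x %d samples (%.2f s @ %g Hz)\n",
              x$id, nrow(x$signals), ncol(x$signals),
              ncol(x$signals) / x$fs, x$fs))
  cat(sprintf("  task %s, target level %s, phase %s, rest prefix %g s\n",
              x$task,
              ifelse(is.na(x$target_level), "none",
                     sprintf("%d %%MVC", round(100 * x$target_level))),
              x$phase, x$rest_s))
  invisible(x)
}

#' @export
duration.emg_recording <- function(x) ncol(x$signals) / x$fs

#' Recording duration in seconds
#' @param x An object with a time extent.
#' @export
duration <- function(x) UseMethod("duration")

geometry_to_list <- function(g) {
  list(name = g$name, rows = g$rows, cols = g$cols, pitch = g$pitch,
       muscle_regions = lapply(g$muscle_regions, as.integer))
}

geometry_from_list <- function(l) {
  array_geometry(l$name, l$rows, l$cols, l$pitch,
                 lapply(l$muscle_regions, as.integer))
}

#' Save / load a recording bundle
#'
#' A bundle is a JSON metadata sidecar (`<path>.json`) plus raw little-endian
#' float32 matrices: `<path>.f32` holding the signals channel-major and
#' `<path>.torque.f32` holding the torque trace. Saving quantizes signal and
#' torque values to float32; loading a saved bundle and saving it again is
#' bit-exact.
#'
#' @param recording An [emg_recording()].
#' @param path Bundle path without extension.
#' @return `save_bundle`: `path`, invisibly. `load_bundle`: the validated
#'   [emg_recording()].
#' @export
save_bundle <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  if (ncol(recording$signals) == 0L)
    stop("save_bundle: empty recording", call. = FALSE)
  meta <- list(
    fs = recording$fs,
    n_channels = nrow(recording$signals),
    n_samples = ncol(recording$signals),
    geometries = lapply(recording$geometries, geometry_to_list),
    task = recording$task,
    target_level = if (is.na(recording$target_level)) NULL else recording$target_level,
    phase = recording$phase,
    rest_s = recording$rest_s,
    mvc = as.list(recording$mvc),
    id = recording$id)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(paste0(path, ".f32"), "wb")
  on.exit(close(con), add = TRUE)
  # channel-major: channel 0's samples first
  writeBin(as.numeric(t(recording$signals)), con, size = 4L, endian = "little")
  con2 <- file(paste0(path, ".torque.f32"), "wb")
  on.exit(close(con2), add = TRUE)
  writeBin(as.numeric(recording$torque), con2, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("load_bundle: missing sidecar '%s'", sidecar), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
  n_ch <- as.integer(meta$n_channels); n_s <- as.integer(meta$n_samples)
  f32 <- paste0(path, ".f32")
  if (!file.exists(f32))
    stop(sprintf("load_bundle: missing matrix file '%s'", f32), call. = FALSE)
  n_avail <- file.info(f32)$size / 4
  if (n_avail != n_ch * n_s)
    stop(sprintf("load_bundle: metadata promises %d x %d values but '%s' holds %g",
                 n_ch, n_s, f32, n_avail), call. = FALSE)
  con <- file(f32, "rb"); on.exit(close(con), add = TRUE)
  sig <- readBin(con, numeric(), n = n_ch * n_s, size = 4L, endian = "little")
  signals <- matrix(sig, nrow = n_ch, ncol = n_s, byrow = TRUE)
  tq_file <- paste0(path, ".torque.f32")
  con2 <- file(tq_file, "rb"); on.exit(close(con2), add = TRUE)
  torque <- readBin(con2, numeric(), n = n_s, size = 4L, endian = "little")
  if (length(torque) != n_s)
    stop("load_bundle: torque length does not match sample count", call. = FALSE)
  emg_recording(signals, fs = meta$fs,
                geometries = lapply(meta$geometries, geometry_from_list),
                torque = torque, task = meta$task,
                target_level = if (is.null(meta$target_level)) NA_real_ else meta$target_level,
                phase = meta$phase, rest_s = meta$rest_s,
                mvc = if (length(meta$mvc)) unlist(meta$mvc) else NULL,
                id = meta$id)
}

#' Session of recordings for one subject
#'
#' Groups the recordings of a measurement session and tags each with the
#' analysis sets it belongs to: submaximal recordings form the submaximal
#' set; endurance recordings belong to both the time-effect set (their first
#' 20 % TDC) and the endurance set.
#'
#' @param recordings List of [emg_recording()] objects.
#' @param subject_id Subject label.
#' @return An object of class `emg_session`.
#' @export
emg_session <- function(recordings, subject_id = "S1") {
  stopifnot(length(recordings) >= 1L,
            all(vapply(recordings, inherits, logical(1), "emg_recording")))
  tags <- lapply(recordings, function(r)
    if (r$phase == "submaximal") "submaximal" else c("time_effect", "endurance"))
  structure(list(recordings = recordings, subject_id = subject_id,
                 set_tags = tags),
            class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  n_sub <- sum(vapply(x$recordings, function(r) r$phase == "submaximal", logical(1)))
  cat(sprintf("HD-EMG session '%s': %d recordings (%d submaximal, %d endurance)\n",
              x$subject_id, length(x$recordings), n_sub,
              length(x$recordings) - n_sub))
  invisible(x)
}

session_subset <- function(session, tag) {
  keep <- vapply(seq_along(session$recordings),
                 function(i) tag %in% session$set_tags[[i]], logical(1))
  session$recordings[keep]
}

#' Save / load a full session as bundles plus a manifest
#'
#' Writes every recording as a bundle under `dir` and a `manifest.json`
#' listing bundle names with their set tags.
#'
#' @param session An [emg_session()].
#' @param dir Output directory.
#' @return `save_session`: `dir` invisibly; `load_session`: the session.
#' @export
save_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  names <- character(length(session$recordings))
  for (i in seq_along(session$recordings)) {
    names[i] <- sprintf("rec%02d_%s", i, session$recordings[[i]]$id)
    save_bundle(session$recordings[[i]], file.path(dir, names[i]))
  }
  jsonlite::write_json(
    list(subject_id = session$subject_id,
         bundles = lapply(seq_along(names), function(i)
           list(name = names[i], tags = as.list(session$set_tags[[i]])))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_session
#' @export
load_session <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  recs <- lapply(man$bundles, function(b) load_bundle(file.path(dir, b$name)))
  emg_session(recs, subject_id = man$subject_id)
}
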