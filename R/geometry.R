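#' Electrode array geometry
#'
#' Describes one 2-D electrode grid: its size, inter-electrode pitch and the
#' assignment of column ranges to muscles. Channels are laid out row-major;
#' grid coordinates are 1-based in user-facing code while flat channel
#' indices are 0-based.
#'
#' @param name Array label, e.g. `"A1"`.
#' @param rows,cols Grid dimensions (each at least 2).
#' @param pitch Inter-electrode distance in mm (default 10).
#' @param muscle_regions Named list mapping a muscle label to an inclusive
#'   column range `c(from, to)`. Ranges must be disjoint and inside
#'   `[1, cols]`; every channel belongs to at most one muscle.
#' @return An object of class `array_geometry`.
#' @examples
#' g <- array_geometry("A2", 6, 12,
#'                     muscle_regions = list(biceps_brachii = c(1, 12)))
#' n_channels(g)
#' @export
array_geometry <- function(name, rows, cols, pitch = 10, muscle_regions = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2L || cols < 2L)
    stop("array_geometry: rows and cols must each be >= 2", call. = FALSE)
  if (!is.numeric(pitch) || pitch <= 0)
    stop("array_geometry: pitch must be positive", call. = FALSE)
  if (length(muscle_regions)) {
    if (is.null(names(muscle_regions)) || any(names(muscle_regions) == ""))
      stop("array_geometry: muscle_regions must be a named list", call. = FALSE)
    rng <- lapply(muscle_regions, function(r) {
      r <- as.integer(r)
      if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > cols)
        stop("array_geometry: each muscle region must be an inclusive column range within [1, cols]",
             call. = FALSE)
      r
    })
    covered <- unlist(lapply(rng, function(r) seq(r[1], r[2])))
    if (anyDuplicated(covered))
      stop("array_geometry: muscle regions overlap", call. = FALSE)
    muscle_regions <- rng
  }
  structure(list(name = name, rows = rows, cols = cols, pitch = pitch,
                 muscle_regions = muscle_regions),
            class = "array_geometry")
}

#' @rdname array_geometry
#' @param geometry An `array_geometry`.
#' @export
n_channels <- function(geometry) geometry$rows * geometry$cols

#' Grid-to-flat channel index
#'
#' Maps a 1-based grid position `(row, col)` of an array to the 0-based
#' flat channel index within that array (row-major), and back.
#'
#' @param geometry An [array_geometry()].
#' @param row,col 1-based grid coordinates.
#' @return `channel_index`: 0-based flat index. `channel_grid`: a list with
#'   elements `row` and `col`.
#' @examples
#' g <- array_geometry("A1", 6, 16,
#'                     muscle_regions = list(anconeus = c(1, 5)))
#' channel_index(g, 1, 1)   # 0
#' channel_index(g, 6, 16)  # 95
#' @export
channel_index <- function(geometry, row, col) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (any(row < 1L) || any(row > geometry$rows) ||
      any(col < 1L) || any(col > geometry$cols))
    stop("channel_index: grid position out of range", call. = FALSE)
  (as.integer(row) - 1L) * geometry$cols + (as.integer(col) - 1L)
}

#' @rdname channel_index
#' @param flat 0-based flat channel index.
#' @export
channel_grid <- function(geometry, flat) {
  stopifnot(inherits(geometry, "array_geometry"))
  flat <- as.integer(flat)
  if (any(flat < 0L) || any(flat >= n_channels(geometry)))
    stop("channel_grid: flat index out of range", call. = FALSE)
  list(row = flat %/% geometry$cols + 1L, col = flat %% geometry$cols + 1L)
}

#' Default three-array montage
#'
#' The standard montage used throughout: array A1 (6 x 16) on the forearm
#' covering Anconeus, Brachioradialis and Pronator Teres; A2 (6 x 12) over
#' Biceps Brachii; A3 (6 x 12) over Triceps Brachii — 240 monopolar
#' channels in total. The column split of A1 among its three muscles is a
#' configurable convention (5/6/5 columns by default).
#'
#' @param a1_split Integer vector of three column counts for the A1
#'   muscles, summing to 16.
#' @return List of three `array_geometry` objects.
#' @export
default_geometries <- function(a1_split = c(5L, 6L, 5L)) {
  a1_split <- as.integer(a1_split)
  stopifnot(length(a1_split) == 3L, sum(a1_split) == 16L, all(a1_split >= 2L))
  b <- cumsum(c(0L, a1_split))
  list(
    array_geometry("A1", 6, 16, muscle_regions = list(
      anconeus        = c(b[1] + 1L, b[2]),
      brachioradialis = c(b[2] + 1L, b[3]),
      pronator_teres  = c(b[3] + 1L, b[4]))),
    array_geometry("A2", 6, 12, muscle_regions = list(biceps_brachii = c(1L, 12L))),
    array_geometry("A3", 6, 12, muscle_regions = list(triceps_brachii = c(1L, 12L)))
  )
}

#' Reduced-size montage for fast experimentation
#'
#' Same five-muscle layout as [default_geometries()] on smaller grids
#' (4 x 9 + 4 x 6 + 4 x 6 = 84 channels); used by the quick simulator
#' presets.
#'
#' @return List of three `array_geometry` objects.
#' @export
small_geometries <- function() {
  list(
    array_geometry("A1", 4, 9, muscle_regions = list(
      anconeus        = c(1L, 3L),
      brachioradialis = c(4L, 6L),
      pronator_teres  = c(7L, 9L))),
    array_geometry("A2", 4, 6, muscle_regions = list(biceps_brachii = c(1L, 6L))),
    array_geometry("A3", 4, 6, muscle_regions = list(triceps_brachii = c(1L, 6L)))
  )
}

#' Canonical muscle order used in feature vectors
#' @return Character vector of the five muscle labels.
#' @export
muscle_order <- function() {
  c("biceps_brachii", "triceps_brachii", "anconeus",
    "brachioradialis", "pronator_teres")
}

# Map every muscle of a montage to (geometry index, global row range of the
# signal matrix, local column range). Geometries are stacked in list order,
# each row-major.
muscle_channel_table <- function(geometries) {
  offset <- 0L
  out <- list()
  for (gi in seq_along(geometries)) {
    g <- geometries[[gi]]
    for (m in names(g$muscle_regions)) {
      r <- g$muscle_regions[[m]]
      idx <- integer(0)
      for (i in seq_len(g$rows))
        idx <- c(idx, offset + channel_index(g, i, seq(r[1], r[2])) + 1L)
      out[[m]] <- list(geometry = gi, rows = g$rows,
                       cols = r[2] - r[1] + 1L, col_range = r,
                       channels = idx)   # 1-based global rows, row-major grid
    }
    offset <- offset + n_channels(g)
  }
  out
}
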