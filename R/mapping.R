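#' HD-EMG activation maps
#'
#' An activation map is the grid of per-channel RMS values of one muscle's
#' electrode region over one analysis window: `HM[i, j] = RMS(sEMG[i, j])`.
#' Maps are computed on non-overlapping windows (250 ms by default) aligned
#' to sample 0 of the recording; a trailing partial window is discarded.
#'
#' @param recording A preprocessed [emg_recording()].
#' @param window_s Analysis window length in seconds (default 0.250).
#' @param bad Optional integer vector of artifact channels (global indices,
#'   e.g. from [screen_channels()]); their map cells are replaced by
#'   scattered-data interpolation over the good cells of the same region.
#' @return A list, one element per muscle (in [muscle_order()] where
#'   present), each a list of `activation_map` objects: a `rows x cols`
#'   numeric matrix with attributes `muscle`, `window_index` and
#'   `window_span` (half-open sample span, 0-based).
#' @examples
#' g <- list(array_geometry("G", 4, 4, muscle_regions = list(m = c(1, 4))))
#' r <- emg_recording(matrix(rnorm(16 * 2048), 16), 2048, g,
#'                    torque = numeric(2048), task = "flexion",
#'                    target_level = 0.10)
#' maps <- compute_maps(r)
#' length(maps$m)  # 4 windows of 250 ms in 1 s
#' @export
compute_maps <- function(recording, window_s = 0.250, bad = integer(0)) {
  stopifnot(inherits(recording, "emg_recording"), window_s > 0)
  fs <- recording$fs
  win <- as.integer(round(window_s * fs))
  n_s <- ncol(recording$signals)
  if (win > n_s)
    stop("compute_maps: window longer than the recording", call. = FALSE)
  n_win <- n_s %/% win
  tbl <- muscle_channel_table(recording$geometries)
  ord <- muscle_order()[muscle_order() %in% names(tbl)]
  if (!length(ord)) ord <- names(tbl)
  sq <- recording$signals^2
  out <- stats::setNames(vector("list", length(ord)), ord)
  for (m in ord) {
    info <- tbl[[m]]
    bad_local <- match(intersect(bad, info$channels), info$channels)
    maps <- vector("list", n_win)
    for (w in seq_len(n_win)) {
      span <- c((w - 1L) * win, w * win)   # half-open, 0-based
      rms <- sqrt(rowMeans(sq[info$channels, (span[1] + 1L):span[2], drop = FALSE]))
      hm <- matrix(rms, nrow = info$rows, ncol = info$cols, byrow = TRUE)
      hm <- structure(hm, muscle = m, window_index = w, window_span = span,
                      class = c("activation_map", "matrix"))
      if (length(bad_local)) {
        bl <- cbind((bad_local - 1L) %/% info$cols + 1L,
                    (bad_local - 1L) %% info$cols + 1L)
        hm <- interpolate_bad(hm, bl)
      }
      maps[[w]] <- hm
    }
    out[[m]] <- maps
  }
  out
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("Activation map: muscle %s, window %d (samples %d-%d)\n",
              attr(x, "muscle"), attr(x, "window_index"),
              attr(x, "window_span")[1], attr(x, "window_span")[2]))
  print(unclass(x)[seq_len(nrow(x)), , drop = FALSE], ...)
  invisible(x)
}

#' @export
plot.activation_map <- function(x, ...) {
  graphics::image(t(unclass(x))[, nrow(x):1, drop = FALSE],
                  xlab = "column", ylab = "row",
                  main = sprintf("%s, window %d", attr(x, "muscle"),
                                 attr(x, "window_index")), ...)
  invisible(x)
}

# ---- scattered-data interpolation helpers ------------------------------

# Andrew's monotone-chain convex hull; points: n x 2 matrix. Returns hull
# vertex indices in counter-clockwise order.
convex_hull <- function(pts) {
  n <- nrow(pts)
  o <- order(pts[, 1], pts[, 2])
  cross <- function(o1, o2, o3)
    (pts[o2, 1] - pts[o1, 1]) * (pts[o3, 2] - pts[o1, 2]) -
    (pts[o2, 2] - pts[o1, 2]) * (pts[o3, 1] - pts[o1, 1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(h[length(h) - 1], h[length(h)], i) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(o)
  upper <- build(rev(o))
  c(lower[-length(lower)], upper[-length(upper)])
}

# Point-in-convex-polygon (hull vertices counter-clockwise), boundary counts
# as inside; small tolerance absorbs floating-point edge cases.
in_hull <- function(p, pts, hull, tol = 1e-9) {
  nh <- length(hull)
  if (nh < 3) return(FALSE)
  for (i in seq_len(nh)) {
    a <- pts[hull[i], ]; b <- pts[hull[i %% nh + 1], ]
    if ((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) < -tol)
      return(FALSE)
  }
  TRUE
}

# Exact thin-plate-spline interpolant fitted to (x, y, z); evaluates at xi.
# The affine polynomial part makes the interpolant exact for planes.
tps_interp <- function(xy, z, xi) {
  n <- nrow(xy)
  phi <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
  d2 <- as.matrix(stats::dist(xy))^2
  K <- phi(d2)
  P <- cbind(1, xy)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, 0, 0, 0)
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) qr.solve(A, rhs, tol = 1e-12))
  w <- sol[seq_len(n)]; a <- sol[n + 1:3]
  apply(xi, 1L, function(p) {
    r2 <- (xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2
    sum(w * phi(r2)) + a[1] + a[2] * p[1] + a[3] * p[2]
  })
}

#' Interpolate artifact cells of an activation map
#'
#' Replaces the listed bad cells with values interpolated from the good
#' cells of the same map using an exact thin-plate-spline scattered-data
#' interpolant (smooth, reproduces planar fields exactly). Bad cells lying
#' outside the convex hull of the good cells fall back to the
#' nearest-neighbour good value. Good cells are never altered.
#'
#' @param map An `activation_map` (or plain matrix).
#' @param bad Two-column matrix of 1-based `(row, col)` positions.
#' @return The map with bad cells replaced.
#' @export
interpolate_bad <- function(map, bad) {
  if (is.null(dim(bad))) bad <- matrix(bad, ncol = 2)
  if (nrow(bad) == 0L) return(map)
  nr <- nrow(map); nc <- ncol(map)
  if (any(bad[, 1] < 1 | bad[, 1] > nr | bad[, 2] < 1 | bad[, 2] > nc))
    stop("interpolate_bad: bad cell outside the grid", call. = FALSE)
  bad_flat <- (bad[, 1] - 1L) * nc + bad[, 2]
  all_flat <- seq_len(nr * nc)
  good_flat <- setdiff(all_flat, bad_flat)
  if (!length(good_flat))
    stop("interpolate_bad: no good cells to interpolate from", call. = FALSE)
  gxy <- cbind((good_flat - 1L) %/% nc + 1L, (good_flat - 1L) %% nc + 1L)
  gz <- map[gxy]
  hull <- convex_hull(gxy)
  inside <- vapply(seq_len(nrow(bad)), function(i)
    in_hull(as.numeric(bad[i, ]), gxy, hull), logical(1))
  vals <- numeric(nrow(bad))
  if (any(inside))
    vals[inside] <- tps_interp(gxy, gz, bad[inside, , drop = FALSE])
  if (any(!inside)) {
    for (i in which(!inside)) {
      d2 <- (gxy[, 1] - bad[i, 1])^2 + (gxy[, 2] - bad[i, 2])^2
      vals[i] <- gz[which.min(d2)]
    }
  }
  out <- map
  out[bad] <- vals
  out
}
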