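#' Centroid track from one camera
#'
#' Per-frame particle centroid positions from a single camera, paired with
#' frame timestamps. The vertical coordinate is depth below the release point
#' (m, increasing downward); the horizontal coordinate is the in-view lateral
#' position (m). Consumer webcams record at a variable frame rate, so
#' timestamps need not be uniform — velocities are later obtained by least
#' squares, not frame differencing.
#'
#' @param camera_id 1 or 2 (the two cameras are mounted at 90 degrees).
#' @param t Timestamps, s, strictly increasing.
#' @param horiz Horizontal positions, m.
#' @param vert Vertical positions (depth), m.
#' @param depth_window Optional length-2 depth interval (m) over which the
#'   settling velocity should be computed (e.g. the central 0.8 m of the
#'   tank, away from release transients and bottom end effects).
#' @return An object of class `centroid_track`.
#' @export
centroid_track <- function(camera_id, t, horiz, vert, depth_window = NULL) {
  if (!camera_id %in% c(1, 2)) stop("camera_id must be 1 or 2", call. = FALSE)
  n <- length(t)
  if (n < 2L || length(horiz) != n || length(vert) != n) {
    stop("t, horiz and vert must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  if (!is.null(depth_window)) {
    stopifnot(length(depth_window) == 2L, depth_window[1] < depth_window[2])
  }
  structure(list(camera_id = as.integer(camera_id),
                 t = as.numeric(t), horiz = as.numeric(horiz), vert = as.numeric(vert),
                 depth_window = depth_window),
            class = "centroid_track")
}

#' @export
print.centroid_track <- function(x, ...) {
  cat(sprintf("<centroid_track> camera %d, %d samples over %.2f s, depth %.3f-%.3f m\n",
              x$camera_id, length(x$t), diff(range(x$t)), min(x$vert), max(x$vert)))
  invisible(x)
}

ls_slope <- function(t, p) {
  tc <- t - mean(t)
  sum(tc * (p - mean(p))) / sum(tc^2)
}

#' Settling speed from a pair of two-camera tracks
#'
#' For each camera, the horizontal and vertical velocity components are the
#' least-squares slopes of position against timestamp over the depth window
#' (robust to the variable frame rate of consumer webcams; identical to the
#' average velocity for uniform motion). Each camera's resultant speed is
#' `sqrt(U_horiz^2 + U_z^2)`, and the two resultants are averaged into a
#' single speed estimate for the drop.
#'
#' @param track1,track2 [centroid_track()]s from the two cameras.
#' @param depth_window Optional length-2 depth interval (m); overrides the
#'   windows stored in the tracks. `NULL` uses each track's own window, or
#'   all samples if none is set.
#' @return Settling speed, m s^-1.
#' @export
track_velocity <- function(track1, track2, depth_window = NULL) {
  stopifnot(inherits(track1, "centroid_track"), inherits(track2, "centroid_track"))
  one <- function(tr) {
    win <- if (!is.null(depth_window)) depth_window else tr$depth_window
    sel <- if (is.null(win)) rep(TRUE, length(tr$t)) else
      tr$vert >= win[1] & tr$vert <= win[2]
    if (sum(sel) < 2L) {
      stop(sprintf("insufficient data: camera %d has %d sample(s) in the depth window",
                   tr$camera_id, sum(sel)), call. = FALSE)
    }
    uh <- ls_slope(tr$t[sel], tr$horiz[sel])
    uz <- ls_slope(tr$t[sel], tr$vert[sel])
    sqrt(uh^2 + uz^2)
  }
  (one(track1) + one(track2)) / 2
}

#' Aggregate replicate drop speeds with the median +/- 5% filter
#'
#' Each model is dropped several times; replicates beyond a threshold of
#' +/- 5% of the median sinking velocity are discarded and the mean is taken
#' over the survivors. The boundary is inclusive (a replicate at exactly 5%
#' from the median is kept), and the median itself always survives, so the
#' result is never empty.
#'
#' @param speeds Replicate settling speeds, m s^-1 (at least one).
#' @return An object of class `replicate_set` with fields `speeds`, `kept`
#'   (logical mask), `median_U` and `mean_U` (mean over kept replicates only).
#' @examples
#' aggregate_replicates(c(1.00, 1.01, 0.99, 1.20, 0.98)) # keeps 4, mean 0.995
#' @export
aggregate_replicates <- function(speeds) {
  if (length(speeds) < 1L || any(!is.finite(speeds)) || any(speeds <= 0)) {
    stop("speeds must be a non-empty vector of positive finite values", call. = FALSE)
  }
  med <- stats::median(speeds)
  kept <- speeds >= 0.95 * med & speeds <= 1.05 * med
  structure(list(speeds = as.numeric(speeds), kept = kept,
                 median_U = med, mean_U = mean(speeds[kept])),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %d/%d replicates kept (median %.4g), mean U = %.4g m s^-1\n",
              sum(x$kept), length(x$speeds), x$median_U, x$mean_U))
  invisible(x)
}
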