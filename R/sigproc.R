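# Preprocessing and repetition segmentation.
#
# The device chain applies a sliding (moving-average) filter, re-expresses
# each device's channels relative to its pose at movement onset (headless
# mode), and delimits repetitions by hysteresis crossing of the primary
# movement channel.

#' Sliding (moving-average) filter
#'
#' Centered moving average of odd window length. At the sequence edges the
#' window is truncated to the available samples, so the output has the
#' same length as the input and filtering a constant sequence is the
#' identity.
#'
#' @param signal Non-empty numeric vector.
#' @param window Odd positive integer window length (frames).
#' @return Numeric vector, same length as \code{signal}.
#' @examples
#' sliding_filter(c(0, 3, 0), window = 3)  # 1.5 1.0 1.5
#' @export
sliding_filter <- function(signal, window = 5) {
  if (length(signal) == 0) stop_param("`signal` must be non-empty")
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != round(window) || window %% 2 == 0) {
    stop_param("`window` must be an odd positive integer")
  }
  if (window == 1) return(as.numeric(signal))
  as.numeric(zoo::rollapply(zoo::zoo(as.numeric(signal)), width = window,
                            FUN = mean, partial = TRUE, align = "center"))
}

# Orthonormal body frame from one sample's accelerometer (gravity) and
# magnetometer readings (TRIAD construction). Columns are the frame axes;
# premultiplying by its transpose maps sensor readings into the canonical
# z-up frame.
pose_basis <- function(accel, mag) {
  z <- normalize3(accel)
  if (all(z == 0)) z <- c(0, 0, 1)
  y <- cross3(z, normalize3(mag))
  if (sqrt(sum(y^2)) < 1e-8) {
    # magnetometer parallel to gravity: fall back to an arbitrary
    # horizontal reference (rotation about z then becomes undefined)
    ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    y <- cross3(z, ref)
  }
  y <- normalize3(y)
  x <- cross3(y, z)
  cbind(x, y, z)
}

#' Rebase a stream to its initial pose (headless mode)
#'
#' Re-expresses every device's accelerometer, gyroscope, and magnetometer
#' channels relative to the device's pose at the first sample, emulating
#' the headless-mode convention in which the position at movement onset is
#' defined as the origin by coordinate transformation. The initial frame
#' is gravity-aligned (z up); a stream already in that pose is unchanged,
#' and a stream pre-rotated by any fixed rotation rebases to the same
#' result.
#'
#' @param stream A \code{motion_stream}.
#' @return The rebased \code{motion_stream}.
#' @export
rebase_orientation <- function(stream) {
  if (!inherits(stream, "motion_stream") || length(stream$devices) == 0 ||
      nrow(stream$devices[[1]]) == 0) {
    stop_param("`stream` must be a non-empty motion_stream")
  }
  out <- stream
  for (d in names(stream$devices)) {
    fr <- stream$devices[[d]]
    m <- pose_basis(c(fr$ax[1], fr$ay[1], fr$az[1]),
                    c(fr$mx[1], fr$my[1], fr$mz[1]))
    rot <- function(cols) {
      v <- t(m) %*% t(as.matrix(fr[, cols]))
      fr[, cols] <<- t(v)
    }
    rot(c("ax", "ay", "az"))
    rot(c("gx", "gy", "gz"))
    rot(c("mx", "my", "mz"))
    out$devices[[d]] <- fr
  }
  out
}

#' Apply a fixed rotation to every device of a stream
#'
#' Utility (mainly for testing headless-mode invariance): rotates the
#' accelerometer, gyroscope, and magnetometer vectors of every frame by
#' the same 3x3 rotation matrix, emulating an arbitrary sensor mounting
#' orientation.
#'
#' @param stream A \code{motion_stream}.
#' @param rotation A 3x3 rotation matrix.
#' @return The rotated \code{motion_stream}.
#' @export
rotate_stream <- function(stream, rotation) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  out <- stream
  for (d in names(stream$devices)) {
    fr <- stream$devices[[d]]
    for (cols in list(c("ax", "ay", "az"), c("gx", "gy", "gz"),
                      c("mx", "my", "mz"))) {
      fr[, cols] <- t(rotation %*% t(as.matrix(fr[, cols])))
    }
    out$devices[[d]] <- fr
  }
  out
}

#' Primary movement channel of a stream
#'
#' Reduces the multi-channel stream to the scalar channel the Table-style
#' feature formulas operate on: for limb exercises, the magnitude of the
#' dynamic acceleration of the proximal IMU (Euclidean distance from the
#' first-sample acceleration, in g); for hand exercises, the wrist pitch
#' angle in degrees derived from the glove accelerometer. Both choices are
#' invariant to the sensor's mounting orientation once the stream has been
#' rebased.
#'
#' @param stream A \code{motion_stream} (rebase first; see
#'   \code{\link{rebase_orientation}}).
#' @return Numeric vector, one value per frame.
#' @export
primary_channel <- function(stream) {
  fr <- stream$devices[[stream$primary_device]]
  if (is.null(fr)) stop_param("stream lacks its primary device")
  a <- as.matrix(fr[, c("ax", "ay", "az")])
  if (stream$segment == "hand") {
    atan2(-a[, 1], sqrt(a[, 2]^2 + a[, 3]^2)) * 180 / pi
  } else {
    sqrt(rowSums(sweep(a, 2, a[1, ])^2))
  }
}

#' A detected repetition segment
#'
#' @param start_index,end_index 0-based half-open frame indices.
#' @param rep_index Ordinal of the segment within the bout.
#' @param primary Filtered primary-channel slice for the segment.
#' @param flex Optional matrix of glove flex channels for the segment.
#' @param fs Sampling rate in Hz.
#' @return An object of class \code{repetition_segment}.
#' @keywords internal
repetition_segment <- function(start_index, end_index, rep_index, primary,
                               flex = NULL, fs = 30) {
  structure(
    list(start_index = as.integer(start_index),
         end_index = as.integer(end_index),
         rep_index = as.integer(rep_index),
         primary = primary, flex = flex, fs = fs),
    class = "repetition_segment"
  )
}

#' @export
print.repetition_segment <- function(x, ...) {
  cat(sprintf("<repetition_segment> #%d frames [%d, %d) (%.2f s)\n",
              x$rep_index, x$start_index, x$end_index,
              (x$end_index - x$start_index) / x$fs))
  invisible(x)
}

#' Segment a stream into repetitions
#'
#' Delimits repetitions by hysteresis crossing of the filtered primary
#' channel: candidate segments are maximal runs above a low threshold
#' (40\% of \code{threshold_frac} times the signal range above baseline),
#' kept if they clearly rise toward the nominal activity level
#' (\code{threshold_frac} of the range), then extended outward to the
#' near-baseline crossing so boundaries track movement onset and offset.
#' Segments shorter than \code{min_duration} are discarded.
#'
#' @param stream A \code{motion_stream} (ideally rebased).
#' @param threshold_frac Nominal activity threshold as a fraction of the
#'   signal range above baseline; default 0.3.
#' @param min_duration Minimum segment duration in seconds; default 0.5.
#' @param filter_window Sliding-filter window applied to the primary
#'   channel before thresholding; default 5.
#' @return A list of \code{repetition_segment} objects (possibly empty).
#' @examples
#' st <- generate_session("squat", synth_params(n_reps = 3, noise_sd = 0))
#' length(segment_repetitions(st))
#' @export
segment_repetitions <- function(stream, threshold_frac = 0.3,
                                min_duration = 0.5, filter_window = 5) {
  if (!inherits(stream, "motion_stream")) {
    stop_param("`stream` must be a motion_stream")
  }
  n <- nrow(stream$devices[[1]])
  if (n == 0) return(list())
  x <- sliding_filter(primary_channel(stream), filter_window)
  base <- as.numeric(stats::quantile(x, 0.05))
  rng <- max(x) - base
  if (!is.finite(rng) || rng < 1e-9) return(list())
  t_lo <- base + 0.4 * threshold_frac * rng
  t_keep <- base + 0.7 * threshold_frac * rng
  above <- x > t_lo
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0) return(list())
  # keep runs that rise convincingly above the detection band
  keep <- vapply(seq_len(nrow(runs)), function(i) {
    max(x[runs$start[i]:runs$end[i]]) >= t_keep
  }, logical(1))
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0) return(list())
  # extend each run outward to the near-baseline crossing
  eps <- base + 0.01 * rng
  min_frames <- max(2L, as.integer(ceiling(min_duration * stream$fs)))
  segs <- list()
  prev_end <- 0L  # 1-based exclusive floor for extension
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]
    e <- runs$end[i]
    floor_i <- max(prev_end + 1L, 1L)
    ceil_i <- if (i < nrow(runs)) runs$start[i + 1] - 1L else n
    while (s > floor_i && x[s - 1] > eps) s <- s - 1L
    while (e < ceil_i && x[e + 1] > eps) e <- e + 1L
    prev_end <- e
    if (e - s + 1L < min_frames) next
    flex <- NULL
    gl <- stream$devices[["glove"]]
    if (!is.null(gl)) {
      flex <- as.matrix(gl[s:e, paste0("flex", 1:5), drop = FALSE])
    }
    segs[[length(segs) + 1L]] <- repetition_segment(
      start_index = s - 1L, end_index = e, rep_index = length(segs) + 1L,
      primary = x[s:e], flex = flex, fs = stream$fs)
  }
  segs
}

#' Dump segments to a debug CSV
#'
#' @param segments List of \code{repetition_segment}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
segments_to_csv <- function(segments, path) {
  df <- data.frame(
    rep_index = vapply(segments, `[[`, integer(1), "rep_index"),
    start_t = vapply(segments, function(s) s$start_index / s$fs, numeric(1)),
    end_t = vapply(segments, function(s) s$end_index / s$fs, numeric(1))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
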