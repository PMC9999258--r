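# Synthetic 30 Hz sensor-stream generator with ground-truth labels.
#
# The generator stands in for the wearable hardware: two 9-axis IMU
# modules for limb exercises (upper_arm/lower_arm or thigh/calf) or the
# rehabilitation glove (one IMU + five flex sensors) for hand exercises.
# Repetitions follow a closed-form raised-cosine (or minimum-jerk)
# out-and-back profile so that amplitude and jerk are analytically
# checkable downstream.

#' Parameters for synthetic session generation
#'
#' @param n_reps Number of repetitions (>= 0).
#' @param amplitude Peak-to-trough span of each repetition on the primary
#'   channel: dynamic acceleration in g for limb exercises, wrist pitch in
#'   degrees for hand exercises.
#' @param rep_duration Duration of one repetition in seconds (>= 0.5).
#' @param pause_duration Rest between repetitions in seconds (>= 0).
#' @param noise_sd Standard deviation of additive Gaussian sensor noise,
#'   in primary-channel units (>= 0).
#' @param smoothness In [0, 1]; 1 gives the pure smooth profile, lower
#'   values add 4-8 Hz tremor harmonics scaled by (1 - smoothness).
#' @param seed Integer seed; all randomness in one generated session
#'   derives from it.
#' @param profile Repetition shape: \code{"raised_cosine"} (default) or
#'   \code{"minimum_jerk"} (out-and-back quintic).
#' @return An object of class \code{synth_params}.
#' @examples
#' synth_params(n_reps = 5, amplitude = 2, noise_sd = 0)
#' @export
synth_params <- function(n_reps = 10, amplitude = 2, rep_duration = 2,
                         pause_duration = 1, noise_sd = 0.02,
                         smoothness = 1, seed = 1,
                         profile = c("raised_cosine", "minimum_jerk")) {
  profile <- match.arg(profile)
  assert_scalar_number(n_reps, "n_reps", lower = 0)
  if (n_reps != round(n_reps)) stop_param("`n_reps` must be an integer")
  assert_scalar_number(amplitude, "amplitude", lower = 0)
  assert_scalar_number(rep_duration, "rep_duration", lower = 0.5)
  assert_scalar_number(pause_duration, "pause_duration", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(smoothness, "smoothness", lower = 0, upper = 1)
  assert_scalar_number(seed, "seed")
  structure(
    list(n_reps = as.integer(n_reps), amplitude = amplitude,
         rep_duration = rep_duration, pause_duration = pause_duration,
         noise_sd = noise_sd, smoothness = smoothness,
         seed = as.integer(seed), profile = profile, fs = 30),
    class = "synth_params"
  )
}

# Unit out-and-back shape on tau in [0, 1): 0 -> 1 -> 0.
rep_shape <- function(tau, profile) {
  if (profile == "raised_cosine") {
    (1 - cos(2 * pi * tau)) / 2
  } else {
    # minimum-jerk quintic on each half
    u <- ifelse(tau <= 0.5, 2 * tau, 2 * (1 - tau))
    10 * u^3 - 15 * u^4 + 6 * u^5
  }
}

# Scalar movement profile over the frame grid, plus ground-truth windows.
build_profile <- function(params, amps) {
  fs <- params$fs
  n_reps <- params$n_reps
  pau <- params$pause_duration
  rep_d <- params$rep_duration
  total <- if (n_reps > 0) pau + n_reps * (rep_d + pau) else max(2 * pau, 1)
  n_frames <- floor(total * fs) + 1L
  t <- (seq_len(n_frames) - 1L) / fs
  p <- numeric(n_frames)
  gt <- data.frame(rep_index = integer(0), start_index = integer(0),
                   end_index = integer(0), t_start = numeric(0),
                   t_end = numeric(0), amplitude = numeric(0),
                   intended_valid = logical(0))
  if (n_reps > 0) {
    tremor_phase <- stats::runif(2, 0, 2 * pi)
    for (i in seq_len(n_reps)) {
      t0 <- pau + (i - 1) * (rep_d + pau)
      t1 <- t0 + rep_d
      idx <- which(t >= t0 & t < t1)
      tau <- (t[idx] - t0) / rep_d
      shape <- rep_shape(tau, params$profile)
      seg <- amps[i] * shape
      if (params$smoothness < 1) {
        trem <- (1 - params$smoothness) * 0.08 * amps[i] * shape *
          (sin(2 * pi * 4.7 * t[idx] + tremor_phase[1]) +
             sin(2 * pi * 6.3 * t[idx] + tremor_phase[2]))
        seg <- seg + trem
      }
      p[idx] <- seg
      gt <- rbind(gt, data.frame(
        rep_index = i,
        start_index = as.integer(round(t0 * fs)),
        end_index = as.integer(round(t1 * fs)),
        t_start = t0, t_end = t1,
        amplitude = amps[i], intended_valid = TRUE))
    }
  }
  list(t = t, p = p, ground_truth = gt)
}

# One limb-mounted IMU device frame table. `scale` damps the profile for
# the distal module (the two modules move with different excursions).
imu_device_frames <- function(t, p, scale, fs, noise_sd) {
  n <- length(t)
  ps <- p * scale
  dp <- c(0, diff(ps)) * fs            # primary-axis rate, units/s
  nz <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
  data.frame(
    t = t,
    ax = ps + nz(noise_sd), ay = nz(noise_sd), az = 1 + nz(noise_sd),
    gx = nz(10 * noise_sd), gy = dp + nz(10 * noise_sd),
    gz = nz(10 * noise_sd),
    mx = 0.6 + nz(0.1 * noise_sd), my = nz(0.1 * noise_sd),
    mz = 0.8 + nz(0.1 * noise_sd)
  )
}

# Glove device: the profile is a wrist pitch angle in degrees, encoded in
# the gravity direction; flex channels mirror the normalized profile.
glove_device_frames <- function(t, p, fs, noise_sd, nominal_amp) {
  n <- length(t)
  r <- p * pi / 180
  dth <- c(0, diff(p)) * fs            # deg/s
  nz <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
  # accel noise expressed in g: the pitch proxy has slope ~57.3 deg per g
  # near rest, so divide the (degree-scale) noise_sd accordingly
  a_sd <- noise_sd * pi / 180
  fr <- data.frame(
    t = t,
    ax = -sin(r) + nz(a_sd), ay = nz(a_sd), az = cos(r) + nz(a_sd),
    gx = nz(10 * a_sd), gy = dth + nz(10 * a_sd), gz = nz(10 * a_sd),
    mx = cos(r) * 0.6 - sin(r) * 0.8 + nz(0.1 * a_sd),
    my = nz(0.1 * a_sd),
    mz = sin(r) * 0.6 + cos(r) * 0.8 + nz(0.1 * a_sd)
  )
  base <- if (nominal_amp > 0) 0.8 * p / nominal_amp else p * 0
  for (k in 1:5) {
    fr[[paste0("flex", k)]] <- pmin(pmax(base + nz(0.02 * (noise_sd > 0)),
                                         0), 1)
  }
  fr
}

#' Generate one synthetic training session
#'
#' Produces a ground-truth-labeled multi-device sensor stream emulating a
#' patient performing \code{n_reps} repetitions of a catalog exercise:
#' smooth out-and-back movement profiles separated by rest pauses, with
#' additive Gaussian sensor noise. Identical parameters (including
#' \code{seed}) give bit-identical streams.
#'
#' @param exercise A catalog exercise id (see \code{\link{exercise_catalog}})
#'   or the list returned by \code{\link{get_exercise}}.
#' @param params A \code{\link{synth_params}} object.
#' @param rep_amplitudes Optional per-repetition amplitude vector of length
#'   \code{n_reps}, overriding \code{params$amplitude} (used by
#'   \code{\link{degrade_repetitions}}).
#' @return A \code{motion_stream}: list with \code{exercise_id},
#'   \code{segment}, \code{fs}, \code{primary_device}, \code{devices}
#'   (named list of frame data.frames with columns \code{t, ax..az,
#'   gx..gz, mx..mz} and \code{flex1..flex5} for the glove), and
#'   \code{ground_truth} (repetition windows, 0-based half-open frame
#'   indices, per-rep amplitude and intended-validity flag).
#' @examples
#' st <- generate_session("bobath_handshake",
#'                        synth_params(n_reps = 3, noise_sd = 0, seed = 7))
#' st$ground_truth
#' @export
generate_session <- function(exercise, params, rep_amplitudes = NULL) {
  ex <- if (is.character(exercise)) get_exercise(exercise) else exercise
  if (!is.list(ex) || is.null(ex$id) || is.null(ex$devices)) {
    stop_param("`exercise` must be a catalog id or get_exercise() result")
  }
  if (!inherits(params, "synth_params")) {
    stop_param("`params` must come from synth_params()")
  }
  amps <- if (is.null(rep_amplitudes)) {
    rep(params$amplitude, params$n_reps)
  } else {
    if (length(rep_amplitudes) != params$n_reps) {
      stop_param("rep_amplitudes must have length n_reps")
    }
    rep_amplitudes
  }
  with_seed(params$seed, {
    prof <- build_profile(params, amps)
    devices <- list()
    for (d in ex$devices) {
      devices[[d]] <- switch(
        d,
        glove = glove_device_frames(prof$t, prof$p, params$fs,
                                    params$noise_sd, params$amplitude),
        # proximal module carries the full profile, distal one 60%
        imu_device_frames(prof$t, prof$p,
                          scale = if (d == ex$devices[1]) 1 else 0.6,
                          fs = params$fs, noise_sd = params$noise_sd)
      )
    }
    structure(
      list(exercise_id = ex$id, segment = ex$segment, fs = params$fs,
           primary_device = ex$devices[1], devices = devices,
           ground_truth = prof$ground_truth, params = params),
      class = "motion_stream"
    )
  })
}

#' @export
print.motion_stream <- function(x, ...) {
  n <- nrow(x$devices[[1]])
  cat(sprintf(
    "<motion_stream> exercise '%s' (%s): %d frames @ %g Hz, %d device(s), %d ground-truth rep(s)\n",
    x$exercise_id, x$segment, n, x$fs, length(x$devices),
    nrow(x$ground_truth)))
  invisible(x)
}

#' Degrade selected repetitions of a synthetic stream
#'
#' Rescales the movement amplitude of the listed ground-truth repetitions
#' by \code{factor} and marks them as not intended to be valid, producing
#' known-invalid repetitions for testing the threshold logic. The stream
#' is regenerated deterministically from its stored parameters, so the
#' noise realization and all untouched repetitions are unchanged.
#'
#' @param stream A \code{motion_stream} produced by
#'   \code{\link{generate_session}}.
#' @param indices Repetition ordinals (1-based ground-truth
#'   \code{rep_index}) to degrade.
#' @param factor Amplitude scale in [0, 1).
#' @return A new \code{motion_stream} with updated frames and ground truth.
#' @examples
#' st <- generate_session("squat", synth_params(n_reps = 5, noise_sd = 0))
#' dg <- degrade_repetitions(st, 2, 0.3)
#' dg$ground_truth$intended_valid
#' @export
degrade_repetitions <- function(stream, indices, factor) {
  if (!inherits(stream, "motion_stream") || is.null(stream$params)) {
    stop_param("`stream` must be a generated motion_stream")
  }
  assert_scalar_number(factor, "factor", lower = 0)
  if (factor >= 1) stop_param("`factor` must be < 1")
  indices <- unique(as.integer(indices))
  if (length(indices) == 0) return(stream)
  if (any(indices < 1 | indices > nrow(stream$ground_truth))) {
    stop_param("repetition index out of range")
  }
  amps <- stream$ground_truth$amplitude
  amps[indices] <- amps[indices] * factor
  out <- generate_session(get_exercise(stream$exercise_id), stream$params,
                          rep_amplitudes = amps)
  out$ground_truth$intended_valid <-
    stream$ground_truth$intended_valid & !(out$ground_truth$rep_index %in% indices)
  out
}
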