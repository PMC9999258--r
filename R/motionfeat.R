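# Per-repetition motion features.
#
# Five scalar features summarize one repetition of the primary channel:
# AMP (movement magnitude), MEAN (movement direction), RMS (dynamic
# energy), JERK (smoothness; normalized, dimensionless, lower = smoother),
# and Strength (exercise effort, from the glove flex sensors).

#' Movement amplitude (AMP)
#'
#' Peak-to-trough span, \code{max(x) - min(x)}.
#'
#' @param x Non-empty numeric vector.
#' @return Non-negative scalar.
#' @export
feature_amp <- function(x) {
  if (length(x) == 0 || !is.numeric(x)) stop_param("`x` must be non-empty numeric")
  max(x) - min(x)
}

#' Movement direction (MEAN)
#'
#' Arithmetic mean of the signal.
#'
#' @inheritParams feature_amp
#' @return Scalar.
#' @export
feature_mean <- function(x) {
  if (length(x) == 0 || !is.numeric(x)) stop_param("`x` must be non-empty numeric")
  mean(x)
}

#' Motion dynamic energy (RMS)
#'
#' Root mean square, \code{sqrt(mean(x^2))}.
#'
#' @inheritParams feature_amp
#' @return Non-negative scalar.
#' @export
feature_rms <- function(x) {
  if (length(x) == 0 || !is.numeric(x)) stop_param("`x` must be non-empty numeric")
  sqrt(mean(x^2))
}

#' Motion smoothness (normalized JERK)
#'
#' Mean squared first difference of the signal, expressed as a rate via
#' the sampling frequency and normalized by \code{fs^2 * amp(x)^2} so the
#' metric is dimensionless and invariant to amplitude rescaling:
#' \deqn{J = \frac{\frac{1}{N-1}\sum_i ((x_{i+1}-x_i) f_s)^2}{f_s^2\,\mathrm{amp}(x)^2}}
#' Defined as 0 for constant signals (amp = 0). Lower values indicate
#' smoother movement.
#'
#' @param x Numeric vector of length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @return Non-negative dimensionless scalar.
#' @examples
#' feature_jerk(c(0, 1, 2, 3), fs = 30)  # 1/9
#' @export
feature_jerk <- function(x, fs = 30) {
  if (length(x) < 2) stop_param("`x` must have length >= 2")
  assert_scalar_number(fs, "fs", lower = 0, strict_lower = TRUE)
  a <- feature_amp(x)
  if (a == 0) return(0)
  mean((diff(x) * fs)^2) / (fs^2 * a^2)
}

#' Exercise effort (Strength)
#'
#' Mean over time of the mean flex-sensor deflection from the first
#' frame (the reference frame itself is excluded from the average),
#' clipped to be non-negative. Only available for glove (hand exercise)
#' streams; for other streams the feature is reported as 0 with
#' \code{available = FALSE}.
#'
#' @param flex Matrix with one row per frame and one column per flex
#'   channel (values in [0, 1]), or \code{NULL} when no glove is worn.
#' @return List with \code{value} (non-negative scalar) and
#'   \code{available} (flag).
#' @export
feature_strength <- function(flex) {
  if (is.null(flex)) return(list(value = 0, available = FALSE))
  flex <- as.matrix(flex)
  if (nrow(flex) == 0) stop_param("`flex` must have at least one frame")
  if (nrow(flex) == 1) return(list(value = 0, available = TRUE))
  defl <- sweep(flex[-1, , drop = FALSE], 2, flex[1, ])
  list(value = max(0, mean(rowMeans(defl))), available = TRUE)
}

#' Extract the full feature vector of one repetition
#'
#' Applies AMP, MEAN, RMS, and JERK to the segment's primary channel and
#' Strength to the glove flex channels (when present).
#'
#' @param segment A \code{repetition_segment} from
#'   \code{\link{segment_repetitions}}.
#' @param fs Sampling rate in Hz; defaults to the segment's own rate.
#' @return A \code{feature_vector}: list with \code{amp}, \code{mean},
#'   \code{rms}, \code{jerk}, \code{strength}, and
#'   \code{strength_available}.
#' @export
extract_features <- function(segment, fs = NULL) {
  if (!inherits(segment, "repetition_segment")) {
    stop_param("`segment` must be a repetition_segment")
  }
  fs <- if (is.null(fs)) segment$fs else fs
  x <- segment$primary
  s <- feature_strength(segment$flex)
  structure(
    list(amp = feature_amp(x), mean = feature_mean(x),
         rms = feature_rms(x), jerk = feature_jerk(x, fs),
         strength = s$value, strength_available = s$available),
    class = "feature_vector"
  )
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf(
    "<feature_vector> amp=%.4g mean=%.4g rms=%.4g jerk=%.4g strength=%.4g%s\n",
    x$amp, x$mean, x$rms, x$jerk, x$strength,
    if (x$strength_available) "" else " (strength unavailable)"))
  invisible(x)
}

#' Export feature vectors as a data.frame / CSV
#'
#' @param features List of \code{feature_vector} objects, one per
#'   repetition.
#' @param path Optional CSV output path.
#' @return Data.frame with columns \code{rep_index, amp, mean, rms, jerk,
#'   strength}.
#' @export
features_to_csv <- function(features, path = NULL) {
  df <- data.frame(
    rep_index = seq_along(features),
    amp = vapply(features, `[[`, numeric(1), "amp"),
    mean = vapply(features, `[[`, numeric(1), "mean"),
    rms = vapply(features, `[[`, numeric(1), "rms"),
    jerk = vapply(features, `[[`, numeric(1), "jerk"),
    strength = vapply(features, `[[`, numeric(1), "strength")
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
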