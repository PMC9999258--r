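#' The 16-exercise rehabilitation catalog
#'
#' Returns the fixed catalog of rehabilitation training movements used by
#' the system: 8 upper-extremity, 5 hand, and 3 lower-extremity exercises.
#' Upper-extremity exercises use two IMU modules strapped to the upper and
#' lower arm, lower-extremity exercises use the same modules on the thigh
#' and calf, and hand exercises use the rehabilitation glove (one IMU plus
#' five flex sensors).
#'
#' @return A data.frame with one row per exercise and columns
#'   \code{id}, \code{name}, \code{segment} (one of \code{"upper"},
#'   \code{"hand"}, \code{"lower"}) and \code{devices} (comma-separated
#'   device roles required by the exercise).
#' @examples
#' cat16 <- exercise_catalog()
#' table(cat16$segment)
#' @export
exercise_catalog <- function() {
  upper <- c(
    bobath_handshake        = "Bobath handshake training",
    bobath_flex_ext         = "Bobath flexion and extension",
    bobath_ext_ant_flex_ext = "Bobath external anterior flexion and extension",
    bobath_pre_post_rot     = "Bobath pre- and postrotation",
    breast_expansion        = "Breast expansion exercise",
    shoulder_int_ext_rot    = "Shoulder joint internal and external rotation",
    shoulder_touch          = "Shoulder touch training",
    elbow_flex_touch        = "Elbow joint flexion and touch"
  )
  hand <- c(
    flex_pressure_rot   = "Flexion-pressure rotation forward and backward",
    wrist_flex_ext      = "Wrist flexion and extension",
    elbow_flex_wrist    = "Elbow flexion and wrist compression training",
    finger_to_finger    = "Finger-to-finger training",
    ball_gripping       = "Ball gripping training"
  )
  lower <- c(
    squat            = "Squat training",
    knee_flex_ext    = "Knee flexion and extension",
    knee_int_ext_rot = "Knee internal and external rotation"
  )
  devices <- c(upper = "upper_arm,lower_arm",
               hand  = "glove",
               lower = "thigh,calf")
  seg <- rep(c("upper", "hand", "lower"), c(length(upper), length(hand),
                                            length(lower)))
  data.frame(
    id = c(names(upper), names(hand), names(lower)),
    name = unname(c(upper, hand, lower)),
    segment = seg,
    devices = unname(devices[seg]),
    stringsAsFactors = FALSE
  )
}

#' Look up one exercise from the catalog
#'
#' @param exercise_id Catalog id, e.g. \code{"bobath_handshake"}.
#' @return A one-row list with fields \code{id}, \code{name},
#'   \code{segment}, and \code{devices} (character vector of device roles).
#' @examples
#' get_exercise("squat")$devices
#' @export
get_exercise <- function(exercise_id) {
  cat16 <- exercise_catalog()
  i <- match(exercise_id, cat16$id)
  if (is.na(i)) {
    stop_param("unknown exercise id '%s'; see exercise_catalog()",
               exercise_id)
  }
  list(
    id = cat16$id[i],
    name = cat16$name[i],
    segment = cat16$segment[i],
    devices = strsplit(cat16$devices[i], ",", fixed = TRUE)[[1]]
  )
}
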