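# Similarity scoring against standard-movement templates, validity by
# difficulty threshold, and game/session score accumulation.
#
# A repetition is a "valid action" when its weighted feature similarity to
# the standard movement meets the difficulty threshold: 80% for hard, 60%
# for moderate, 40% for easy. Each valid action increments the game score
# by one point (one apple picked); invalid actions leave it unchanged.

DIFFICULTY_LEVELS <- c("easy", "moderate", "hard")
DIFFICULTY_THRESHOLDS <- c(easy = 0.40, moderate = 0.60, hard = 0.80)
FEATURE_NAMES <- c("amp", "mean", "rms", "jerk", "strength")
# hard-mode weights in feature order (amp, mean, rms, jerk, strength)
HARD_MODE_WEIGHTS <- c(amp = 0.5, mean = 0.2, rms = 0.1, jerk = 0.1,
                       strength = 0.1)

#' Validity threshold of a difficulty level
#'
#' @param level One of \code{"easy"}, \code{"moderate"}, \code{"hard"}.
#' @return The similarity threshold: 0.40, 0.60, or 0.80.
#' @examples
#' difficulty_threshold("hard")
#' @export
difficulty_threshold <- function(level) {
  level <- match.arg(level, DIFFICULTY_LEVELS)
  unname(DIFFICULTY_THRESHOLDS[level])
}

#' Build a standard-movement reference template
#'
#' @param exercise_id Catalog exercise id.
#' @param difficulty Difficulty level; selects the default feature set:
#'   easy uses AMP only (simple mode), moderate uses AMP and RMS with
#'   weights 0.7/0.3, hard uses all five features with weights
#'   0.5/0.2/0.1/0.1/0.1 in the order (amp, mean, rms, jerk, strength).
#' @param ref_features Named numeric vector of reference feature values
#'   for the standard movement (at least the active features).
#' @param weights Optional named weights over \code{active_set}
#'   (non-negative, summing to 1); defaults per difficulty as above.
#' @param active_set Optional character subset of
#'   \code{c("amp","mean","rms","jerk","strength")}.
#' @return An object of class \code{reference_template}.
#' @export
reference_template <- function(exercise_id, difficulty, ref_features,
                               weights = NULL, active_set = NULL) {
  difficulty <- match.arg(difficulty, DIFFICULTY_LEVELS)
  if (is.null(active_set)) {
    active_set <- switch(difficulty,
                         easy = "amp",
                         moderate = c("amp", "rms"),
                         hard = FEATURE_NAMES)
  }
  if (!all(active_set %in% FEATURE_NAMES)) {
    stop_param("active_set must be a subset of the five feature names")
  }
  if (is.null(weights)) {
    weights <- switch(difficulty,
                      easy = c(amp = 1),
                      moderate = c(amp = 0.7, rms = 0.3),
                      hard = HARD_MODE_WEIGHTS)
    weights <- weights[active_set]
  }
  if (is.null(names(weights)) || !setequal(names(weights), active_set)) {
    stop_param("weights must be named after the active feature set")
  }
  weights <- weights[active_set]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop_param("weights must be non-negative and sum to 1")
  }
  if (!all(active_set %in% names(ref_features)) ||
      !all(is.finite(ref_features[active_set]))) {
    stop_param("ref_features must supply finite values for the active set")
  }
  if ("amp" %in% active_set && ref_features[["amp"]] <= 0) {
    stop_param("reference amp must be > 0")
  }
  structure(
    list(exercise_id = exercise_id, difficulty = difficulty,
         ref_features = ref_features[intersect(FEATURE_NAMES,
                                               names(ref_features))],
         weights = weights, active_set = active_set),
    class = "reference_template"
  )
}

#' Derive a template from a noiseless standard-movement stream
#'
#' Runs the segmentation/feature pipeline on a reference stream (the
#' stand-in for the standard training video) and uses the mean feature
#' vector over its repetitions as the template reference values.
#'
#' @param stream A \code{motion_stream} of the standard movement.
#' @param difficulty Difficulty level of the session to score.
#' @return A \code{reference_template}.
#' @export
template_from_reference <- function(stream, difficulty) {
  difficulty <- match.arg(difficulty, DIFFICULTY_LEVELS)
  segs <- segment_repetitions(rebase_orientation(stream))
  if (length(segs) == 0) stop_param("reference stream has no repetitions")
  fv <- features_to_csv(lapply(segs, extract_features))
  ref <- colMeans(fv[, FEATURE_NAMES])
  active <- switch(difficulty,
                   easy = "amp", moderate = c("amp", "rms"), FEATURE_NAMES)
  # strength is only meaningful for glove streams
  if (is.null(stream$devices[["glove"]])) {
    active <- setdiff(active, "strength")
    w <- switch(difficulty, easy = c(amp = 1),
                moderate = c(amp = 0.7, rms = 0.3),
                hard = HARD_MODE_WEIGHTS[setdiff(FEATURE_NAMES, "strength")] /
                  sum(HARD_MODE_WEIGHTS[setdiff(FEATURE_NAMES, "strength")]))
    return(reference_template(stream$exercise_id, difficulty, ref,
                              weights = w, active_set = active))
  }
  reference_template(stream$exercise_id, difficulty, ref)
}

#' Similarity of one feature value to its reference
#'
#' Relative-error kernel: \code{s = max(0, 1 - |f - ref| / |ref|)},
#' clipped to [0, 1]. When the reference value is 0 the comparison falls
#' back to an absolute scale of 1 unit.
#'
#' @param f Observed feature value (finite).
#' @param ref Reference feature value (finite).
#' @return Similarity fraction in [0, 1].
#' @examples
#' feature_similarity(1.5, 2)  # 0.75
#' @export
feature_similarity <- function(f, ref) {
  if (!is.finite(f) || !is.finite(ref)) {
    stop_param("feature and reference values must be finite")
  }
  scale <- if (ref != 0) abs(ref) else 1
  min(1, max(0, 1 - abs(f - ref) / scale))
}

#' Weighted similarity of a feature vector to a template
#'
#' Convex combination of per-feature similarities over the template's
#' active feature set. If the strength feature is in the active set but
#' unavailable (no glove worn), it is dropped and the remaining weights
#' renormalized.
#'
#' @param features A \code{feature_vector} (or named list/vector with the
#'   active features).
#' @param template A \code{reference_template}.
#' @return Combined similarity fraction in [0, 1].
#' @export
combined_score <- function(features, template) {
  if (!inherits(template, "reference_template")) {
    stop_param("`template` must be a reference_template")
  }
  active <- template$active_set
  w <- template$weights
  unavailable <- "strength" %in% active &&
    !is.null(features$strength_available) && !features$strength_available
  if (unavailable) {
    active <- setdiff(active, "strength")
    if (length(active) == 0) return(0)
    w <- w[active] / sum(w[active])
  }
  sims <- vapply(active, function(k) {
    feature_similarity(as.numeric(features[[k]]),
                       as.numeric(template$ref_features[[k]]))
  }, numeric(1))
  sum(w[active] * sims)
}

#' Is a repetition a valid action?
#'
#' Inclusive comparison of the combined similarity score against the
#' difficulty threshold.
#'
#' @param score Similarity fraction in [0, 1].
#' @param difficulty Difficulty level.
#' @return Logical flag.
#' @examples
#' is_valid(0.80, "hard")  # TRUE
#' is_valid(0.79, "hard")  # FALSE
#' @export
is_valid <- function(score, difficulty) {
  assert_scalar_number(score, "score", lower = 0, upper = 1)
  score >= difficulty_threshold(difficulty)
}

#' Advance the game score by one action
#'
#' A valid action picks one apple (one point); an invalid action leaves
#' the score unchanged.
#'
#' @param score Current non-negative integer game score.
#' @param valid Logical validity flag of the action.
#' @param points_per_action Points granted per valid action (default 1).
#' @return Updated game score.
#' @export
update_game <- function(score, valid, points_per_action = 1L) {
  assert_scalar_number(score, "score", lower = 0)
  if (isTRUE(valid)) score + points_per_action else score
}

#' Score a full training session
#'
#' Runs the end-to-end pipeline on a raw stream: orientation rebasing,
#' sliding filtering, repetition segmentation, feature extraction,
#' template similarity, validity by difficulty threshold, and game/session
#' score accumulation. Deterministic for a fixed input.
#'
#' @param stream A raw \code{motion_stream}.
#' @param template A \code{reference_template} for the same exercise.
#' @param difficulty Difficulty level; defaults to the template's.
#' @return A \code{session_result}: list with \code{exercise_id},
#'   \code{difficulty}, \code{rep_results} (data.frame: rep_index,
#'   features, similarity, valid), \code{valid_count}, \code{game_score},
#'   and \code{session_score} (0-100: percentage of valid repetitions).
#' @examples
#' p <- synth_params(n_reps = 5, noise_sd = 0)
#' st <- generate_session("bobath_handshake", p)
#' tpl <- template_from_reference(st, "easy")
#' score_session(st, tpl)$session_score
#' @export
score_session <- function(stream, template, difficulty = template$difficulty) {
  if (!inherits(stream, "motion_stream")) {
    stop_param("`stream` must be a motion_stream")
  }
  if (!identical(stream$exercise_id, template$exercise_id)) {
    stop_param("template is for exercise '%s' but stream is '%s'",
               template$exercise_id, stream$exercise_id)
  }
  difficulty <- match.arg(difficulty, DIFFICULTY_LEVELS)
  segs <- segment_repetitions(rebase_orientation(stream))
  feats <- lapply(segs, extract_features)
  rep_results <- features_to_csv(feats)
  sims <- vapply(feats, combined_score, numeric(1), template = template)
  rep_results$similarity <- if (length(sims)) sims else numeric(0)
  rep_results$valid <- if (length(sims)) {
    vapply(sims, is_valid, logical(1), difficulty = difficulty)
  } else {
    logical(0)
  }
  game <- 0L
  for (v in rep_results$valid) game <- update_game(game, v)
  n <- nrow(rep_results)
  structure(
    list(exercise_id = stream$exercise_id, difficulty = difficulty,
         rep_results = rep_results,
         valid_count = sum(rep_results$valid),
         game_score = game,
         session_score = if (n > 0) 100 * sum(rep_results$valid) / n else 0),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf(
    "<session_result> '%s' (%s): %d/%d valid reps, game score %d, session score %.1f\n",
    x$exercise_id, x$difficulty, x$valid_count, nrow(x$rep_results),
    x$game_score, x$session_score))
  invisible(x)
}

#' Read reference templates from a JSON or YAML catalog file
#'
#' The file holds a list of template records with fields
#' \code{exercise_id}, \code{difficulty}, \code{ref_features},
#' and optionally \code{weights} and \code{active_set}.
#'
#' @param path Path to a \code{.json}, \code{.yaml}, or \code{.yml} file.
#' @return Named list of \code{reference_template} objects, keyed by
#'   \code{"<exercise_id>/<difficulty>"}.
#' @export
read_templates <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_param("the 'yaml' package is required to read YAML templates")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  out <- list()
  for (rec in raw) {
    tpl <- reference_template(
      rec$exercise_id, rec$difficulty, unlist(rec$ref_features),
      weights = if (!is.null(rec$weights)) unlist(rec$weights) else NULL,
      active_set = if (!is.null(rec$active_set)) unlist(rec$active_set)
                   else NULL)
    out[[paste(tpl$exercise_id, tpl$difficulty, sep = "/")]] <- tpl
  }
  out
}
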